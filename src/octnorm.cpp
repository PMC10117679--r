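// Compiled kernels: 3x3 same-padding convolution forward/backward via
// im2col + BLAS gemm, 2x2 max pooling, nearest-neighbour upsampling, and
// the monotone dynamic-programming projection of per-sample class scores
// onto ordered boundary cuts.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 kernel with zero padding 1, pixel-major layout:
// (H*W) x (9*Cin), so the inner copy along i is contiguous in both the
// source slice and the destination column.
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        double* dst = col.colptr(r);
        const uword i0 = (di < 0) ? 1 : 0;           // valid output rows
        const uword i1 = (di > 0) ? H - 1 : H;
        const uword j0 = (dj < 0) ? 1 : 0;
        const uword j1 = (dj > 0) ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          const double* src = xc + (j + dj) * H + (i0 + di);
          std::memcpy(dst + j * H + i0, src, (i1 - i0) * sizeof(double));
        }
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col3: (H*W) x (9*Cin) -> H x W x Cin
static cube col2im3(const mat& col, uword H, uword W, uword C) {
  cube x(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* xc = x.slice_memptr(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* src0 = col.colptr(r);
        const uword i0 = (di < 0) ? 1 : 0;
        const uword i1 = (di > 0) ? H - 1 : H;
        const uword j0 = (dj < 0) ? 1 : 0;
        const uword j1 = (dj > 0) ? W - 1 : W;
        for (uword j = j0; j < j1; ++j) {
          double* dst = xc + (j + dj) * H + (i0 + di);
          const double* src = src0 + j * H + i0;
          const uword n = i1 - i0;
          for (uword i = 0; i < n; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = w.n_cols;
  mat col = im2col3(x);            // (HW) x (9Cin)
  mat y = col * w;                 // (HW) x Cout  (BLAS gemm)
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3_backward(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const uword Cout = gy.n_slices;
  mat gym(const_cast<double*>(gy.memptr()), H * W, Cout, false, true);
  mat col = im2col3(x);
  mat gw = col.t() * gym;          // (9Cin) x Cout
  vec gb = sum(gym, 0).t();
  mat gcol = gym * w.t();          // (HW) x (9Cin)
  cube gx = col2im3(gcol, H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // linear index into the input slice
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword besti = 0;
        for (uword dj = 0; dj < 2; ++dj) {
          for (uword di = 0; di < 2; ++di) {
            const uword ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; besti = jj * H + ii; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = besti;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::ucube& idx, const arma::cube& gy,
                             int H, int W) {
  const uword C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < gy.n_cols; ++j) {
      for (uword i = 0; i < gy.n_rows; ++i) {
        gx.slice(c)(idx(i, j, c)) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube upsample2_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W; ++j) {
      for (uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_backward(const arma::cube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W; ++j) {
      for (uword i = 0; i < H; ++i) {
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return gx;
}

// Monotone boundary projection for one A-scan.
//
// scores: n_samples x K matrix; entry (s, c) is the reward for labeling
// sample s with class c. Finds cuts 0 <= c_0 <= ... <= c_{K-2} <= n
// maximizing the total reward of the induced monotone labeling (samples
// [0, c_0) get class 0, [c_{m-1}, c_m) class m, [c_{K-2}, n) class K-1).
// Among maximizers, returns the lexicographically smallest cut vector.
static ivec dp_cuts_impl(const mat& S /* (n+1) x K prefix sums */) {
  const uword n = S.n_rows - 1, K = S.n_cols;
  // E(c, i): best reward for samples i..n-1 using classes c..K-1
  mat E(K, n + 1);
  // suffix max of H_c(j) = S(j, c) + E(c+1, j), kept per class row
  mat HM(K, n + 1);
  for (uword i = 0; i <= n; ++i) {
    E(K - 1, i) = S(n, K - 1) - S(i, K - 1);
  }
  for (int c = (int)K - 2; c >= 0; --c) {
    double m = -datum::inf;
    for (int j = (int)n; j >= 0; --j) {
      const double h = S(j, c) + E(c + 1, j);
      if (h > m) m = h;
      HM(c, j) = m;
      E(c, j) = m - S(j, c);
    }
  }
  ivec cuts(K - 1);
  uword prev = 0;
  for (uword m = 0; m + 1 < K; ++m) {
    const double target = HM(m, prev);
    uword j = prev;
    while (S(j, m) + E(m + 1, j) != target) ++j; // exact: same arithmetic
    cuts(m) = (sword)j;
    prev = j;
  }
  return cuts;
}

// [[Rcpp::export]]
arma::ivec dp_cuts_scores(const arma::mat& scores) {
  const uword n = scores.n_rows, K = scores.n_cols;
  mat S(n + 1, K, fill::zeros);
  for (uword c = 0; c < K; ++c) {
    double acc = 0;
    for (uword s = 0; s < n; ++s) {
      acc += scores(s, c);
      S(s + 1, c) = acc;
    }
  }
  return dp_cuts_impl(S);
}

// Hard-label fast path over one B-scan: labels is n_ascans x n_samples
// with values 0..K-1; returns n_ascans x (K-1) integer cuts.
// [[Rcpp::export]]
arma::imat dp_cuts_labels(const arma::imat& labels, int K) {
  const uword A = labels.n_rows, n = labels.n_cols;
  imat cuts(A, K - 1);
  mat S(n + 1, K);
  for (uword a = 0; a < A; ++a) {
    S.zeros();
    for (uword s = 0; s < n; ++s) {
      for (int c = 0; c < K; ++c) S(s + 1, c) = S(s, c);
      const int l = labels(a, s);
      if (l >= 0 && l < K) S(s + 1, l) += 1.0;
    }
    ivec ct = dp_cuts_impl(S);
    for (int m = 0; m < K - 1; ++m) cuts(a, m) = (int)ct(m);
  }
  return cuts;
}
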