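# Per-sample layer classification of B-scans with a compact fully
# convolutional encoder-decoder, plus the projection of class maps onto
# ordered boundary surfaces by dynamic programming.
#
# Ten classes are used throughout: 0 = vitreous, 1..8 = the retinal layers
# of `retinal_layers()` (inner to outer), 9 = sub-RPE. The two background
# classes give the boundary extraction explicit above/below context.

N_CLASSES <- 10L

#' Encoder-decoder model configuration
#'
#' Hyperparameters for the compact U-type segmentation network: `depth`
#' encoder levels of 3x3 convolution + ReLU + 2x2 max pooling, a
#' bottleneck convolution, and a mirrored decoder that nearest-neighbour
#' upsamples and concatenates the matching encoder feature map (the skip
#' connection) before each convolution. A 1x1 convolution maps the final
#' features to the 10 class scores. Channel width doubles per level from
#' `base_channels`.
#'
#' @param depth Number of encoder levels (>= 2).
#' @param base_channels Channels at the first level.
#' @param lr Adam learning rate.
#' @param epochs Passes over the training set.
#' @param batch_size Images per gradient step (gradients are averaged).
#' @param seed Seed controlling initialisation and shuffling.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(depth = 2L, base_channels = 8L, lr = 5e-3,
                        epochs = 10L, batch_size = 1L, seed = 1L) {
  stopifnot(depth >= 2L, base_channels >= 1L, lr > 0, epochs >= 0L,
            batch_size >= 1L)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "unet_config")
}

# He-uniform initialisation for a 3x3 conv: (9*cin) x cout
.init_conv <- function(cin, cout) {
  lim <- sqrt(6 / (9 * cin))
  list(w = matrix(runif(9 * cin * cout, -lim, lim), 9 * cin, cout),
       b = rep(0, cout))
}

.unet_init <- function(config) {
  d <- config$depth; C <- config$base_channels
  enc <- vector("list", d)
  cin <- 2L  # standardised intensity + normalised depth coordinate
  for (l in seq_len(d)) {
    enc[[l]] <- .init_conv(cin, C * 2^(l - 1))
    cin <- C * 2^(l - 1)
  }
  bott <- .init_conv(C * 2^(d - 1), C * 2^d)
  dec <- vector("list", d)
  for (l in seq_len(d)) {
    dec[[l]] <- .init_conv(C * 2^l + C * 2^(l - 1), C * 2^(l - 1))
  }
  lim <- sqrt(6 / C)
  head <- list(w = matrix(runif(C * N_CLASSES, -lim, lim), C, N_CLASSES),
               b = rep(0, N_CLASSES))
  list(enc = enc, bott = bott, dec = dec, head = head)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.concat_c <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# forward pass; returns logits [H, W, 10] and, if keep, the tape for backprop
.unet_forward <- function(params, x, keep = FALSE) {
  d <- length(params$enc)
  H <- nrow(x); W <- ncol(x)
  if (H %% 2^d != 0 || W %% 2^d != 0) {
    stop("B-scan dimensions must be divisible by 2^depth = ", 2^d,
         call. = FALSE)
  }
  # two input channels: per-image standardised intensity, and the axial
  # depth coordinate in [0, 1] (layers are depth-ordered bands, so an
  # explicit coordinate feature conditions the problem well)
  cur <- array(0, c(H, W, 2L))
  cur[, , 1] <- (x - mean(x)) / (sd(x) + 1e-8)
  cur[, , 2] <- matrix((seq_len(H) - 1) / (H - 1), H, W)
  enc_in <- vector("list", d); enc_pre <- vector("list", d)
  enc_act <- vector("list", d); pool_idx <- vector("list", d)
  for (l in seq_len(d)) {
    enc_in[[l]] <- cur
    pre <- conv3_forward(cur, params$enc[[l]]$w, params$enc[[l]]$b)
    act <- .relu(pre)
    pl <- maxpool2_forward(act)
    enc_pre[[l]] <- pre; enc_act[[l]] <- act; pool_idx[[l]] <- pl$idx
    cur <- pl$y
  }
  bott_in <- cur
  bott_pre <- conv3_forward(cur, params$bott$w, params$bott$b)
  cur <- .relu(bott_pre)
  dec_in <- vector("list", d); dec_pre <- vector("list", d)
  up_ch <- integer(d)
  for (l in rev(seq_len(d))) {
    u <- upsample2_forward(cur)
    up_ch[l] <- dim(u)[3]
    cat_ <- .concat_c(u, enc_act[[l]])
    pre <- conv3_forward(cat_, params$dec[[l]]$w, params$dec[[l]]$b)
    dec_in[[l]] <- cat_; dec_pre[[l]] <- pre
    cur <- .relu(pre)
  }
  featM <- matrix(cur, H * W, dim(cur)[3])
  logits <- featM %*% params$head$w +
    matrix(params$head$b, H * W, N_CLASSES, byrow = TRUE)
  out <- list(logits = array(logits, c(H, W, N_CLASSES)))
  if (keep) {
    out$tape <- list(enc_in = enc_in, enc_pre = enc_pre, enc_act = enc_act,
                     pool_idx = pool_idx, bott_in = bott_in,
                     bott_pre = bott_pre, dec_in = dec_in, dec_pre = dec_pre,
                     feat = cur, up_ch = up_ch, H = H, W = W)
  }
  out
}

# class-weighted softmax cross-entropy and gradient wrt logits;
# labels in 0..9, weights indexed by class + 1
.softmax_ce <- function(logits, labels, weights = rep(1, N_CLASSES)) {
  H <- dim(logits)[1]; W <- dim(logits)[2]
  lm <- matrix(logits, H * W, N_CLASSES)
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  idx <- cbind(seq_len(H * W), as.integer(labels) + 1L)
  wpix <- weights[idx[, 2]]
  wsum <- sum(wpix)
  loss <- -sum(wpix * log(pmax(p[idx], 1e-12))) / wsum
  g <- p
  g[idx] <- g[idx] - 1
  g <- g * (wpix / wsum)
  list(loss = loss, grad = array(g, c(H, W, N_CLASSES)))
}

# inverse-frequency class weights (square-rooted to temper the extremes),
# normalised to mean 1 over observed classes
.class_weights <- function(labels) {
  counts <- rep(0, N_CLASSES)
  tab <- table(factor(unlist(lapply(labels, as.vector)), levels = 0:9))
  counts <- as.numeric(tab)
  w <- ifelse(counts > 0, 1 / sqrt(counts), 0)
  w[w > 0] <- w[w > 0] / mean(w[w > 0])
  w
}

.unet_backward <- function(params, tape, glogits) {
  d <- length(params$enc)
  H <- tape$H; W <- tape$W
  glM <- matrix(glogits, H * W, N_CLASSES)
  featM <- matrix(tape$feat, H * W, dim(tape$feat)[3])
  g <- list(enc = vector("list", d), dec = vector("list", d))
  g$head <- list(w = crossprod(featM, glM), b = colSums(glM))
  gcur <- array(glM %*% t(params$head$w), dim(tape$feat))
  skip_g <- vector("list", d)
  for (l in seq_len(d)) {
    gpre <- gcur * (tape$dec_pre[[l]] > 0)
    bk <- conv3_backward(tape$dec_in[[l]], params$dec[[l]]$w, gpre)
    g$dec[[l]] <- list(w = bk$gw, b = bk$gb)
    nu <- tape$up_ch[l]
    gu <- bk$gx[, , seq_len(nu), drop = FALSE]
    skip_g[[l]] <- bk$gx[, , nu + seq_len(dim(bk$gx)[3] - nu), drop = FALSE]
    gcur <- upsample2_backward(gu)
  }
  gpre <- gcur * (tape$bott_pre > 0)
  bk <- conv3_backward(tape$bott_in, params$bott$w, gpre)
  g$bott <- list(w = bk$gw, b = bk$gb)
  gpool <- bk$gx
  for (l in rev(seq_len(d))) {
    ga <- skip_g[[l]] +
      maxpool2_backward(tape$pool_idx[[l]], gpool,
                        dim(tape$enc_act[[l]])[1], dim(tape$enc_act[[l]])[2])
    gpre <- ga * (tape$enc_pre[[l]] > 0)
    bk <- conv3_backward(tape$enc_in[[l]], params$enc[[l]]$w, gpre)
    g$enc[[l]] <- list(w = bk$gw, b = bk$gb)
    gpool <- bk$gx
  }
  g
}

# flat walk over the parameter tree, applying f(param, grad, state) in place
.map_params <- function(params, grads, state, f) {
  walk <- function(p, g, s, path) {
    if (is.list(p) && !is.null(p$w)) {
      return(f(p, g, s, path))
    }
    out_p <- p
    out_s <- vector("list", length(p))
    names(out_s) <- names(p)
    for (i in seq_along(p)) {
      # grads/state are matched by name when available, else by position
      key <- if (!is.null(names(p)) && nzchar(names(p)[i])) names(p)[i] else i
      r <- walk(p[[i]], g[[key]], if (is.null(s)) NULL else s[[key]],
                c(path, key))
      out_p[[i]] <- r$p
      out_s[[i]] <- r$s
    }
    list(p = out_p, s = out_s)
  }
  walk(params, grads, state, character())
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  .map_params(params, grads, state, function(p, g, s, path) {
    if (is.null(s)) s <- list(mw = p$w * 0, vw = p$w * 0,
                              mb = p$b * 0, vb = p$b * 0)
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    p$w <- p$w - lr * (s$mw / corr1) / (sqrt(s$vw / corr2) + eps)
    p$b <- p$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    list(p = p, s = s)
  })
}

#' Train the segmentation network
#'
#' Trains the encoder-decoder on labelled B-scans with per-pixel softmax
#' cross-entropy and Adam. Training is deterministic given
#' `config$seed`. A warning (not an error) is raised when some of the 10
#' classes never occur in the labels.
#'
#' @param bscans List of `n_samples x n_ascans` intensity matrices (depth
#'   as rows), all the same shape, divisible by `2^depth` in both
#'   dimensions.
#' @param labels List of matching integer label matrices with values 0..9.
#' @param config A [unet_config()].
#' @return An object of class `oct_segmenter`: trained parameters, the
#'   config, and a tibble `loss` with the per-step training loss
#'   trajectory.
#' @export
train_segmenter <- function(bscans, labels, config = unet_config()) {
  stopifnot(length(bscans) == length(labels), length(bscans) >= 8L)
  seen <- sort(unique(unlist(lapply(labels, unique))))
  if (any(!seen %in% 0:9)) stop("labels must be integers in 0..9", call. = FALSE)
  if (length(setdiff(0:9, seen)) > 0L) {
    warning("classes absent from training labels: ",
            paste(setdiff(0:9, seen), collapse = ", "), call. = FALSE)
  }
  .with_seed(config$seed, {
    params <- .unet_init(config)
    cw <- .class_weights(labels)
    state <- NULL
    t <- 0L
    steps <- list()
    if (config$epochs > 0L) {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(length(bscans))
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        for (bt in batches) {
          acc <- NULL
          loss_b <- 0
          for (i in bt) {
            fw <- .unet_forward(params, bscans[[i]], keep = TRUE)
            l <- .softmax_ce(fw$logits, labels[[i]], cw)
            gr <- .unet_backward(params, fw$tape, l$grad)
            loss_b <- loss_b + l$loss
            acc <- if (is.null(acc)) gr else .add_grads(acc, gr)
          }
          if (length(bt) > 1L) acc <- .scale_grads(acc, 1 / length(bt))
          t <- t + 1L
          upd <- .adam_step(params, acc, state, config$lr, t)
          params <- upd$p; state <- upd$s
          steps[[t]] <- loss_b / length(bt)
        }
      }
    }
    structure(
      list(params = params, config = config,
           loss = tibble::tibble(step = seq_along(steps),
                                 loss = as.numeric(unlist(steps)))),
      class = "oct_segmenter"
    )
  })
}

.add_grads <- function(a, b) {
  .map_params(a, b, NULL, function(p, g, s, path) {
    list(p = list(w = p$w + g$w, b = p$b + g$b), s = NULL)
  })$p
}

.scale_grads <- function(a, k) {
  .map_params(a, a, NULL, function(p, g, s, path) {
    list(p = list(w = p$w * k, b = p$b * k), s = NULL)
  })$p
}

#' @export
print.oct_segmenter <- function(x, ...) {
  cat(sprintf("<oct_segmenter> depth %d, base channels %d, %d training steps\n",
              x$config$depth, x$config$base_channels, nrow(x$loss)))
  invisible(x)
}

#' Segment a volume into a class map
#'
#' Runs the trained network on every B-scan and stacks the per-sample
#' argmax labels into a volumetric class map. Inference is deterministic.
#'
#' @param model An [train_segmenter()] result.
#' @param volume An [oct_volume()] whose A-scan and sample counts are
#'   divisible by `2^depth`.
#' @return A `class_map`: list with `labels` (`[n_bscans, n_ascans,
#'   n_samples]`, values 0..9), `n_classes`, and the volume `meta`.
#' @export
segment_volume <- function(model, volume) {
  stopifnot(inherits(model, "oct_segmenter"), inherits(volume, "oct_volume"))
  d <- dim(volume$intensities)
  lab <- array(0L, d)
  for (b in seq_len(d[1])) {
    x <- t(matrix(volume$intensities[b, , ], d[2], d[3]))  # samples x ascans
    fw <- .unet_forward(model$params, x)
    lm <- matrix(fw$logits, length(x), N_CLASSES)
    page <- max.col(lm, ties.method = "first") - 1L       # argmax class
    lab[b, , ] <- t(matrix(page, nrow(x), ncol(x)))
  }
  structure(list(labels = lab, n_classes = N_CLASSES, meta = volume$meta),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<class_map> %d x %d x %d, %d classes\n",
              d[1], d[2], d[3], x$n_classes))
  invisible(x)
}

#' Class map from ground-truth boundaries
#'
#' The ideal per-sample labelling induced by known boundaries: sample `s`
#' (0-based) of an A-scan gets class `k` iff `b_k <= s < b_{k+1}`, class 0
#' above the first boundary and class 9 at or below the last. Lets the
#' thickness and normative stages be exercised independently of network
#' quality.
#'
#' @param truth A `ground_truth` from [generate_phantom()].
#' @return A `class_map`.
#' @export
oracle_classmap <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  bnd <- truth$boundaries
  d <- dim(bnd)
  ns <- truth$scale$n_samples
  lab <- array(0L, c(d[1], d[2], ns))
  svals <- matrix(0:(ns - 1), d[2], ns, byrow = TRUE)
  for (b in seq_len(d[1])) {
    page <- matrix(0L, d[2], ns)
    for (k in 1:9) page <- page + (svals >= bnd[b, , k])
    lab[b, , ] <- page
  }
  structure(list(labels = lab, n_classes = N_CLASSES, meta = truth$meta),
            class = "class_map")
}

#' Project a class map onto monotone boundary surfaces
#'
#' For each A-scan independently, finds integer cut positions
#' `0 <= c_0 <= ... <= c_8 <= n_samples` maximising the number of samples
#' whose class agrees with the monotone labelling the cuts induce, by
#' dynamic programming in `O(n_samples x classes)`. Ties are broken by the
#' lexicographically smallest cut vector, so the result is deterministic
#' and never contains crossing boundaries. Equal adjacent cuts encode a
#' locally absent layer.
#'
#' @param classmap A `class_map` (from [segment_volume()] or
#'   [oracle_classmap()]).
#' @return A `boundary_set`: list with `boundaries`
#'   (`[n_bscans, n_ascans, 9]` axial sample positions), a logical `valid`
#'   matrix (all `TRUE` here), `n_samples`, and `meta`.
#' @export
boundaries_from_classmap <- function(classmap) {
  stopifnot(inherits(classmap, "class_map"))
  d <- dim(classmap$labels)
  bnd <- array(0, c(d[1], d[2], N_CLASSES - 1L))
  for (b in seq_len(d[1])) {
    page <- matrix(as.integer(classmap$labels[b, , ]), d[2], d[3])
    bnd[b, , ] <- dp_cuts_labels(page, N_CLASSES)
  }
  structure(list(boundaries = bnd,
                 valid = matrix(TRUE, d[1], d[2]),
                 n_samples = d[3], meta = classmap$meta),
            class = "boundary_set")
}

#' Boundary set from ground truth
#'
#' Wraps the real-valued ground-truth boundary surfaces as a
#' `boundary_set`, bypassing segmentation entirely.
#'
#' @param truth A `ground_truth`.
#' @return A `boundary_set`.
#' @export
as_boundary_set <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- dim(truth$boundaries)
  structure(list(boundaries = truth$boundaries,
                 valid = matrix(TRUE, d[1], d[2]),
                 n_samples = truth$scale$n_samples, meta = truth$meta),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  d <- dim(x$boundaries)
  cat(sprintf("<boundary_set> %d x %d en-face grid, 9 surfaces, %d/%d valid\n",
              d[1], d[2], sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Monotone cut projection of one A-scan
#'
#' Low-level access to the dynamic program: given a per-sample score
#' matrix (rows = axial samples, columns = classes), returns the
#' lexicographically smallest score-maximising monotone cut vector. Hard
#' labels correspond to a one-hot score matrix.
#'
#' @param scores `n_samples x n_classes` numeric matrix of per-class
#'   rewards (finite).
#' @return Integer vector of `n_classes - 1` cut positions in
#'   `0..n_samples`.
#' @examples
#' dp_project(diag(4)[c(1, 1, 2, 3), ])
#' @export
dp_project <- function(scores) {
  stopifnot(is.matrix(scores), all(is.finite(scores)), ncol(scores) >= 2L)
  as.integer(dp_cuts_scores(scores))
}

#' Mean per-class Dice overlap
#'
#' Dice coefficient between predicted and reference label volumes,
#' averaged over the requested classes (by default the eight retinal
#' layers, i.e. foreground). Classes absent from both volumes are skipped.
#'
#' @param pred,ref `class_map`s or integer label arrays of equal shape.
#' @param classes Classes to average over.
#' @return Mean Dice in `[0, 1]`.
#' @export
dice_score <- function(pred, ref, classes = 1:8) {
  p <- if (inherits(pred, "class_map")) pred$labels else pred
  r <- if (inherits(ref, "class_map")) ref$labels else ref
  stopifnot(identical(dim(p), dim(r)))
  per <- vapply(classes, function(k) {
    np <- sum(p == k); nr <- sum(r == k)
    if (np + nr == 0L) return(NA_real_)
    2 * sum(p == k & r == k) / (np + nr)
  }, numeric(1))
  mean(per, na.rm = TRUE)
}
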