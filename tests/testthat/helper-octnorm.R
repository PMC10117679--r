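# Shared fixtures and independent oracles, all built in code.

# Exhaustive monotone-cut search: enumerates every cut vector
# 0 <= c_0 <= ... <= c_{K-2} <= n, scores the induced labelling, and
# returns the maximal objective with the lexicographically smallest
# maximiser. Independent of the dynamic program it checks.
brute_force_cuts <- function(scores) {
  n <- nrow(scores)
  K <- ncol(scores)
  prefix <- apply(scores, 2, function(v) cumsum(c(0, v)))  # (n+1) x K
  best <- -Inf
  best_cuts <- NULL
  recurse <- function(cuts, lo) {
    if (length(cuts) == K - 1) {
      bounds <- c(0, cuts, n)
      obj <- 0
      for (k in seq_len(K)) {
        obj <- obj + prefix[bounds[k + 1] + 1, k] - prefix[bounds[k] + 1, k]
      }
      if (obj > best || (obj == best && is.null(best_cuts))) {
        best <<- obj
        best_cuts <<- cuts
      }
      return(invisible())
    }
    for (j in lo:n) recurse(c(cuts, j), j)
  }
  recurse(integer(), 0)
  list(objective = best, cuts = best_cuts)
}

# objective value of a cut vector under a score matrix
cuts_objective <- function(scores, cuts) {
  n <- nrow(scores)
  K <- ncol(scores)
  bounds <- c(0, cuts, n)
  obj <- 0
  for (k in seq_len(K)) {
    if (bounds[k + 1] > bounds[k]) {
      obj <- obj + sum(scores[(bounds[k] + 1):bounds[k + 1], k])
    }
  }
  obj
}

# hand-built flat ground truth: constant boundaries at `levels` (axial
# samples) over an nb x na grid
flat_truth <- function(levels, nb = 4, na_ = 20, n_samples = 256,
                       eye = "OD", scale = axial_scale(1.4 * n_samples / 1024,
                                                       n_samples)) {
  stopifnot(length(levels) == 9)
  bnd <- array(rep(levels, each = nb * na_), c(nb, na_, 9))
  th <- array(0, c(nb, na_, 8))
  for (k in 1:8) th[, , k] <- (levels[k + 1] - levels[k]) *
      scale$microns_per_sample
  structure(
    list(boundaries = bnd, layer_thickness_um = th,
         meta = list(eye = eye, age_months = 1L, group = "WT",
                     animal_id = "T1"),
         scale = scale),
    class = "ground_truth"
  )
}

# small rendered phantom shared by several tests
small_phantom <- function(dims = c(6, 32, 256), noise = "none", seed = 42,
                          eye = "OD", ...) {
  generate_phantom(phantom_spec(), eye = eye, dims = dims, noise = noise,
                   seed = seed, ...)
}

# thickness map with every field under direct control
manual_map <- function(values, valid = NULL, eye = "OD") {
  d <- dim(values)[1:2]
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  structure(list(thickness = values, valid = valid,
                 meta = list(eye = eye, age_months = 1L, group = "WT",
                             animal_id = "M1"),
                 scale = axial_scale()),
            class = "thickness_map")
}

# constant-thickness 9-slab map (8 layers + consistent TRT)
constant_map <- function(n = 35, value = 20, eye = "OD") {
  th <- array(value, c(n, n, 9))
  th[, , 9] <- 8 * value
  manual_map(th, eye = eye)
}
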