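# Boundary surfaces -> per-layer thickness maps in micrometres, three
# quality-control criteria with A-scan exclusion, left-eye mirroring, and
# the central-crop 3x3 ROI block machinery (B1-B9).

#' Per-layer thickness maps from boundary surfaces
#'
#' Layer `k` thickness is `(b_{k+1} - b_k) * microns_per_sample`; total
#' retinal thickness (TRT) is `(b_8 - b_0) * microns_per_sample`, the
#' distance from the vitreous-RNFL interface to the RPE-choroid interface,
#' so TRT equals the sum of the eight layer fields exactly. A-scans whose
#' boundaries cross (negative separation) are marked invalid and carry no
#' thickness values.
#'
#' @param boundaries A `boundary_set`.
#' @param scale An [axial_scale()].
#' @return A `thickness_map`: list with `thickness`
#'   (`[n_bscans, n_ascans, 9]`, layers 1..8 then TRT, um), logical
#'   `valid`, `meta`, `scale`.
#' @export
compute_thickness <- function(boundaries, scale = axial_scale()) {
  stopifnot(inherits(boundaries, "boundary_set"))
  bnd <- boundaries$boundaries
  d <- dim(bnd)
  mps <- scale$microns_per_sample
  th <- array(NA_real_, c(d[1], d[2], 9L))
  sep <- bnd[, , 2:9, drop = FALSE] - bnd[, , 1:8, drop = FALSE]
  crossing <- apply(sep < 0, c(1, 2), any)
  valid <- boundaries$valid & !crossing
  for (k in 1:8) th[, , k] <- sep[, , k] * mps
  th[, , 9] <- (bnd[, , 9] - bnd[, , 1]) * mps
  # blank invalid A-scans across all layers
  for (k in 1:9) {
    page <- th[, , k]
    page[!valid] <- NA_real_
    th[, , k] <- page
  }
  structure(list(thickness = th, valid = valid,
                 meta = boundaries$meta, scale = scale),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  d <- dim(x$thickness)
  cat(sprintf("<thickness_map> %d x %d en-face grid, 8 layers + TRT, %d/%d valid\n",
              d[1], d[2], sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Quality-control parameters
#'
#' Defaults for the three A-scan exclusion criteria: boundary contrast
#' window `w` (samples) and minimum Michelson-style contrast `c`;
#' maximum boundary jump `J` (samples) against the four neighbouring
#' A-scans; and robust z-score cap `z_star` on each layer's thickness
#' against the volume-wide median/MAD. The block exclusion fraction is the
#' strict threshold above which a whole ROI block is discarded.
#'
#' @param w Half-window, samples, for the contrast criterion.
#' @param c_min Minimum contrast.
#' @param J Maximum neighbour boundary jump, samples.
#' @param z_star Robust z cap for the thickness-distribution criterion.
#' @param block_exclusion_frac Strict block discard threshold.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(w = 3L, c_min = 0.05, J = 15, z_star = 4,
                      block_exclusion_frac = 0.10) {
  stopifnot(w >= 1L, c_min > 0, J > 0, z_star > 0,
            block_exclusion_frac > 0, block_exclusion_frac < 1)
  structure(list(w = as.integer(w), c_min = c_min, J = J, z_star = z_star,
                 block_exclusion_frac = block_exclusion_frac),
            class = "qc_params")
}

# mean intensity over a w-sample window on one side of each boundary
.window_mean <- function(vol, bidx, offsets) {
  d <- dim(vol)
  nb <- d[1]; na_ <- d[2]; ns <- d[3]
  rows <- rep(seq_len(nb), na_)
  cols <- rep(seq_len(na_), each = nb)
  acc <- matrix(0, nb, na_)
  for (o in offsets) {
    s <- pmin(pmax(as.vector(bidx) + o, 1L), ns)
    acc <- acc + matrix(vol[cbind(rows, cols, s)], nb, na_)
  }
  acc / length(offsets)
}

#' A-scan quality control
#'
#' Applies the three exclusion criteria to every A-scan of a volume:
#'
#' * **contrast** — for each boundary, the Michelson-style contrast
#'   `|I_below - I_above| / (I_below + I_above + eps)` between `w`-sample
#'   windows on either side must reach `c_min`; a constant (corrupted)
#'   A-scan has zero contrast everywhere and always fails;
#' * **consistency** — no boundary may jump more than `J` samples
#'   relative to the four neighbouring A-scans;
#' * **distribution** — each layer's thickness must lie within `z_star`
#'   robust z-scores (median/MAD, volume-wide) of that layer's
#'   distribution.
#'
#' Failure of any criterion excludes the A-scan.
#'
#' @param volume The [oct_volume()] the boundaries came from.
#' @param boundaries The matching `boundary_set`.
#' @param thickness The matching `thickness_map`.
#' @param params A [qc_params()].
#' @return A `qc_report`: logical pass matrices per criterion and the
#'   combined `valid` matrix.
#' @export
qc_ascan <- function(volume, boundaries, thickness, params = qc_params()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(boundaries, "boundary_set"),
            inherits(thickness, "thickness_map"), inherits(params, "qc_params"))
  vol <- volume$intensities
  bnd <- boundaries$boundaries
  d <- dim(bnd)
  if (!any(thickness$valid)) stop("no valid A-scans to QC", call. = FALSE)
  eps <- 1e-9
  pass_contrast <- matrix(TRUE, d[1], d[2])
  for (k in 1:9) {
    bi <- floor(bnd[, , k])
    above <- .window_mean(vol, bi, -(params$w:1) + 1L) # samples b-w .. b-1
    below <- .window_mean(vol, bi, 1:params$w)         # samples b .. b+w-1
    contrast <- abs(below - above) / (below + above + eps)
    pass_contrast <- pass_contrast & (contrast >= params$c_min)
  }
  pass_consistency <- matrix(TRUE, d[1], d[2])
  for (k in 1:9) {
    B <- bnd[, , k]
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- d[1]; na_ <- d[2]
      ri <- seq_len(nb) + sh[1]; ci <- seq_len(na_) + sh[2]
      ok_r <- ri >= 1 & ri <= nb; ok_c <- ci >= 1 & ci <= na_
      diffm <- matrix(0, nb, na_)
      diffm[ok_r, ok_c] <- abs(B[ok_r, ok_c] - B[ri[ok_r], ci[ok_c]])
      pass_consistency <- pass_consistency & (diffm <= params$J)
    }
  }
  pass_distribution <- matrix(TRUE, d[1], d[2])
  # the MAD is floored at one axial sample: boundary cuts are integer, so
  # sub-sample quantisation must not masquerade as thickness outliers
  mad_floor <- thickness$scale$microns_per_sample
  for (k in 1:8) {
    t_k <- thickness$thickness[, , k]
    vals <- t_k[thickness$valid]
    med <- median(vals, na.rm = TRUE)
    md <- max(mad(vals, na.rm = TRUE), mad_floor)  # mad() scales by 1.4826
    z <- abs(t_k - med) / md
    z[is.na(z)] <- Inf
    pass_distribution <- pass_distribution & (z <= params$z_star)
  }
  valid <- thickness$valid & pass_contrast & pass_consistency & pass_distribution
  structure(list(pass_contrast = pass_contrast,
                 pass_consistency = pass_consistency,
                 pass_distribution = pass_distribution,
                 valid = valid, params = params),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n <- length(x$valid)
  cat(sprintf(
    "<qc_report> %d A-scans: contrast %d fail, consistency %d fail, distribution %d fail -> %d excluded\n",
    n, sum(!x$pass_contrast), sum(!x$pass_consistency),
    sum(!x$pass_distribution), sum(!x$valid)))
  invisible(x)
}

#' Apply a QC report to a thickness map
#'
#' Marks QC-failed A-scans invalid and blanks their thickness values.
#'
#' @param map A `thickness_map`.
#' @param report A [qc_ascan()] report.
#' @return The filtered `thickness_map`.
#' @export
apply_qc <- function(map, report) {
  stopifnot(inherits(map, "thickness_map"), inherits(report, "qc_report"))
  map$valid <- map$valid & report$valid
  for (k in 1:9) {
    page <- map$thickness[, , k]
    page[!map$valid] <- NA_real_
    map$thickness[, , k] <- page
  }
  map
}

#' Mirror left-eye maps
#'
#' Reverses the A-scan (column) axis of left-eye (`OS`) thickness maps so
#' that the left half of every map is temporal, making left and right eyes
#' directly comparable. Right-eye (`OD`) maps pass through unchanged. The
#' operation is an involution on OS maps.
#'
#' @param map A `thickness_map` with `meta$eye` set.
#' @return The (possibly mirrored) `thickness_map`.
#' @export
mirror_if_left <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  eye <- map$meta$eye
  if (is.null(eye) || is.na(eye)) stop("missing eye metadata", call. = FALSE)
  if (eye == "OD") return(map)
  flip <- rev(seq_len(dim(map$thickness)[2]))
  map$thickness <- map$thickness[, flip, , drop = FALSE]
  map$valid <- map$valid[, flip, drop = FALSE]
  map
}

.block_id <- function(r, c) paste0("B", (r - 1) * 3 + c)

#' Central crop and 3x3 ROI block summaries
#'
#' Drops the one-pixel frame (rows/columns 1 and `n`), partitions the
#' cropped grid into 3x3 equal non-overlapping blocks — `B1` top-left
#' (superior-temporal, after mirroring) through `B9` bottom-right, row
#' major — and summarises each layer per block over the retained (valid)
#' A-scans. A block is discarded entirely when strictly more than
#' `block_exclusion_frac` of its A-scans are excluded (tested on integer
#' counts, so a block at exactly the threshold is retained). A whole-area
#' summary over all retained A-scans of the cropped grid is appended as
#' region `"whole"`. For the default 512 x 512 grid the blocks are the
#' standard 170 x 170-point ROIs.
#'
#' @param map A `thickness_map` (typically QC-filtered and mirrored).
#' @param params A [qc_params()] (for the block exclusion fraction).
#' @return A tibble with one row per region x layer: `region`, `layer`,
#'   `mean_um`, `sd_um`, `n_ascans`, `n_excluded`, `excluded_frac`,
#'   `retained`, plus the map's metadata columns.
#' @export
crop_and_block <- function(map, params = qc_params()) {
  stopifnot(inherits(map, "thickness_map"))
  d <- dim(map$thickness)
  if (d[1] != d[2]) stop("en-face grid must be square", call. = FALSE)
  side <- d[1] - 2L
  if (side %% 3L != 0L) {
    stop("grid minus the 1-pixel frame must be divisible into 3x3 blocks; ",
         "got ", d[1], call. = FALSE)
  }
  bs <- side %/% 3L
  keep <- 2:(d[1] - 1L)
  th <- map$thickness[keep, keep, , drop = FALSE]
  valid <- map$valid[keep, keep, drop = FALSE]
  frac_num <- params$block_exclusion_frac
  summarise_region <- function(rows, cols, region, force_retain = FALSE) {
    v <- valid[rows, cols]
    n_tot <- length(v)
    n_exc <- sum(!v)
    # strict "> frac" on integer counts (robust to 0.1 not being binary-exact)
    retained <- force_retain || !(n_exc > frac_num * n_tot + 1e-9 * n_tot)
    purrr::map_dfr(1:9, function(k) {
      vals <- th[rows, cols, k][v]
      tibble::tibble(
        region = region, layer = LAYERS_TRT[k],
        mean_um = if (retained && length(vals)) mean(vals) else NA_real_,
        sd_um = if (retained && length(vals) > 1) sd(vals) else
          if (retained && length(vals) == 1) 0 else NA_real_,
        n_ascans = sum(v), n_excluded = n_exc,
        excluded_frac = n_exc / n_tot, retained = retained
      )
    })
  }
  out <- list()
  for (r in 1:3) {
    for (cc in 1:3) {
      rows <- ((r - 1) * bs + 1):(r * bs)
      cols <- ((cc - 1) * bs + 1):(cc * bs)
      out[[length(out) + 1L]] <- summarise_region(rows, cols, .block_id(r, cc))
    }
  }
  out[[length(out) + 1L]] <-
    summarise_region(seq_len(side), seq_len(side), "whole", force_retain = TRUE)
  res <- dplyr::bind_rows(out)
  meta <- map$meta
  tibble::add_column(res,
                     group = meta$group %||% NA_character_,
                     animal_id = meta$animal_id %||% NA_character_,
                     eye = meta$eye %||% NA_character_,
                     age_months = meta$age_months %||% NA_integer_,
                     .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
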