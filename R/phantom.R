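# Synthetic layered-retina phantoms with known ground-truth boundaries.
#
# The phantom is the package's test bed: an 8-layer retina whose per-layer
# thickness follows the bundled normative age trends, with a linear
# superior->inferior thickness gradient (the imaged area sits directly above
# the optic disc, which lies inferior), a temporal-nasal asymmetry
# (temporal thicker), per-animal random offsets, multiplicative gamma
# speckle, and optional corrupted A-scans for exercising quality control.

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Defines the geometry, optics and population variability of a synthetic
#' retinal phantom. Per-layer thickness trends over age follow the bundled
#' normative table for `group` (piecewise-linear through its seven ages,
#' constant beyond the endpoints). The superior-inferior gradient and
#' temporal-nasal asymmetry amplitudes are total-retina amplitudes split
#' across layers proportionally to their base thickness; both spatial terms
#' are centred so that the grid-mean thickness of every layer equals its
#' age-trend value. Between-animal variability is one additive Gaussian
#' offset per (animal, layer) whose SD is the per-layer mean of the
#' normative SD columns for `group`.
#'
#' @param group `"WT"` or `"3xTg-AD"`; selects age trends and SDs.
#' @param gradient_trt_um Total-retina superior->inferior gradient amplitude
#'   (um); inferior (high row index) is thicker.
#' @param asymmetry_trt_um Total-retina temporal-nasal asymmetry amplitude
#'   (um); temporal (low column index, right eye convention) is thicker.
#' @param reflectivity Mean reflectivities in `(0, 1]` for the 10 rendered
#'   classes: vitreous, the 8 layers inner to outer, sub-RPE. The default
#'   alternates bright and dark bands (bright RNFL, dark nuclear layers,
#'   bright plexiform/RPE), the contrast pattern that makes retinal layers
#'   visible in OCT; under default speckle it keeps the boundary-contrast
#'   QC failure rate of clean scans below one percent.
#' @param contrast_margin Minimum reflectivity difference required between
#'   axially adjacent classes.
#' @param speckle_shape Shape parameter of the unit-mean multiplicative
#'   gamma speckle; larger is cleaner. `Inf` disables speckle.
#' @param jitter_um SD of white per-A-scan thickness jitter (um, per layer).
#' @param between_sd_um Optional length-8 override of the per-layer
#'   between-animal SD (um).
#' @param thickness_offset_um Optional length-8 per-layer additive offset
#'   (um) applied on top of the age trend, e.g. to build an artificial
#'   group effect.
#' @return An object of class `phantom_spec`.
#' @examples
#' sp <- phantom_spec("WT")
#' sp$base_um
#' @export
phantom_spec <- function(group = "WT",
                         gradient_trt_um = 8,
                         asymmetry_trt_um = 4,
                         reflectivity = c(0.05, 0.90, 0.40, 0.15, 0.50,
                                          0.12, 0.55, 0.20, 0.95, 0.10),
                         contrast_margin = 0.1,
                         speckle_shape = 9,
                         jitter_um = 0.3,
                         between_sd_um = NULL,
                         thickness_offset_um = NULL) {
  ref <- reference_thickness(group = group)
  layer_ref <- dplyr::filter(ref, .data$layer != "TRT")
  base <- dplyr::filter(layer_ref, .data$age_months == 1L)
  base_um <- setNames(base$mean_um, base$layer)[LAYERS]
  if (is.null(between_sd_um)) {
    bsd <- layer_ref |>
      dplyr::group_by(.data$layer) |>
      dplyr::summarise(sd_um = mean(.data$sd_um), .groups = "drop")
    between_sd_um <- setNames(bsd$sd_um, bsd$layer)[LAYERS]
  }
  stopifnot(
    length(reflectivity) == 10L, all(reflectivity > 0), all(reflectivity <= 1),
    all(base_um > 0), gradient_trt_um >= 0, asymmetry_trt_um >= 0,
    speckle_shape > 0, jitter_um >= 0, length(between_sd_um) == 8L
  )
  if (any(abs(diff(reflectivity)) < contrast_margin)) {
    stop("adjacent reflectivities must differ by at least `contrast_margin`",
         call. = FALSE)
  }
  if (is.null(thickness_offset_um)) thickness_offset_um <- rep(0, 8L)
  stopifnot(length(thickness_offset_um) == 8L)
  share <- base_um / sum(base_um)
  trends <- lapply(LAYERS, function(ly) {
    d <- dplyr::filter(layer_ref, .data$layer == ly)
    list(x = d$age_months, y = d$mean_um)
  })
  names(trends) <- LAYERS
  structure(
    list(
      group = group,
      base_um = base_um,
      trends = trends,
      gradient_um = gradient_trt_um * share,
      asymmetry_um = asymmetry_trt_um * share,
      reflectivity = reflectivity,
      contrast_margin = contrast_margin,
      speckle_shape = speckle_shape,
      jitter_um = jitter_um,
      between_sd_um = setNames(as.numeric(between_sd_um), LAYERS),
      thickness_offset_um = setNames(as.numeric(thickness_offset_um), LAYERS)
    ),
    class = "phantom_spec"
  )
}

# piecewise-linear age trend, constant outside the tabulated range
.base_at_age <- function(spec, layer_idx, age_months) {
  tr <- spec$trends[[layer_idx]]
  approx(tr$x, tr$y, xout = age_months, rule = 2)$y +
    spec$thickness_offset_um[layer_idx]
}

#' Noise-free thickness field of one layer
#'
#' The deterministic thickness (um) of layer `layer` at en-face position
#' (`row`, `col`) for an animal with additive offset `animal_effect`:
#' `base(age) + gradient * (row/(nrow-1) - 1/2) + asymmetry * (1/2 -
#' col/(ncol-1)) + animal_effect`, floored at 1 um. Row 0 is superior,
#' column 0 temporal (right-eye convention). Both spatial terms are
#' mean-zero over the grid, so the grid average equals `base(age) +
#' animal_effect`.
#'
#' @param spec A [phantom_spec()].
#' @param layer Layer index 1..8 (inner to outer).
#' @param age_months Age in months.
#' @param row,col 0-based en-face coordinates (vectors recycle).
#' @param animal_effect Additive per-animal offset (um).
#' @param grid En-face grid size `c(n_rows, n_cols)`.
#' @return Thickness in um.
#' @examples
#' thickness_field(phantom_spec(), 1, 1, row = 0, col = 0)
#' @export
thickness_field <- function(spec, layer, age_months, row, col,
                            animal_effect = 0, grid = c(512L, 512L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(layer) != 1L || !layer %in% 1:8) {
    stop("`layer` must be a single index in 1..8", call. = FALSE)
  }
  base <- .base_at_age(spec, layer, age_months)
  t_um <- base +
    spec$gradient_um[layer] * (row / (grid[1] - 1) - 0.5) +
    spec$asymmetry_um[layer] * (0.5 - col / (grid[2] - 1)) +
    animal_effect
  pmax(t_um, 1)
}

# all eight layer fields as an [n_rows, n_cols, 8] array (0-based rows/cols)
.thickness_fields <- function(spec, age_months, grid, animal_effect,
                              jitter_um = spec$jitter_um) {
  nr <- grid[1]; nc <- grid[2]
  rowf <- matrix(seq_len(nr) - 1L, nr, nc) / (nr - 1)
  colf <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE) / (nc - 1)
  th <- array(0, c(nr, nc, 8L))
  for (k in 1:8) {
    t_um <- .base_at_age(spec, k, age_months) +
      spec$gradient_um[k] * (rowf - 0.5) +
      spec$asymmetry_um[k] * (0.5 - colf) +
      animal_effect[k]
    if (jitter_um > 0) t_um <- t_um + rnorm(nr * nc, 0, jitter_um)
    th[, , k] <- pmax(t_um, 1)
  }
  th
}

#' Generate a phantom OCT volume with ground truth
#'
#' Renders an 8-layer retina into an intensity volume. Each axial sample is
#' assigned the reflectivity of the structure it falls in (vitreous above
#' the first boundary, sub-RPE at and below the last) and multiplied by
#' unit-mean gamma speckle. Left eyes (`eye = "OS"`) are rendered mirrored
#' along the A-scan axis, so their temporal side lies on the right and the
#' left-eye mirroring rule of the thickness stage applies meaningfully.
#'
#' @param spec A [phantom_spec()].
#' @param eye,age_months,group,animal_id Volume metadata.
#' @param dims Volume dimensions `c(n_bscans, n_ascans, n_samples)`.
#' @param animal_effect Length-8 per-layer additive offset (um), typically
#'   drawn once per animal by [simulate_cohort()].
#' @param noise `"speckle"` or `"none"` (also disables thickness jitter).
#' @param top_margin_frac Fraction of the axial range above the first
#'   boundary (vitreous).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param render If `FALSE`, skip intensity rendering (`volume` is `NULL`);
#'   the ground truth is still produced.
#' @param scale An [axial_scale()]; defaults to the acquisition sampling
#'   density (1.3672 um/sample) regardless of `dims[3]`.
#' @return A list with elements `volume` ([oct_volume()]) and `truth`
#'   (class `ground_truth`: `boundaries` `[n_bscans, n_ascans, 9]` in axial
#'   samples, `layer_thickness_um` `[n_bscans, n_ascans, 8]`, plus `meta`
#'   and `scale`).
#' @examples
#' ph <- generate_phantom(phantom_spec(), dims = c(4, 32, 128), seed = 1)
#' dim(ph$truth$boundaries)
#' @export
generate_phantom <- function(spec, eye = "OD", age_months = 1,
                             group = spec$group, animal_id = "A1",
                             dims = c(512L, 512L, 1024L),
                             animal_effect = rep(0, 8L),
                             noise = c("speckle", "none"),
                             top_margin_frac = 0.25,
                             seed = NULL, render = TRUE,
                             scale = axial_scale(1.4 * dims[3] / 1024, dims[3])) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "phantom_spec"), length(dims) == 3L,
            length(animal_effect) == 8L)
  .with_seed(seed, {
    nb <- dims[1]; na_ <- dims[2]; ns <- dims[3]
    jit <- if (noise == "none") 0 else spec$jitter_um
    th <- .thickness_fields(spec, age_months, c(nb, na_), animal_effect, jit)
    mps <- scale$microns_per_sample
    b0 <- top_margin_frac * ns
    bnd <- array(0, c(nb, na_, 9L))
    bnd[, , 1] <- b0
    for (k in 1:8) bnd[, , k + 1] <- bnd[, , k] + th[, , k] / mps
    if (max(bnd[, , 9]) > ns) {
      stop("total thickness exceeds the imaging depth; increase `dims[3]` ",
           "or reduce `top_margin_frac`", call. = FALSE)
    }
    intens <- NULL
    if (render) {
      intens <- array(0, c(nb, na_, ns))
      svals <- matrix(0:(ns - 1), na_, ns, byrow = TRUE)
      for (b in seq_len(nb)) {
        lab <- matrix(0L, na_, ns)
        for (k in 1:9) lab <- lab + (svals >= bnd[b, , k])
        page <- matrix(spec$reflectivity[lab + 1L], na_, ns)
        intens[b, , ] <- page
      }
      if (noise == "speckle" && is.finite(spec$speckle_shape)) {
        sh <- spec$speckle_shape
        intens <- intens * array(rgamma(length(intens), shape = sh, rate = sh),
                                 dim(intens))
      }
    }
    if (identical(eye, "OS")) {
      flip <- rev(seq_len(na_))
      if (render) intens <- intens[, flip, , drop = FALSE]
      bnd <- bnd[, flip, , drop = FALSE]
      th <- th[, flip, , drop = FALSE]
    }
    truth <- structure(
      list(boundaries = bnd, layer_thickness_um = th,
           meta = list(eye = eye, age_months = age_months, group = group,
                       animal_id = as.character(animal_id)),
           scale = scale),
      class = "ground_truth"
    )
    vol <- if (render) {
      oct_volume(intens, eye = eye, age_months = age_months,
                 group = group, animal_id = animal_id)
    }
    list(volume = vol, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$boundaries)
  cat(sprintf("<ground_truth> %d x %d en-face grid, 9 boundary surfaces\n",
              d[1], d[2]))
  invisible(x)
}

#' Corrupt a fraction of A-scans
#'
#' Degrades randomly chosen A-scans so downstream quality control has
#' failures to catch. `"low_contrast"` replaces each selected depth profile
#' with its own mean (zero boundary contrast); `"dropout"` zeroes it.
#'
#' @param volume An [oct_volume()].
#' @param fraction Fraction of A-scans to corrupt, in `[0, 1)`. When
#'   `region` is given, the fraction applies to the region's A-scans.
#' @param mode `"low_contrast"` or `"dropout"`.
#' @param region Optional `list(rows =, cols =)` of 1-based index ranges to
#'   restrict corruption to (e.g. one ROI block).
#' @param seed Integer seed.
#' @return A list with `volume` (corrupted copy) and `corrupted`, a tibble
#'   of 1-based `(row, col)` en-face positions that were degraded.
#' @export
corrupt_volume <- function(volume, fraction, mode = c("low_contrast", "dropout"),
                           region = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "oct_volume"), fraction >= 0, fraction < 1)
  d <- dim(volume$intensities)
  rows <- if (is.null(region)) seq_len(d[1]) else region$rows
  cols <- if (is.null(region)) seq_len(d[2]) else region$cols
  grid <- expand.grid(row = rows, col = cols)
  n_pick <- round(fraction * nrow(grid))
  if (n_pick == 0L) {
    return(list(volume = volume,
                corrupted = tibble::tibble(row = integer(), col = integer())))
  }
  .with_seed(seed, {
    pick <- grid[sample.int(nrow(grid), n_pick), , drop = FALSE]
    x <- volume$intensities
    for (i in seq_len(n_pick)) {
      prof <- x[pick$row[i], pick$col[i], ]
      x[pick$row[i], pick$col[i], ] <-
        if (mode == "low_contrast") mean(prof) else 0
    }
    out <- volume
    out$intensities <- x
    list(volume = out,
         corrupted = tibble::as_tibble(pick[order(pick$row, pick$col), ]))
  })
}

#' Simulate a longitudinal two-eye cohort
#'
#' Draws one additive per-(animal, layer) Gaussian effect per animal —
#' persistent across ages and shared by both eyes — and generates an OS and
#' an OD phantom per animal at every requested age.
#'
#' @param specs Named list of [phantom_spec()] objects, one per group.
#' @param ages Ages in months at which every animal is imaged.
#' @param n_animals Animals per group.
#' @param dims Volume dimensions passed to [generate_phantom()].
#' @param noise `"speckle"` or `"none"`.
#' @param render If `FALSE`, skip intensity rendering (volumes are `NULL`)
#'   and return ground truth only — much faster for statistical studies.
#' @param seed Integer seed for the whole cohort.
#' @return A tibble with one row per volume: `group`, `animal_id`, `eye`,
#'   `age_months`, and list-columns `volume`, `truth`.
#' @examples
#' coh <- simulate_cohort(list(WT = phantom_spec()), ages = c(1, 4),
#'                        n_animals = 2, dims = c(4, 32, 256),
#'                        render = FALSE, seed = 1)
#' nrow(coh)  # 2 animals x 2 eyes x 2 ages
#' @export
simulate_cohort <- function(specs, ages, n_animals,
                            dims = c(64L, 64L, 512L),
                            noise = "speckle", render = TRUE, seed = 1L) {
  stopifnot(length(ages) >= 1L, n_animals >= 1L, length(specs) >= 1L)
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "group")
  .with_seed(seed, {
    rows <- list()
    for (g in names(specs)) {
      spec <- specs[[g]]
      for (a in seq_len(n_animals)) {
        id <- sprintf("%s_%02d", g, a)
        eff <- rnorm(8L, 0, spec$between_sd_um)
        for (age in ages) {
          for (eye in c("OS", "OD")) {
            ph <- generate_phantom(
              spec, eye = eye, age_months = age, group = g, animal_id = id,
              dims = dims, animal_effect = eff, noise = noise, render = render,
              seed = sample.int(2147483646L, 1L)
            )
            rows[[length(rows) + 1L]] <- tibble::tibble(
              group = g, animal_id = id, eye = eye, age_months = age,
              volume = list(ph$volume), truth = list(ph$truth)
            )
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
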