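# Normative database over group x age x eye x layer x region, kernel
# density summaries, longitudinal min-max block maps, and per-subject
# abnormality probabilities.

#' Build a normative database from cohort block summaries
#'
#' Aggregates per-volume block summaries (rows of [crop_and_block()],
#' bound over a cohort) into one entry per group x age x eye x layer x
#' region: mean and SD *across volumes* (not A-scans), the number of
#' contributing volumes, and the raw per-volume means retained for kernel
#' density estimation and the nonparametric abnormality mode. Regions
#' discarded by block-level QC do not contribute. Cells with fewer than
#' two volumes are kept but flagged unusable for probabilities (their
#' `sd_um` is `NA`); empty cells are skipped with a warning.
#'
#' @param block_summaries Tibble of [crop_and_block()] rows across a
#'   cohort; must contain `group`, `animal_id`, `eye`, `age_months`,
#'   `region`, `layer`, `mean_um`, `retained`.
#' @param pool_eyes If `TRUE`, pool OS and OD into a single `"both"`
#'   stratum (as the whole-area reference tables do); by default eyes are
#'   kept separate.
#' @return A tibble of class `normative_db` with columns `group`,
#'   `age_months`, `eye`, `layer`, `region`, `mean_um`, `sd_um`, `n`, and
#'   list-column `values`.
#' @export
build_normative <- function(block_summaries, pool_eyes = FALSE) {
  need <- c("group", "animal_id", "eye", "age_months", "region", "layer",
            "mean_um", "retained")
  stopifnot(all(need %in% names(block_summaries)))
  x <- dplyr::filter(block_summaries, .data$retained, !is.na(.data$mean_um))
  if (pool_eyes) x <- dplyr::mutate(x, eye = "both")
  dropped <- nrow(block_summaries) - nrow(x)
  if (nrow(x) == 0L) stop("no retained block summaries", call. = FALSE)
  if (dropped > 0L) {
    n_cells <- block_summaries |>
      dplyr::anti_join(x, by = c("group", "eye", "age_months", "region", "layer")) |>
      dplyr::distinct(.data$group, .data$eye, .data$age_months, .data$region,
                      .data$layer) |>
      nrow()
    if (n_cells > 0L) {
      warning(n_cells, " empty normative cell(s) skipped", call. = FALSE)
    }
  }
  out <- x |>
    dplyr::group_by(.data$group, .data$age_months, .data$eye, .data$layer,
                    .data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      values = list(.data$mean_um),
      sd_um = if (dplyr::n() >= 2L) sd(.data$mean_um) else NA_real_,
      mean_um = mean(.data$mean_um),  # last: shadows the input column
      .groups = "drop"
    ) |>
    dplyr::select("group", "age_months", "eye", "layer", "region",
                  "mean_um", "sd_um", "n", "values")
  class(out) <- c("normative_db", class(out))
  out
}

#' Kernel density estimate with empirical quartiles
#'
#' Gaussian-kernel density with Silverman's rule-of-thumb bandwidth
#' (`stats::bw.nrd0`) unless a numeric bandwidth is given. A minimum
#' bandwidth guards degenerate zero-variance samples. The reported median
#' and quartiles are computed from the raw values, not from the density.
#'
#' @param values Numeric vector, at least 3 finite values.
#' @param bandwidth `"auto"` (Silverman) or a positive number.
#' @param min_bandwidth Lower bandwidth bound (um).
#' @param n_grid Number of evaluation points.
#' @return A `kde_estimate`: list with `x`, `density`, `bandwidth`,
#'   `median`, `q1`, `q3`, `n`.
#' @export
kde_estimate <- function(values, bandwidth = "auto", min_bandwidth = 0.01,
                         n_grid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 finite values", call. = FALSE)
  bw <- if (identical(bandwidth, "auto")) {
    tryCatch(stats::bw.nrd0(values), error = function(e) min_bandwidth)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  bw <- max(bw, min_bandwidth)
  dd <- density(values, bw = bw, n = n_grid, kernel = "gaussian", cut = 4)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(x = dd$x, density = dd$y, bandwidth = bw,
                 median = q[2], q1 = q[1], q3 = q[3], n = length(values)),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat(sprintf("<kde_estimate> n=%d bw=%.4g median=%.4g [Q1 %.4g, Q3 %.4g]\n",
              x$n, x$bandwidth, x$median, x$q1, x$q3))
  invisible(x)
}

#' Normalise longitudinal block means per layer
#'
#' Min-max normalisation of block means to `[0, 1]` within each layer,
#' over all (region, age) cells jointly — the scaling used to display
#' longitudinal block maps on a common colour scale per layer. Affine
#' transformations of a layer's inputs leave its output unchanged; a
#' constant layer maps to 0.5 by convention.
#'
#' @param block_means Tibble with columns `layer`, `region`, `age_months`,
#'   `mean_um` (e.g. a `normative_db` restricted to one group/eye).
#' @return The input with a `norm` column appended.
#' @export
normalize_longitudinal <- function(block_means) {
  stopifnot(all(c("layer", "region", "age_months", "mean_um") %in%
                  names(block_means)))
  block_means |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(
      norm = {
        rng <- range(.data$mean_um, na.rm = TRUE)
        if (diff(rng) == 0) rep(0.5, dplyr::n())
        else (.data$mean_um - rng[1]) / diff(rng)
      }
    ) |>
    dplyr::ungroup()
}

#' Score a subject against the normative database
#'
#' For each of the subject's block values, looks up the matching
#' normative entry (same group, age, eye, layer, region) and computes a
#' deviation score. The default Gaussian mode uses
#' `z = (x - mean) / sd` and the two-sided tail probability
#' `p = 2 * (1 - pnorm(|z|))`; the nonparametric `"percentile"` mode uses
#' the rank of `x` among the normative raw values,
#' `p = 2 * min(F(x), 1 - F(x-))`, capped at 1. A block is flagged
#' abnormal when `p < alpha`. Blocks without a usable entry (missing cell,
#' `n < 2`, or zero SD) are reported not evaluable and never flagged.
#'
#' @param subject Tibble with columns `group`, `age_months`, `eye`,
#'   `layer`, `region`, `value_um` (one row per block).
#' @param db A [build_normative()] database.
#' @param alpha Flagging level.
#' @param method `"gaussian"` or `"percentile"`.
#' @return The subject tibble with `z`, `p`, `flag`, `evaluable` appended.
#' @export
abnormality <- function(subject, db, alpha = 0.05,
                        method = c("gaussian", "percentile")) {
  method <- match.arg(method)
  stopifnot(inherits(db, "normative_db"),
            all(c("group", "age_months", "eye", "layer", "region",
                  "value_um") %in% names(subject)),
            alpha > 0, alpha < 1)
  joined <- dplyr::left_join(
    subject, db,
    by = c("group", "age_months", "eye", "layer", "region")
  )
  res <- joined |>
    dplyr::mutate(
      evaluable = !is.na(.data$mean_um) & !is.na(.data$sd_um) &
        .data$sd_um > 0 & .data$n >= 2L,
      z = dplyr::if_else(.data$evaluable,
                         (.data$value_um - .data$mean_um) / .data$sd_um,
                         NA_real_),
      p = NA_real_
    )
  if (method == "gaussian") {
    res$p <- ifelse(res$evaluable, 2 * (1 - pnorm(abs(res$z))), NA_real_)
  } else {
    res$p <- purrr::pmap_dbl(
      list(res$values, res$value_um, res$evaluable),
      function(vals, x, ok) {
        if (!ok) return(NA_real_)
        lo <- mean(vals <= x)
        hi <- mean(vals >= x)
        min(1, 2 * min(lo, hi))
      }
    )
  }
  res$p <- ifelse(!is.na(res$p), pmax(pmin(res$p, 1), .Machine$double.xmin),
                  NA_real_)
  res$flag <- !is.na(res$p) & res$p < alpha
  dplyr::select(res, dplyr::all_of(names(subject)), "z", "p", "flag",
                "evaluable")
}

#' Persist / load a normative database
#'
#' The database is written as one CSV (list-column of raw values collapsed
#' to a `;`-separated field) plus a JSON metadata file recording the QC
#' parameters, seeds and normalisation mode used to build it.
#'
#' @param db A `normative_db`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @param metadata Named list written alongside.
#' @return `path`, invisibly (`write_normative`); a `normative_db`
#'   (`read_normative`).
#' @export
write_normative <- function(db, path, metadata = list()) {
  stopifnot(inherits(db, "normative_db"))
  flat <- db |>
    dplyr::mutate(values = vapply(.data$values, paste, "", collapse = ";"))
  write.csv(flat, path, row.names = FALSE)
  jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  x <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  x$values <- lapply(strsplit(as.character(x$values), ";", fixed = TRUE),
                     as.numeric)
  class(x) <- c("normative_db", class(x))
  x
}
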