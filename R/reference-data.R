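# Bundled normative reference values for C57BL6/129S wild-type (WT) and
# triple-transgenic Alzheimer's-disease (3xTg-AD) mice: whole-area mean (SD)
# thickness in micrometres per layer at 1, 2, 3, 4, 8, 12 and 16 months,
# pooled over both eyes. These are the calibration targets of the phantom
# generator and the worked-example inputs of the summary-level statistics.

REF_AGES <- c(1L, 2L, 3L, 4L, 8L, 12L, 16L)

.ref_layer_rows <- function(group, layer, means, sds) {
  tibble::tibble(
    group = group, layer = layer, age_months = REF_AGES,
    mean_um = means, sd_um = sds
  )
}

.reference_thickness_build <- function() {
  w <- list(
    `RNFL-GCL` = list(c(13.59, 13.10, 13.27, 13.32, 12.51, 12.62, 12.34),
                      c(0.76, 0.63, 0.87, 0.63, 0.71, 0.80, 0.79)),
    IPL = list(c(50.26, 46.66, 46.04, 45.63, 44.90, 44.80, 44.65),
               c(1.33, 1.43, 1.15, 0.85, 1.09, 1.18, 1.14)),
    INL = list(c(25.72, 22.18, 21.52, 20.96, 20.32, 20.08, 19.66),
               c(0.99, 0.86, 0.76, 0.57, 0.56, 0.76, 0.61)),
    OPL = list(c(15.71, 15.58, 15.46, 15.56, 15.96, 15.84, 15.89),
               c(0.24, 0.24, 0.18, 0.17, 0.35, 0.38, 0.41)),
    ONL = list(c(61.57, 60.00, 60.03, 59.63, 59.15, 59.14, 60.05),
               c(1.11, 1.16, 1.12, 0.97, 1.25, 2.33, 2.21)),
    ILS = list(c(11.06, 11.25, 11.21, 11.38, 11.90, 11.88, 12.04),
               c(0.50, 0.52, 0.37, 0.36, 0.56, 0.62, 0.50)),
    OLS = list(c(11.69, 11.49, 11.40, 11.37, 11.42, 11.36, 11.04),
               c(0.30, 0.30, 0.23, 0.25, 0.30, 0.46, 0.40)),
    RPE = list(c(20.26, 21.91, 22.62, 22.97, 23.41, 24.11, 23.51),
               c(0.91, 0.96, 1.24, 0.90, 1.11, 1.44, 1.21)),
    TRT = list(c(209.85, 202.18, 201.54, 200.82, 199.57, 199.83, 199.17),
               c(3.08, 2.89, 2.46, 2.48, 3.33, 4.39, 3.96))
  )
  tg <- list(
    `RNFL-GCL` = list(c(13.37, 13.45, 13.57, 13.36, 13.10, 13.31, 13.08),
                      c(0.77, 0.81, 0.83, 0.77, 0.85, 0.76, 0.79)),
    IPL = list(c(46.69, 44.14, 44.15, 43.67, 43.13, 42.89, 43.09),
               c(1.52, 1.28, 1.23, 1.22, 1.34, 1.31, 1.56)),
    INL = list(c(22.86, 20.19, 20.06, 19.49, 19.03, 18.73, 18.73),
               c(0.97, 0.68, 0.68, 0.54, 0.72, 0.67, 0.75)),
    OPL = list(c(15.39, 15.34, 15.38, 15.41, 15.59, 15.55, 15.74),
               c(0.23, 0.17, 0.20, 0.17, 0.29, 0.33, 0.34)),
    ONL = list(c(61.03, 59.73, 59.80, 59.17, 58.05, 57.62, 57.84),
               c(1.40, 1.32, 1.45, 1.42, 1.52, 1.53, 2.00)),
    ILS = list(c(10.48, 10.87, 11.00, 11.16, 11.31, 11.31, 11.57),
               c(0.36, 0.33, 0.36, 0.30, 0.38, 0.40, 0.58)),
    OLS = list(c(11.42, 11.38, 11.40, 11.46, 11.42, 11.34, 11.24),
               c(0.23, 0.25, 0.25, 0.24, 0.24, 0.24, 0.39)),
    RPE = list(c(19.80, 21.58, 21.96, 21.87, 22.60, 23.43, 23.68),
               c(0.94, 0.98, 0.88, 0.76, 0.96, 1.32, 1.16)),
    TRT = list(c(201.03, 196.67, 197.34, 195.58, 194.23, 194.18, 194.98),
               c(3.47, 2.62, 3.21, 2.68, 3.36, 3.81, 4.51))
  )
  rows <- c(
    purrr::imap(w, ~ .ref_layer_rows("WT", .y, .x[[1]], .x[[2]])),
    purrr::imap(tg, ~ .ref_layer_rows("3xTg-AD", .y, .x[[1]], .x[[2]]))
  )
  dplyr::bind_rows(rows)
}

#' Bundled normative whole-area thickness table
#'
#' Whole-imaged-area mean and standard deviation of retinal layer thickness
#' (micrometres) for wild-type (`"WT"`) and triple-transgenic
#' Alzheimer's-disease (`"3xTg-AD"`) mice at 1, 2, 3, 4, 8, 12 and 16 months
#' of age, pooled over both eyes. The eight layers of [retinal_layers()] plus
#' total retinal thickness (`"TRT"`) are included. These values are the
#' calibration targets for [phantom_spec()] age trends and the inputs to
#' summary-level worked examples such as [welch_from_summary()].
#'
#' @param group Optional filter, `"WT"` or `"3xTg-AD"`.
#' @param layer Optional filter, one of [retinal_layers()] or `"TRT"`.
#' @return A tibble with columns `group`, `layer`, `age_months`, `mean_um`,
#'   `sd_um`.
#' @examples
#' reference_thickness("WT", "TRT")
#' @export
reference_thickness <- function(group = NULL, layer = NULL) {
  out <- .reference_thickness_build()
  if (!is.null(group)) {
    stopifnot(group %in% unique(out$group))
    out <- dplyr::filter(out, .data$group %in% !!group)
  }
  if (!is.null(layer)) {
    stopifnot(layer %in% LAYERS_TRT)
    out <- dplyr::filter(out, .data$layer %in% !!layer)
  }
  out
}

#' Bundled per-eye volume counts
#'
#' Number of OCT volumes available per group, eye and age in the normative
#' cohort the reference table summarises. Used as the sample sizes for
#' summary-level tests on [reference_thickness()] rows.
#'
#' @return A tibble with columns `group`, `eye`, `age_months`, `n`.
#' @examples
#' reference_eye_counts()
#' @export
reference_eye_counts <- function() {
  tibble::tibble(
    group = rep(c("WT", "3xTg-AD"), each = 14L),
    eye = rep(rep(c("OS", "OD"), each = 7L), 2L),
    age_months = rep(REF_AGES, 4L),
    n = c(
      56L, 51L, 51L, 53L, 49L, 46L, 32L,
      53L, 51L, 49L, 53L, 49L, 44L, 27L,
      54L, 53L, 53L, 51L, 47L, 43L, 35L,
      55L, 54L, 54L, 51L, 46L, 43L, 43L
    )
  )
}

#' Complete-case longitudinal sample sizes
#'
#' Number of eyes measurable at every age (the complete-case subset used by
#' the longitudinal repeated-measures analyses), per group and eye.
#'
#' @return A tibble with columns `group`, `eye`, `n_complete`.
#' @export
reference_complete_cases <- function() {
  tibble::tibble(
    group = c("WT", "WT", "3xTg-AD", "3xTg-AD"),
    eye = c("OS", "OD", "OS", "OD"),
    n_complete = c(27L, 22L, 33L, 36L)
  )
}
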