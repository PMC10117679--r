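# ggplot2 views of the result types.

#' @export
autoplot.thickness_map <- function(object, layer = "TRT", ...) {
  k <- match(layer, LAYERS_TRT)
  if (is.na(k)) stop("unknown layer: ", layer, call. = FALSE)
  d <- dim(object$thickness)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    thickness_um = as.vector(object$thickness[, , k])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$thickness_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = paste0(layer, " (µm)"),
                                  na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "A-scan (temporal → nasal)",
                  y = "B-scan (superior → inferior)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kde_estimate <- function(object, ...) {
  df <- tibble::tibble(x = object$x, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$median, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(object$q1, object$q3),
                        linetype = "dotted") +
    ggplot2::labs(x = "thickness (µm)", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.oct_pairwise <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time1, .data$time2,
                                   fill = .data$p.adjusted)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars)) +
    ggplot2::scale_fill_viridis_c(name = "adjusted p", limits = c(0, 1),
                                  direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, title = object$method) +
    ggplot2::theme_minimal()
}

#' Longitudinal normalised block map
#'
#' Displays per-layer min-max normalised block means as a block x age
#' tile grid per layer, the standard view of longitudinal normative
#' variation across the 3x3 ROIs.
#'
#' @param db A `normative_db` (ideally one group and eye stratum).
#' @param group,eye Strata to display.
#' @return A ggplot.
#' @export
plot_longitudinal_blocks <- function(db, group = NULL, eye = NULL) {
  x <- dplyr::filter(db, .data$region != "whole")
  if (!is.null(group)) x <- dplyr::filter(x, .data$group == !!group)
  if (!is.null(eye)) x <- dplyr::filter(x, .data$eye == !!eye)
  x <- normalize_longitudinal(x)
  x$layer <- factor(x$layer, levels = LAYERS_TRT)
  x$region <- factor(x$region, levels = paste0("B", 1:9))
  ggplot2::ggplot(x, ggplot2::aes(factor(.data$age_months), .data$region,
                                  fill = .data$norm)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_y_discrete(limits = rev(paste0("B", 1:9))) +
    ggplot2::scale_fill_viridis_c(name = "normalised\nthickness",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "age (months)", y = "block") +
    ggplot2::theme_minimal()
}
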