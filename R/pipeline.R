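# End-to-end orchestration: simulate -> segment -> thickness + QC ->
# blocks -> normative database -> statistics, with CSV outputs.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. The defaults describe a
#' small two-group demonstration cohort; `load_config()` reads the same
#' structure from a YAML file.
#'
#' @param out_dir Output directory for all report files.
#' @param groups Group labels with bundled reference trends
#'   (`"WT"`, `"3xTg-AD"`).
#' @param ages Imaging ages in months.
#' @param n_animals Animals per group.
#' @param dims Volume dimensions `c(n_bscans, n_ascans, n_samples)`; the
#'   en-face grid must be square and `3k + 2`.
#' @param noise `"speckle"` or `"none"`.
#' @param segmentation `"oracle"` (ideal class map + DP projection),
#'   `"truth"` (ground-truth boundaries, no segmentation), or `"unet"`
#'   (train the compact network on the first volume and segment all).
#' @param qc A [qc_params()].
#' @param pool_eyes Pool eyes in the normative database.
#' @param bonferroni_m Comparisons per family for the per-layer group
#'   tests (the eight layers tested at each age); TRT is tested as its
#'   own family, uncorrected.
#' @param seed Master seed; every downstream random draw derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("octnorm_run_"),
                            groups = c("WT", "3xTg-AD"),
                            ages = c(1, 4), n_animals = 4L,
                            dims = c(35L, 35L, 256L),
                            noise = "speckle",
                            segmentation = c("oracle", "truth", "unet"),
                            qc = qc_params(), pool_eyes = TRUE,
                            bonferroni_m = 8L, seed = 1L) {
  segmentation <- match.arg(segmentation)
  stopifnot(length(ages) >= 1L, n_animals >= 1L, bonferroni_m >= 1L)
  structure(list(out_dir = out_dir, groups = groups, ages = ages,
                 n_animals = as.integer(n_animals), dims = as.integer(dims),
                 noise = noise, segmentation = segmentation, qc = qc,
                 pool_eyes = pool_eyes, bonferroni_m = as.integer(bonferroni_m),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the `pipeline_config()` arguments.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc_args <- y$qc %||% list()
  y$qc <- do.call(qc_params, qc_args)
  y$dims <- as.integer(unlist(y$dims))
  y$ages <- as.numeric(unlist(y$ages))
  y$groups <- as.character(unlist(y$groups))
  do.call(pipeline_config, y)
}

# boundaries for one volume according to the configured segmentation mode
.pipeline_boundaries <- function(mode, volume, truth, model) {
  switch(mode,
         truth = as_boundary_set(truth),
         oracle = boundaries_from_classmap(oracle_classmap(truth)),
         unet = boundaries_from_classmap(segment_volume(model, volume)))
}

#' Run the full pipeline
#'
#' Simulates the configured cohort, extracts boundaries per volume,
#' computes QC-filtered mirrored thickness maps and block summaries, and
#' writes four deterministic outputs to `config$out_dir`:
#'
#' * `thickness_blocks.csv` — per-volume block/whole-area summaries;
#' * `group_age_means.csv` — group x age table of whole-area
#'   `mean (SD)` strings for the 8 layers + TRT;
#' * `normative_db.csv` (+`.json` metadata) — the normative database;
#' * `stats_report.csv` — per age x layer group comparisons
#'   (Bonferroni over the 8 layers; TRT uncorrected) and, when every age
#'   is available for a subject, the longitudinal TRT test per group with
#'   `pairwise_<group>.csv` Tukey-Kramer matrices.
#'
#' Any per-volume failure is collected with its volume id and re-raised
#' at the end.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output paths and the in-memory
#'   tibbles (`blocks`, `table`, `normative`, `stats`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- lapply(config$groups, phantom_spec)
  names(specs) <- config$groups
  cohort <- simulate_cohort(specs, ages = config$ages,
                            n_animals = config$n_animals,
                            dims = config$dims, noise = config$noise,
                            render = TRUE, seed = config$seed)
  model <- NULL
  if (config$segmentation == "unet") {
    model <- .pipeline_train_model(cohort, config)
  }
  scale <- cohort$truth[[1]]$scale
  errors <- character()
  blocks <- purrr::pmap(cohort, function(group, animal_id, eye, age_months,
                                         volume, truth) {
    vol_id <- sprintf("%s/%s/%smo", animal_id, eye, age_months)
    tryCatch({
      bnd <- .pipeline_boundaries(config$segmentation, volume, truth, model)
      th <- compute_thickness(bnd, scale)
      qc <- qc_ascan(volume, bnd, th, config$qc)
      th <- apply_qc(th, qc)
      th <- mirror_if_left(th)
      crop_and_block(th, config$qc)
    }, error = function(e) {
      errors <<- c(errors, paste0(vol_id, ": ", conditionMessage(e)))
      NULL
    })
  })
  if (length(errors)) {
    stop("pipeline failures:\n", paste(errors, collapse = "\n"), call. = FALSE)
  }
  blocks <- dplyr::bind_rows(blocks)
  paths <- list(blocks = file.path(config$out_dir, "thickness_blocks.csv"))
  write.csv(blocks, paths$blocks, row.names = FALSE)

  table_ga <- blocks |>
    dplyr::filter(.data$region == "whole") |>
    dplyr::group_by(.data$group, .data$age_months, .data$layer) |>
    dplyr::summarise(cell = sprintf("%.2f (%.2f)", mean(.data$mean_um),
                                    sd(.data$mean_um)),
                     .groups = "drop") |>
    dplyr::mutate(layer = factor(.data$layer, levels = LAYERS_TRT)) |>
    dplyr::arrange(.data$group, .data$age_months, .data$layer) |>
    tidyr::pivot_wider(names_from = "layer", values_from = "cell")
  paths$table <- file.path(config$out_dir, "group_age_means.csv")
  write.csv(table_ga, paths$table, row.names = FALSE)

  db <- suppressWarnings(build_normative(blocks, pool_eyes = config$pool_eyes))
  paths$normative <- file.path(config$out_dir, "normative_db.csv")
  write_normative(db, paths$normative, metadata = list(
    qc = unclass(config$qc), seed = config$seed,
    pool_eyes = config$pool_eyes, segmentation = config$segmentation,
    normalization = "per-layer min-max over blocks x ages"
  ))

  stats_tbl <- .pipeline_stats(blocks, config)
  paths$stats <- file.path(config$out_dir, "stats_report.csv")
  write.csv(stats_tbl, paths$stats, row.names = FALSE)

  paths$pairwise <- .pipeline_longitudinal(blocks, config)

  invisible(list(paths = paths, blocks = blocks, table = table_ga,
                 normative = db, stats = stats_tbl))
}

# desk-scale training set: B-scans + oracle labels from the first volume
.pipeline_train_model <- function(cohort, config) {
  v <- cohort$volume[[1]]
  cm <- oracle_classmap(cohort$truth[[1]])
  d <- dim(v$intensities)
  idx <- unique(round(seq(1, d[1], length.out = min(32L, d[1]))))
  bs <- lapply(idx, function(b) t(matrix(v$intensities[b, , ], d[2], d[3])))
  lb <- lapply(idx, function(b) t(matrix(cm$labels[b, , ], d[2], d[3])))
  train_segmenter(bs, lb, unet_config(seed = config$seed))
}

.pipeline_stats <- function(blocks, config) {
  whole <- dplyr::filter(blocks, .data$region == "whole")
  if (length(unique(whole$group)) < 2L) return(tibble::tibble())
  gs <- unique(whole$group)[1:2]
  combos <- dplyr::distinct(whole, .data$age_months, .data$layer)
  purrr::pmap_dfr(combos, function(age_months, layer) {
    a <- whole$mean_um[whole$group == gs[1] & whole$age_months == age_months &
                         whole$layer == layer]
    b <- whole$mean_um[whole$group == gs[2] & whole$age_months == age_months &
                         whole$layer == layer]
    m <- if (layer == "TRT") 1L else config$bonferroni_m
    res <- compare_groups(a, b, m = m, seed = config$seed + 7L)
    dplyr::bind_cols(
      tibble::tibble(age_months = age_months, layer = layer,
                     group1 = gs[1], group2 = gs[2]),
      dplyr::select(tidy(res), -"df")
    )
  })
}

# longitudinal TRT per group (subjects = animal x eye), when >= 2 ages
.pipeline_longitudinal <- function(blocks, config) {
  if (length(config$ages) < 2L || config$n_animals < 3L) return(character())
  trt <- blocks |>
    dplyr::filter(.data$region == "whole", .data$layer == "TRT") |>
    dplyr::transmute(group = .data$group,
                     subject = paste(.data$animal_id, .data$eye, sep = "_"),
                     time = .data$age_months, value = .data$mean_um)
  out <- character()
  for (g in unique(trt$group)) {
    cc <- complete_cases(dplyr::filter(trt, .data$group == g))
    fit <- rm_anova_oneway(cc$data, seed = config$seed + 13L)
    if (!is.null(fit$ms_error)) {
      pw <- tukey_kramer(fit)
      f <- file.path(config$out_dir,
                     paste0("pairwise_", gsub("[^A-Za-z0-9]", "_", g), ".csv"))
      write.csv(tidy(pw), f, row.names = FALSE)
      out <- c(out, f)
    }
  }
  out
}
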