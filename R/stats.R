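# The statistical battery for group and longitudinal comparisons:
# Monte-Carlo Lilliefors normality gating, Welch / Mann-Whitney two-group
# tests with Bonferroni correction, one- and two-way repeated-measures
# ANOVA with Friedman fallback, Tukey-Kramer post-hoc pairwise
# comparisons on the within-subject error term, and complete-case
# filtering for longitudinal tables.

SIG_LEVELS <- c(0.05, 0.01, 0.001)

.stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

.oct_htest <- function(method, statistic = NA_real_, df = NA_real_,
                       p.value = NA_real_, p.adjusted = NA_real_,
                       n1 = NA_integer_, n2 = NA_integer_, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = p.value, p.adjusted = p.adjusted,
                   n1 = n1, n2 = n2,
                   stars = .stars(p.adjusted %|NA|% p.value)),
              extra),
            class = "oct_htest")
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

#' @export
print.oct_htest <- function(x, ...) {
  cat(sprintf("<oct_htest> %s: stat=%.4g df=%s p=%.4g adj=%.4g %s\n",
              x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ","),
              x$p.value, x$p.adjusted, x$stars))
  invisible(x)
}

#' @export
tidy.oct_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = list(x$df), p.value = x$p.value,
                 p.adjusted = x$p.adjusted, stars = x$stars,
                 n1 = x$n1, n2 = x$n2)
}

#' @export
glance.oct_htest <- function(x, ...) tidy(x, ...)

# ---- normality --------------------------------------------------------

.lilliefors_D <- function(x) {
  n <- length(x)
  xs <- sort(x)
  Fh <- pnorm(xs, mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - Fh, Fh - (i - 1) / n)
}

.liln_cache <- new.env(parent = emptyenv())

# Monte-Carlo null distribution of the Lilliefors statistic for sample
# size n (estimated mean/SD), cached per (n, m, seed)
.lilliefors_null <- function(n, m = 2000L, seed = 171L) {
  key <- paste(n, m, seed, sep = "_")
  if (!is.null(.liln_cache[[key]])) return(.liln_cache[[key]])
  ds <- .with_seed(seed, {
    vapply(seq_len(m), function(i) .lilliefors_D(rnorm(n)), numeric(1))
  })
  .liln_cache[[key]] <- sort(ds)
  .liln_cache[[key]]
}

#' Normality test (Lilliefors variant, Monte-Carlo null)
#'
#' Kolmogorov-Smirnov distance between the sample and a normal
#' distribution with *estimated* mean and SD, referred to a seeded
#' Monte-Carlo null distribution of the same statistic (m replicates of
#' size `n`), which accounts for the parameter estimation. The sample is
#' called normal when `p >= alpha`; the gating level follows the 10%
#' convention of the analysis battery. Zero-variance samples are never
#' normal.
#'
#' @param x Numeric sample, `n >= 4`.
#' @param alpha Significance level of the gate.
#' @param n_mc Monte-Carlo replicates for the null.
#' @param seed Seed of the Monte-Carlo null (cached per `(n, n_mc, seed)`).
#' @return An `oct_htest` with `normal` (logical) in its fields.
#' @export
normality_test <- function(x, alpha = 0.10, n_mc = 2000L, seed = 171L) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need n >= 4 for the normality test", call. = FALSE)
  if (sd(x) == 0) {
    return(.oct_htest("Lilliefors (Monte-Carlo)", statistic = Inf,
                      p.value = 0, n1 = length(x),
                      extra = list(normal = FALSE, alpha = alpha)))
  }
  D <- .lilliefors_D(x)
  null <- .lilliefors_null(length(x), n_mc, seed)
  p <- (sum(null >= D) + 1) / (length(null) + 1)
  .oct_htest("Lilliefors (Monte-Carlo)", statistic = D, p.value = p,
             n1 = length(x), extra = list(normal = p >= alpha, alpha = alpha))
}

# ---- two-group comparison --------------------------------------------

#' Two-group comparison with normality gating and Bonferroni correction
#'
#' Runs Welch's two-sample t-test when both samples pass the normality
#' gate at the 10% level, otherwise the Mann-Whitney U test (exact for
#' n <= 20 without ties, normal approximation with continuity and tie
#' correction otherwise). The Bonferroni-adjusted p-value is
#' `min(1, m * p)` for `m` comparisons in the family; significance stars
#' mark the 5%, 1% and 0.1% levels.
#'
#' @param a,b Numeric samples, each `n >= 4` (smaller samples yield an
#'   explicit insufficient-data result with `NA` p-value).
#' @param m Number of comparisons in the Bonferroni family.
#' @param gate_alpha Normality-gate level.
#' @param pooled_var Use the pooled-variance t-test instead of Welch.
#' @param seed Seed of the normality-gate Monte-Carlo null.
#' @return An `oct_htest`.
#' @export
compare_groups <- function(a, b, m = 1L, gate_alpha = 0.10,
                           pooled_var = FALSE, seed = 171L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 4L || length(b) < 4L) {
    return(.oct_htest("insufficient data", n1 = length(a), n2 = length(b)))
  }
  normal <- isTRUE(normality_test(a, gate_alpha, seed = seed)$normal) &&
    isTRUE(normality_test(b, gate_alpha, seed = seed)$normal)
  if (normal) {
    ht <- t.test(a, b, var.equal = pooled_var)
    method <- if (pooled_var) "t-test (pooled)" else "Welch t-test"
    res <- .oct_htest(method, statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p.value = ht$p.value,
                      n1 = length(a), n2 = length(b))
  } else {
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = max(length(a), length(b)) <= 20L,
                  correct = TRUE)
    )
    res <- .oct_htest("Mann-Whitney U", statistic = unname(ht$statistic),
                      p.value = ht$p.value, n1 = length(a), n2 = length(b))
  }
  res$p.adjusted <- min(1, m * res$p.value)
  res$stars <- .stars(res$p.adjusted)
  res
}

#' Welch's t-test from summary statistics
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and two-sided p-value, computed from group means, SDs and
#' sizes. Agrees exactly with [compare_groups()] on raw samples sharing
#' the same summaries. Useful for testing printed group-level tables.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return An `oct_htest`.
#' @examples
#' welch_from_summary(199.17, 3.96, 59, 194.98, 4.51, 78)
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  .oct_htest("Welch t-test (summary)", statistic = t, df = df, p.value = p,
             n1 = as.integer(n1), n2 = as.integer(n2))
}

# ---- longitudinal tables ---------------------------------------------

.check_long <- function(data) {
  stopifnot(all(c("subject", "time", "value") %in% names(data)))
  tab <- table(data$subject, data$time)
  if (any(tab != 1L)) {
    stop("longitudinal table must be complete-case: one value per ",
         "subject x time (run complete_cases() first)", call. = FALSE)
  }
  invisible(tab)
}

#' Complete-case filter for longitudinal records
#'
#' Keeps only subjects measured at every requested time point, as the
#' longitudinal repeated-measures analyses require.
#'
#' @param records Tibble with columns `subject`, `time`, `value` (extra
#'   columns pass through).
#' @param times Time points required; defaults to all present.
#' @return A list: `data` (filtered tibble, restricted to `times`),
#'   `kept_ids`, `dropped_ids`.
#' @export
complete_cases <- function(records, times = NULL) {
  stopifnot(all(c("subject", "time") %in% names(records)))
  if (is.null(times)) times <- sort(unique(records$time))
  x <- dplyr::filter(records, .data$time %in% times)
  counts <- x |>
    dplyr::distinct(.data$subject, .data$time) |>
    dplyr::count(.data$subject)
  kept <- counts$subject[counts$n == length(times)]
  dropped <- setdiff(unique(records$subject), kept)
  if (length(kept) == 0L) stop("no complete cases", call. = FALSE)
  list(data = dplyr::filter(x, .data$subject %in% kept),
       kept_ids = kept, dropped_ids = dropped)
}

#' One-way repeated-measures ANOVA / Friedman test
#'
#' Tests a within-subject time effect on a complete-case longitudinal
#' table. When every time point passes the normality gate the
#' within-subject F test `MS_time / MS_error` (subject blocking) is used,
#' fitted via `aov(value ~ time + Error(subject))`; otherwise the
#' rank-based Friedman test. The fitted error term (`ms_error`,
#' `df_error`, `n_subjects`, time means) is carried in the result for
#' [tukey_kramer()].
#'
#' @param data Tibble with columns `subject`, `time`, `value`; complete
#'   cases, at least 2 time points and 3 subjects.
#' @param gate_alpha Normality-gate level (10% convention).
#' @param force `"auto"`, `"ranova"` or `"friedman"`.
#' @param seed Seed for the normality-gate Monte-Carlo null.
#' @return An `oct_htest`.
#' @export
rm_anova_oneway <- function(data, gate_alpha = 0.10,
                            force = c("auto", "ranova", "friedman"),
                            seed = 171L) {
  force <- match.arg(force)
  .check_long(data)
  times <- sort(unique(data$time))
  subjects <- unique(data$subject)
  if (length(times) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (length(subjects) < 3L) stop("need >= 3 subjects", call. = FALSE)
  d <- dplyr::mutate(data, time = factor(.data$time),
                     subject = factor(.data$subject))
  use_ranova <- switch(
    force,
    ranova = TRUE, friedman = FALSE,
    auto = all(vapply(split(d$value, d$time), function(v) {
      isTRUE(normality_test(v, gate_alpha, seed = seed)$normal)
    }, logical(1)))
  )
  time_means <- tapply(d$value, d$time, mean)
  if (use_ranova) {
    fit <- aov(value ~ time + Error(subject), data = d)
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    rn <- trimws(rownames(within))
    it <- which(rn == "time"); ir <- which(rn == "Residuals")
    Fv <- within[it, "F value"]
    pv <- within[it, "Pr(>F)"]
    # degenerate table (no time variation at all): define F = 0, p = 1
    tot <- sum((d$value - mean(d$value))^2)
    if (within[it, "Sum Sq"] <= 1e-12 * max(tot, 1)) {
      Fv <- 0; pv <- 1
    }
    .oct_htest("RANOVA (one-way, within-subject)",
               statistic = Fv,
               df = c(within[it, "Df"], within[ir, "Df"]),
               p.value = pv,
               n1 = length(subjects),
               extra = list(
                 ms_error = within[ir, "Mean Sq"],
                 df_error = within[ir, "Df"],
                 n_subjects = length(subjects),
                 time_means = time_means
               ))
  } else {
    ht <- friedman.test(value ~ time | subject, data = d)
    .oct_htest("Friedman", statistic = unname(ht$statistic),
               df = unname(ht$parameter), p.value = ht$p.value,
               n1 = length(subjects),
               extra = list(n_subjects = length(subjects),
                            time_means = time_means,
                            data = d))
  }
}

#' Two-way mixed repeated-measures ANOVA
#'
#' Between-subject group factor, within-subject time factor: tests the
#' group main effect against the subject-within-group error and the time
#' and group x time effects against the within-subject residual, via
#' `aov(value ~ group * time + Error(subject))`. Both groups must be
#' complete-case.
#'
#' @param data Tibble with columns `group`, `subject`, `time`, `value`.
#' @return An `oct_anova`: a tibble of the three effects with class
#'   attached, printable and `tidy()`-able.
#' @export
rm_anova_twoway <- function(data) {
  stopifnot(all(c("group", "subject", "time", "value") %in% names(data)))
  .check_long(data)
  if (length(unique(data$group)) < 2L) {
    stop("need >= 2 groups for the mixed design", call. = FALSE)
  }
  d <- dplyr::mutate(data, group = factor(.data$group),
                     time = factor(.data$time),
                     subject = factor(.data$subject))
  fit <- aov(value ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  grab <- function(tab, term, stratum) {
    rn <- trimws(rownames(tab))
    i <- which(rn == term); ir <- which(rn == "Residuals")
    tibble::tibble(term = term, stratum = stratum,
                   df = tab[i, "Df"], df_error = tab[ir, "Df"],
                   statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
  }
  out <- dplyr::bind_rows(
    grab(between, "group", "between"),
    grab(within, "time", "within"),
    grab(within, "group:time", "within")
  )
  out$stars <- .stars(out$p.value)
  structure(out, class = c("oct_anova", class(out)))
}

#' @export
tidy.oct_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) != "oct_anova"])
}

#' Tukey-Kramer pairwise time comparisons
#'
#' All pairwise comparisons between time points, using the studentized
#' range distribution on the repeated-measures error term of a fitted
#' one-way RANOVA: `q = |m_i - m_j| / sqrt(MS_error / n)` referred to
#' `ptukey(q, k, df_error)`. With two time points this reduces to the
#' paired comparison on the same error term (`q = sqrt(2) |t|`).
#'
#' @param fit An [rm_anova_oneway()] result fitted with the RANOVA path.
#' @param levels Significance levels marked by stars.
#' @return An `oct_pairwise`: symmetric matrix of adjusted p-values with
#'   unit diagonal; `tidy()` returns the long form.
#' @export
tukey_kramer <- function(fit, levels = SIG_LEVELS) {
  stopifnot(inherits(fit, "oct_htest"))
  if (is.null(fit$ms_error)) {
    stop("tukey_kramer() needs a RANOVA fit (rm_anova_oneway with the ",
         "parametric path)", call. = FALSE)
  }
  means <- fit$time_means
  k <- length(means)
  if (k < 2L) stop("need >= 2 time points", call. = FALSE)
  n <- fit$n_subjects
  se <- sqrt(fit$ms_error / n)
  P <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(means[i] - means[j]) / se
      p <- 1 - ptukey(q, nmeans = k, df = fit$df_error)
      P[i, j] <- P[j, i] <- p
    }
  }
  structure(list(p = P, method = "Tukey-Kramer", levels = levels,
                 df_error = fit$df_error), class = "oct_pairwise")
}

#' @export
print.oct_pairwise <- function(x, ...) {
  cat("<oct_pairwise>", x$method, "adjusted p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' @export
tidy.oct_pairwise <- function(x, ...) {
  k <- nrow(x$p)
  nm <- rownames(x$p)
  idx <- which(upper.tri(x$p), arr.ind = TRUE)
  tibble::tibble(time1 = nm[idx[, 1]], time2 = nm[idx[, 2]],
                 p.adjusted = x$p[idx], stars = .stars(x$p[idx]))
}
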