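# independent oracle: one-way repeated-measures F from the raw SS
# decomposition (grand/subject/time/error), no model-fitting machinery
manual_ranova_F <- function(wide) {
  s <- nrow(wide); t <- ncol(wide)
  grand <- mean(wide)
  ss_time <- s * sum((colMeans(wide) - grand)^2)
  ss_subj <- t * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  ms_time <- ss_time / (t - 1)
  ms_err <- ss_err / ((t - 1) * (s - 1))
  list(F = ms_time / ms_err, df1 = t - 1, df2 = (t - 1) * (s - 1),
       ms_err = ms_err)
}

long_from_wide <- function(wide) {
  tibble::tibble(
    subject = rep(rownames(wide) %||% paste0("S", seq_len(nrow(wide))),
                  ncol(wide)),
    time = rep(seq_len(ncol(wide)), each = nrow(wide)),
    value = as.vector(wide)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("normality gate accepts Gaussians and rejects gross departures", {
  set.seed(1)
  res <- normality_test(rnorm(200), seed = 5)
  expect_true(res$normal)
  expect_gte(res$p.value, 0.10)
  # bimodal sample is rejected
  bim <- normality_test(c(1, 1, 1, 10, 10, 10), seed = 5)
  expect_false(bim$normal)
  # zero variance is never normal
  expect_false(normality_test(rep(3, 10))$normal)
  expect_error(normality_test(c(1, 2, 3)), "n >= 4")
  # the gate's type-I error sits near its 10% level (cached null, so fast)
  set.seed(2)
  rej <- mean(vapply(1:500, function(i) {
    !normality_test(rnorm(20), seed = 5)$normal
  }, logical(1)))
  expect_lt(abs(rej - 0.10), 0.03)
})

test_that("group comparison gates on normality and applies Bonferroni", {
  set.seed(30)
  a <- rnorm(30); b <- rnorm(30)
  res <- compare_groups(a, b, m = 8)
  expect_match(res$method, "Welch")
  expect_equal(res$p.adjusted, min(1, 8 * res$p.value))
  expect_gte(res$p.adjusted, res$p.value)
  # identical samples: t = 0, adjusted p = 1
  same <- compare_groups(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.adjusted, 1)
  # skewed data routes to Mann-Whitney
  sk <- compare_groups(exp(rnorm(40, 0, 1.5)), exp(rnorm(40, 0, 1.5)))
  expect_match(sk$method, "Mann-Whitney")
  # tiny samples give an explicit insufficient-data result
  tiny <- compare_groups(c(1, 2, 3), b)
  expect_match(tiny$method, "insufficient")
  expect_true(is.na(tiny$p.value))
  # a large true offset at realistic SDs survives m = 8 correction
  a2 <- rnorm(40, 200, 3); b2 <- rnorm(40, 192, 3)
  strong <- compare_groups(a2, b2, m = 8)
  expect_lt(strong$p.adjusted, 0.001)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(4)
  ps <- vapply(1:1000, function(i) {
    t.test(rnorm(15), rnorm(15))$p.value
  }, numeric(1))
  d <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(d), 0.05)
})

test_that("summary-based Welch agrees exactly with the raw-sample test", {
  # construct samples with exact means/SDs
  mk <- function(n, m, s) {
    x <- scale(rnorm(n))
    as.vector(x * s + m)
  }
  set.seed(5)
  a <- mk(12, 10, 2); b <- mk(17, 11.5, 3)
  raw <- t.test(a, b)
  summ <- welch_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 17)
  expect_equal(summ$statistic, unname(raw$statistic))
  expect_equal(summ$df, unname(raw$parameter))
  expect_equal(summ$p.value, raw$p.value)
  # equal summaries: t = 0, p = 1
  eq <- welch_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  expect_error(welch_from_summary(1, 0, 10, 2, 1, 10), "sd")
})

test_that("group-level normative summaries separate at the printed sizes", {
  # 16-month whole-area TRT for the two reference groups, with the
  # bundled per-eye volume counts as group sizes
  ref <- reference_thickness(layer = "TRT") |>
    dplyr::filter(.data$age_months == 16)
  ns <- reference_eye_counts() |>
    dplyr::filter(.data$age_months == 16) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n))
  wt <- dplyr::filter(ref, .data$group == "WT")
  tg <- dplyr::filter(ref, .data$group == "3xTg-AD")
  res <- welch_from_summary(wt$mean_um, wt$sd_um,
                            ns$n[ns$group == "WT"],
                            tg$mean_um, tg$sd_um,
                            ns$n[ns$group == "3xTg-AD"])
  expect_lt(res$p.value, 0.001)
  expect_gt(res$statistic, 0)  # WT thicker
})

test_that("repeated-measures ANOVA matches the manual SS decomposition", {
  set.seed(6)
  wide <- matrix(rnorm(5 * 3, 20, 2), 5, 3) +
    matrix(rep(c(0, 1, 2), each = 5), 5, 3)
  oracle <- manual_ranova_F(wide)
  fit <- rm_anova_oneway(long_from_wide(wide), force = "ranova")
  expect_equal(fit$statistic, oracle$F)
  expect_equal(fit$df, c(oracle$df1, oracle$df2))
  expect_equal(fit$ms_error, oracle$ms_err)
  # small worked table: 3 subjects x 3 times, hand-checkable numbers
  wide2 <- matrix(c(10, 12, 13,
                    11, 14, 15,
                    12, 13, 17), 3, 3, byrow = TRUE)
  oracle2 <- manual_ranova_F(wide2)
  fit2 <- rm_anova_oneway(long_from_wide(wide2), force = "ranova")
  expect_equal(fit2$statistic, oracle2$F)
  expect_equal(fit2$df, c(oracle2$df1, oracle2$df2))
  # constant-over-time subjects: F = 0, p = 1
  flat <- matrix(rep(c(5, 7, 9, 11), 3), 4, 3)
  fit3 <- rm_anova_oneway(long_from_wide(flat), force = "ranova")
  expect_equal(fit3$statistic, 0)
  expect_equal(fit3$p.value, 1)
  # non-normal data route to Friedman under the gate
  set.seed(7)
  heavy <- matrix(exp(rnorm(60, 0, 2)), 20, 3)
  fitF <- rm_anova_oneway(long_from_wide(heavy), seed = 5)
  expect_match(fitF$method, "Friedman")
  # incomplete tables are rejected
  bad <- long_from_wide(wide)[-1, ]
  expect_error(rm_anova_oneway(bad), "complete-case")
})

test_that("complete-case filtering keeps exactly the fully measured subjects", {
  rec <- tibble::tibble(
    subject = c("a", "a", "b", "b", "c"),
    time = c(1, 2, 1, 2, 1),
    value = 1:5
  )
  cc <- complete_cases(rec)
  expect_setequal(cc$kept_ids, c("a", "b"))
  expect_equal(cc$dropped_ids, "c")
  expect_equal(nrow(cc$data), 4)
  # no missing data: identity
  cc2 <- complete_cases(rec[1:4, ])
  expect_equal(nrow(cc2$data), 4)
  expect_length(cc2$dropped_ids, 0)
  # requesting fewer ages can only keep more subjects
  cc3 <- complete_cases(rec, times = 1)
  expect_setequal(cc3$kept_ids, c("a", "b", "c"))
  expect_gte(length(cc3$kept_ids), length(cc$kept_ids))
  expect_error(complete_cases(rec[c(1, 3), ], times = c(1, 2)),
               "no complete cases")
})

test_that("two-way mixed ANOVA resolves group, time and interaction", {
  set.seed(8)
  n <- 12; times <- 3
  mk_group <- function(g, offset) {
    eff <- rnorm(n, 0, 1.5)
    tibble::tibble(
      group = g,
      subject = rep(paste0(g, seq_len(n)), times),
      time = rep(1:times, each = n),
      value = 20 + offset + rep(eff, times) +
        rep(c(0, -1, -2), each = n) + rnorm(n * times, 0, 0.5)
    )
  }
  d <- dplyr::bind_rows(mk_group("X", 0), mk_group("Y", -4))
  fit <- rm_anova_twoway(d)
  expect_setequal(fit$term, c("group", "time", "group:time"))
  expect_lt(fit$p.value[fit$term == "group"], 0.001)
  expect_lt(fit$p.value[fit$term == "time"], 0.001)
  expect_gt(fit$p.value[fit$term == "group:time"], 0.01)  # no interaction built
  # a duplicated group: group F ~ 0 and the time effect matches one-way
  set.seed(9)
  g1 <- mk_group("X", 0)
  g2 <- g1 |> dplyr::mutate(group = "Y", subject = paste0("c", subject))
  fit2 <- rm_anova_twoway(dplyr::bind_rows(g1, g2))
  expect_lt(fit2$statistic[fit2$term == "group"], 1e-10)
  expect_gt(fit2$p.value[fit2$term == "group"], 0.99)
  # duplicating a group doubles the time sum of squares while keeping the
  # error mean square, so the two-way time F is exactly twice the one-way F
  one <- rm_anova_oneway(dplyr::select(g1, "subject", "time", "value"),
                         force = "ranova")
  expect_equal(fit2$statistic[fit2$term == "time"], 2 * one$statistic,
               tolerance = 1e-8)
  expect_error(rm_anova_twoway(dplyr::mutate(g1, group = "only")), "2 groups")
})

test_that("Tukey-Kramer reduces to the paired comparison at two time points", {
  set.seed(10)
  wide <- matrix(rnorm(8 * 2, 10, 1), 8, 2)
  fit <- rm_anova_oneway(long_from_wide(wide), force = "ranova")
  pw <- tukey_kramer(fit)
  expect_equal(dim(pw$p), c(2, 2))
  expect_equal(diag(pw$p), c(1, 1), ignore_attr = TRUE)
  expect_equal(pw$p[1, 2], pw$p[2, 1])
  # q = sqrt(2) |t| identity at k = 2: Tukey p equals the F-test p
  expect_equal(pw$p[1, 2], fit$p.value, tolerance = 1e-10)
  # a strong single-time drop flags exactly the pairs involving it
  set.seed(11)
  wide2 <- matrix(rnorm(10 * 4, 200, 1), 10, 4)
  wide2[, 1] <- wide2[, 1] + 8
  fit2 <- rm_anova_oneway(long_from_wide(wide2), force = "ranova")
  pw2 <- tukey_kramer(fit2)
  p <- pw2$p
  expect_true(all(p[1, 2:4] < 0.001))
  others <- p[2:4, 2:4][upper.tri(matrix(0, 3, 3))]
  expect_true(all(others > 0.05))
  td <- tidy(pw2)
  expect_equal(nrow(td), 6)
  expect_true(all(td$p.adjusted >= 0 & td$p.adjusted <= 1))
})

test_that("type-I error is calibrated for every test in the battery", {
  set.seed(12)
  n_rep <- 500
  alpha <- 0.05
  se2 <- 2 * sqrt(alpha * (1 - alpha) / n_rep)
  # Welch on gaussian nulls
  welch_rej <- mean(vapply(1:n_rep, function(i) {
    t.test(rnorm(12), rnorm(12))$p.value < alpha
  }, logical(1)))
  expect_lt(abs(welch_rej - alpha), se2)
  # Mann-Whitney on exponential nulls
  mw_rej <- mean(vapply(1:n_rep, function(i) {
    suppressWarnings(wilcox.test(rexp(25), rexp(25))$p.value) < alpha
  }, logical(1)))
  expect_lt(abs(mw_rej - alpha), se2)
  # RANOVA on no-effect longitudinal tables
  ran_rej <- mean(vapply(1:n_rep, function(i) {
    wide <- matrix(rnorm(8 * 3), 8, 3) + rnorm(8)
    rm_anova_oneway(long_from_wide(wide), force = "ranova")$p.value < alpha
  }, logical(1)))
  expect_lt(abs(ran_rej - alpha), se2)
  # Friedman on no-effect tables
  fr_rej <- mean(vapply(1:n_rep, function(i) {
    wide <- matrix(rexp(10 * 3), 10, 3) + rexp(10)
    rm_anova_oneway(long_from_wide(wide), force = "friedman")$p.value < alpha
  }, logical(1)))
  expect_lt(abs(fr_rej - alpha), se2 + 0.01)  # Friedman is discrete at n=10
})

test_that("tidy and glance produce broom-shaped summaries", {
  res <- welch_from_summary(10, 1, 10, 11, 1, 10)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_true(all(c("method", "statistic", "p.value", "stars") %in% names(td)))
  expect_identical(glance(res), td)
})
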