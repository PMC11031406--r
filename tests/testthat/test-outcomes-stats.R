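test_that("regression grading partitions [0,100] into the CAP bands", {
  g <- grade_regression(c(0, 5, 10, 11, 50, 55, 100))
  expect_equal(g$cap_grade, c("G0", "G1", "G1", "G2", "G2", "G3", "G3"))
  expect_equal(g$pcr, c(TRUE, rep(FALSE, 6)))
  expect_equal(g$mpr, c(TRUE, TRUE, TRUE, rep(FALSE, 4)))
  expect_error(grade_regression(101), "outside")
  # total on [0,100] in 5% increments: every value gets exactly one grade
  all5 <- grade_regression(seq(0, 100, 5))
  expect_false(any(is.na(all5$cap_grade)))
})

test_that("KM matches the hand-worked 5-subject product limit", {
  km <- km_estimate(c(2, 1, 3, 5, 4), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(km$time, c(2, 5))
  expect_equal(km$survival, c(3 / 4, 0))   # 4 at risk at t=2; 1 at t=5
  expect_equal(km_median(km), 5)
  # no events: flat at 1, median not reached
  km0 <- km_estimate(1:5, rep(FALSE, 5))
  expect_equal(nrow(km0), 0L)
  expect_true(is.na(km_median(km0)))
  # all events at t=1
  km1 <- km_estimate(rep(1, 4), rep(TRUE, 4))
  expect_equal(km1$survival, 0)
  expect_equal(km_median(km1), 1)
  expect_error(km_estimate(-1, TRUE), "negative")
})

test_that("KM without censoring equals the empirical survivor function", {
  set.seed(12)
  t <- sample(1:40, 25, replace = TRUE)
  km <- km_estimate(t, rep(TRUE, 25))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$survival, emp)
})

test_that("KM estimate and log-log CI agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(7)
  t <- rexp(40, 0.04)
  e <- runif(40) < 0.6
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
  keep <- sf$n.event > 0
  expect_equal(km$survival, sf$surv[keep], tolerance = 1e-12)
  expect_equal(km$ci_lower, sf$lower[keep], tolerance = 1e-12)
  expect_equal(km$ci_upper, sf$upper[keep], tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  ok <- !is.na(km$ci_lower)
  expect_true(all(km$ci_lower[ok] <= km$survival[ok] &
                    km$survival[ok] <= km$ci_upper[ok]))
})

test_that("log-rank statistic matches survdiff, is relabel-invariant", {
  skip_if_not_installed("survival")
  set.seed(5)
  t <- c(rexp(15, 0.03), rexp(15, 0.09))
  e <- runif(30) < 0.8
  g <- rep(c("x", "y"), each = 15)
  lr <- logrank_test(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # relabeling invariance
  lr2 <- logrank_test(t, e, ifelse(g == "x", "zzz", "aaa"))
  expect_equal(lr2$chi_square, lr$chi_square, tolerance = 1e-12)
  # identical groups -> statistic 0, p 1 (duplicate every subject)
  lr0 <- logrank_test(rep(t, 2), rep(e, 2), rep(c("a", "b"), each = 30))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-10)
  # three groups -> df 2
  g3 <- rep(c("UD", "NEG", "POS"), each = 10)
  expect_equal(logrank_test(t, e, g3)$df, 2L)
  expect_error(logrank_test(t, e, rep("one", 30)), "two nonempty")
})

test_that("Clopper-Pearson endpoints satisfy the binomial tail equations", {
  for (case in list(c(6, 15), c(3, 14), c(1, 10), c(14, 15))) {
    x <- case[1]; n <- case[2]
    ci <- exact_binomial_ci(x, n)
    # P(X >= x | p = lower) = alpha/2 ; P(X <= x | p = upper) = alpha/2
    expect_equal(sum(dbinom(x:n, n, ci$lower)), 0.025, tolerance = 1e-9)
    expect_equal(sum(dbinom(0:x, n, ci$upper)), 0.025, tolerance = 1e-9)
  }
  expect_equal(exact_binomial_ci(0, 10)$lower, 0)
  expect_equal(exact_binomial_ci(10, 10)$upper, 1)
  expect_error(exact_binomial_ci(11, 10), "x must be")
})

test_that("Fisher exact p equals full enumeration and fisher.test", {
  tab <- matrix(c(1, 9, 9, 1), 2)
  p <- fisher_exact_2x2(tab)
  # independent enumeration over all tables with the observed margins
  probs <- dhyper(0:10, 10, 10, 10)
  want <- sum(probs[probs <= dhyper(1, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(p, want, tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "degenerate")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("Wilcoxon rank-sum: exact enumeration for small n, ties approx", {
  w <- wilcoxon_rank_sum(1:3, 4:6)
  # most extreme of the choose(6,3)=20 assignments, symmetric two-sided
  expect_equal(w$p_value, 2 / 20)
  expect_identical(w$method, "exact enumeration")
  expect_equal(wilcoxon_rank_sum(c(1, 3, 5), c(1, 3, 5))$p_value, 1)
  set.seed(31)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  pw <- wilcoxon_rank_sum(a, b)$p_value
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(pw, ref, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("survival_by_ctdna separates planted hazard groups at n = 60", {
  cc <- generate_cohort(sim_config(n_patients = 60L), seed = 101L)
  v <- validate_variant_table(transform(cc$variants,
                                        maf = maf_fraction))
  cl <- classify_cohort(v, cc$manifest,
                        validate_cosmic_annotations(cc$cosmic))
  tr <- build_trajectories(cl$origins, v, cc$manifest)
  cmp <- survival_by_ctdna(tr$trajectories, cc$outcomes, "POSTOP", "RFS")
  med <- function(x) if (is.na(x)) Inf else x
  expect_lt(med(cmp$medians[["DETECTED"]]),
            med(cmp$medians[["UNDETECTED"]]))
  expect_lt(cmp$logrank$p_value, 0.05)
  # UD patients join only the three-way comparison as their own stratum
  cmp3 <- survival_by_ctdna(tr$trajectories, cc$outcomes, "POSTOP",
                            "RFS", three_way = TRUE)
  expect_true("UD" %in% names(cmp3$groups))
  expect_equal(cmp3$logrank$df, 2L)
  expect_false("UD" %in% names(cmp$groups))
  # single-group comparison warns and skips the test
  one <- tr$trajectories[tr$trajectories$evaluability == "UD", ]
  expect_warning(
    res <- survival_by_ctdna(one, cc$outcomes, "POSTOP", "RFS",
                             three_way = TRUE),
    "skipped")
  expect_null(res$logrank)
})

test_that("day-to-month conversion uses the mean Gregorian month", {
  expect_equal(days_to_months(30.4375), 1)
  expect_equal(days_to_months(365.25), 12)
})
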