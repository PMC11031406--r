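## The trial's statistical toolkit: pathological tumor regression grading,
## Kaplan-Meier with Greenwood log-log pointwise CIs, log-rank tests,
## Clopper-Pearson exact binomial CIs, Fisher exact and Wilcoxon rank-sum
## tests, and the grouping of survival endpoints by ctDNA status.
## All tests are two-sided; no multiplicity adjustment.

DAYS_PER_MONTH <- 30.4375

#' Convert days to months
#'
#' @param days numeric vector of day counts.
#' @return months, using the mean Gregorian month of 30.4375 days.
#' @export
days_to_months <- function(days) days / DAYS_PER_MONTH

#' Pathological tumor regression grading
#'
#' Maps percent residual viable tumor (assessed in 5% increments of the
#' tumor bed) to the four-level CAP/modified-Ryan grade: 0% -> G0
#' (complete response), (0, 10] -> G1, (10, 50] -> G2, (50, 100] -> G3.
#' pCR is grade G0; major pathological response (MPR) is residual viable
#' tumor <= 10%. Boundary values fall in the lower-numbered grade band.
#'
#' @param residual_viable_tumor_pct numeric vector in \[0, 100\]
#'   (NA allowed, propagated).
#' @return data.frame with `residual_viable_tumor_pct`, `cap_grade`,
#'   `pcr`, `mpr`.
#' @export
grade_regression <- function(residual_viable_tumor_pct) {
  x <- as.numeric(residual_viable_tumor_pct)
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop("validation error: residual viable tumor % outside [0,100] at ",
         "position(s) ", paste(bad, collapse = ", "))
  }
  grade <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  grade[ok & x == 0] <- "G0"
  grade[ok & x > 0 & x <= 10] <- "G1"
  grade[ok & x > 10 & x <= 50] <- "G2"
  grade[ok & x > 50] <- "G3"
  data.frame(residual_viable_tumor_pct = x, cap_grade = grade,
             pcr = ifelse(ok, x == 0, NA),
             mpr = ifelse(ok, x <= 10, NA))
}

#' Kaplan-Meier product-limit estimate with Greenwood log-log CI
#'
#' Computes the product-limit survival estimate, the Greenwood variance,
#' and pointwise confidence bounds on the complementary log-log scale
#' (the standard delta-method form: CI = S^exp(+-z * se(log(-log S)))),
#' which keeps the bounds inside \[0, 1\]. The median is the earliest
#' event time at which S(t) <= 0.5, or `NA` (not reached).
#'
#' @param time nonnegative follow-up times (months).
#' @param event logical or 0/1 event indicators (TRUE = event).
#' @param conf_level confidence level, default 0.95.
#' @return object of class `km_curve`: data.frame-like list with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`,
#'   `ci_lower`, `ci_upper` at each distinct event time, plus attributes
#'   `median` and `n`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) < 1L) stop("need at least one subject")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(is.na(event))) stop("NA in time or event")
  if (any(time < 0)) stop("validation error: negative time")

  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  dt <- sort(unique(time[event]))
  n_risk <- vapply(dt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(dt, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(dt, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  green <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  std_err <- surv * sqrt(green)          # Greenwood SE of S(t)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # se on the log(-log S) scale; degenerate at S in {0, 1}
  ll_se <- ifelse(surv > 0 & surv < 1, sqrt(green) / abs(log(surv)), NA_real_)
  ci_lower <- ifelse(is.na(ll_se), ifelse(surv == 0, 0, NA_real_),
                     surv^exp(z * ll_se))
  ci_upper <- ifelse(is.na(ll_se), ifelse(surv == 0, 0, NA_real_),
                     surv^exp(-z * ll_se))
  med <- if (any(surv <= 0.5)) dt[which(surv <= 0.5)[1L]] else NA_real_
  out <- data.frame(time = dt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv,
                    std_err = std_err, ci_lower = ci_lower,
                    ci_upper = ci_upper)
  attr(out, "median") <- med
  attr(out, "n") <- n
  attr(out, "conf_level") <- conf_level
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  med <- attr(x, "median")
  cat("Kaplan-Meier estimate (n = ", attr(x, "n"), "), median = ",
      if (is.na(med)) "not reached" else format(med), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Median survival of a fitted curve
#'
#' @param km object from [km_estimate()].
#' @return earliest time with S(t) <= 0.5, or `NA` when not reached.
#' @export
km_median <- function(km) attr(km, "median")

#' Unweighted log-rank test over k groups
#'
#' Standard (unweighted) log-rank statistic over pooled event times with
#' the hypergeometric variance for ties; two-sided p from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param time,event follow-up times and event indicators.
#' @param group group labels (>= 2 nonempty groups).
#' @return list with `chi_square`, `df`, `p_value`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.logical(event)
  group <- as.character(group)
  if (any(is.na(group))) stop("NA group label")
  levels <- sort(unique(group))
  k <- length(levels)
  if (k < 2L) stop("validation error: need at least two nonempty groups")
  if (any(time < 0)) stop("validation error: negative time")
  g <- match(group, levels)
  dt <- sort(unique(time[event]))
  obs <- exp <- numeric(k)
  V <- matrix(0, k, k)
  for (t in dt) {
    at <- time >= t
    n <- sum(at)
    d <- sum(time == t & event)
    nj <- vapply(seq_len(k), function(j) sum(at & g == j), numeric(1))
    dj <- vapply(seq_len(k), function(j) sum(time == t & event & g == j),
                 numeric(1))
    obs <- obs + dj
    exp <- exp + d * nj / n
    if (n > 1) {
      vt <- d * (n - d) / (n - 1) *
        (diag(nj / n, k) - tcrossprod(nj / n))
      V <- V + vt
    }
  }
  u <- (obs - exp)[-k]
  Vr <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(as.numeric(t(u) %*% solve(Vr, u)),
                  error = function(e) {
                    # singular variance (e.g. no events): statistic is 0
                    if (sum(abs(u)) < 1e-12) 0 else stop(e)
                  })
  df <- k - 1L
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE),
       observed = stats::setNames(obs, levels),
       expected = stats::setNames(exp, levels))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval by beta-quantile inversion of the binomial tails:
#' lower = qbeta(alpha/2; x, n - x + 1) (0 when x = 0),
#' upper = qbeta(1 - alpha/2; x + 1, n - x) (1 when x = n).
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n >= 1`.
#' @param conf_level confidence level, default 0.95.
#' @return list with `estimate`, `lower`, `upper` (fractions) and
#'   `percent` (estimate and bounds as percentages rounded to one
#'   decimal, the trial's reporting convention).
#' @export
exact_binomial_ci <- function(x, n, conf_level = 0.95) {
  if (n < 1L) stop("validation error: n must be >= 1")
  if (x < 0L || x > n) stop("validation error: x must be in [0, n]")
  alpha <- 1 - conf_level
  lower <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  list(estimate = x / n, lower = lower, upper = upper,
       percent = round(100 * c(estimate = x / n, lower = lower,
                               upper = upper), 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities no larger than that of the observed table (with the
#' conventional 1e-7 relative tolerance for ties).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("validation error: negative cell")
  if (any(tab != round(tab))) stop("validation error: non-integer cell")
  m <- sum(tab[1L, ])          # row 1 margin
  n2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])         # column 1 margin
  total <- m + n2
  if (total == 0L) stop("validation error: degenerate all-zero table")
  lo <- max(0L, c1 - n2)
  hi <- min(m, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n2, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by complete enumeration of rank assignments when the
#' combined sample size is at most `exact_max` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric samples, both nonempty.
#' @param exact_max combined-size switch for the exact enumeration
#'   (default 20).
#' @return list with `statistic` (Mann-Whitney U for sample `a`),
#'   `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("validation error: empty sample")
  }
  z <- c(a, b)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(z)
  w <- sum(r[seq_len(n1)])               # rank sum of sample a
  u <- w - n1 * (n1 + 1) / 2             # Mann-Whitney U
  ties <- any(duplicated(z))
  if (!ties && n <= exact_max) {
    combs <- utils::combn(n, n1)
    ranks <- rank(z)                     # a permutation of 1..n (no ties)
    ws <- colSums(matrix(ranks[combs], nrow = n1))
    d_obs <- abs(w - n1 * (n + 1) / 2)
    p <- mean(abs(ws - n1 * (n + 1) / 2) >= d_obs - 1e-9)
    return(list(statistic = u, p_value = p, method = "exact enumeration"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(z)
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  cc <- sign(u - mu) * 0.5               # continuity correction
  zstat <- (u - mu - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(zstat))
  list(statistic = u, p_value = min(1, p),
       method = "normal approximation with tie correction")
}

#' Survival grouped by ctDNA status at a timepoint
#'
#' Joins trajectories to outcomes and compares RFS or OS between patients
#' with detectable vs undetectable ctDNA at the post-ICI, preoperative or
#' postoperative timepoint. The undetectable-at-all-timepoints (UD) group
#' is excluded from the two-way comparison and carried as its own stratum
#' in the three-way comparison. Patients NOT_ASSESSED at the queried
#' timepoint are dropped.
#'
#' @param trajectories trajectory table from [build_trajectories()].
#' @param outcomes outcome table ([read_outcome_table()]).
#' @param timepoint `"POST_ICI"`, `"PREOP"` or `"POSTOP"`.
#' @param endpoint `"RFS"` or `"OS"`.
#' @param three_way add the UD stratum as a third group.
#' @return list with `groups` (named list of `km_curve`), `medians`,
#'   `logrank` (or `NULL` with a warning when fewer than two groups have
#'   subjects), `n_per_group`.
#' @export
survival_by_ctdna <- function(trajectories, outcomes,
                              timepoint = c("POST_ICI", "PREOP", "POSTOP"),
                              endpoint = c("RFS", "OS"),
                              three_way = FALSE) {
  timepoint <- match.arg(timepoint)
  endpoint <- match.arg(endpoint)
  col <- c(POST_ICI = "post_ici_status", PREOP = "preop_status",
           POSTOP = "postop_status")[[timepoint]]
  d <- merge(trajectories, outcomes, by = "patient_id")
  tcol <- if (endpoint == "RFS") "rfs_months" else "os_months"
  ecol <- if (endpoint == "RFS") "rfs_event" else "os_event"
  d <- d[!is.na(d[[tcol]]) & !is.na(d[[ecol]]), , drop = FALSE]

  grp <- rep(NA_character_, nrow(d))
  ud <- d$evaluability == "UD"
  grp[!ud & d[[col]] == "POSITIVE"] <- "DETECTED"
  grp[!ud & d[[col]] == "NEGATIVE"] <- "UNDETECTED"
  if (three_way) grp[ud] <- "UD"
  keep <- !is.na(grp)
  d <- d[keep, , drop = FALSE]
  grp <- grp[keep]

  groups <- split(seq_len(nrow(d)), grp)
  kms <- lapply(groups, function(i) km_estimate(d[[tcol]][i], d[[ecol]][i]))
  medians <- vapply(kms, km_median, numeric(1))
  lr <- NULL
  if (length(groups) >= 2L) {
    lr <- logrank_test(d[[tcol]], d[[ecol]], grp)
  } else {
    warning("fewer than two groups with subjects; log-rank test skipped")
  }
  list(timepoint = timepoint, endpoint = endpoint, groups = kms,
       medians = medians, logrank = lr,
       n_per_group = vapply(groups, length, integer(1)))
}
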