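## Bayesian beta-binomial continuous monitoring rules: a beta prior on an
## adverse-event (or feasibility) rate, updated after every patient, with
## accrual suspended when the posterior probability of crossing the rate
## threshold reaches the trigger level.

#' Define a monitoring rule
#'
#' @param prior_a,prior_b beta prior hyperparameters (> 0).
#' @param rate_threshold the rate theta being monitored (for example 0.30
#'   for grade 3-4 pneumonitis/respiratory failure, 0.10 for grade 5
#'   events, 0.75 for on-time surgery feasibility).
#' @param posterior_trigger gamma in (0, 1): suspend when the posterior
#'   probability of crossing theta reaches gamma (0.70 for the toxicity
#'   rule; the grade-5 and feasibility triggers are not printed in the
#'   protocol summary and default to 0.70 by parallel construction —
#'   flagged as an assumption, configurable).
#' @param direction `"ABOVE"` monitors P(p > theta); `"BELOW"` monitors
#'   P(p < theta) (feasibility).
#' @return object of class `monitoring_rule`.
#' @export
monitoring_rule <- function(prior_a, prior_b, rate_threshold,
                            posterior_trigger = 0.70,
                            direction = c("ABOVE", "BELOW")) {
  direction <- match.arg(direction)
  if (prior_a <= 0 || prior_b <= 0) stop("hyperparameters must be positive")
  if (rate_threshold <= 0 || rate_threshold >= 1) {
    stop("rate_threshold must be in (0, 1)")
  }
  if (posterior_trigger <= 0 || posterior_trigger >= 1) {
    stop("posterior_trigger must be in (0, 1)")
  }
  structure(list(prior_a = prior_a, prior_b = prior_b,
                 rate_threshold = rate_threshold,
                 posterior_trigger = posterior_trigger,
                 direction = direction),
            class = "monitoring_rule")
}

#' @export
print.monitoring_rule <- function(x, ...) {
  cat(sprintf(
    "Beta(%g, %g) prior; trigger when P(p %s %g) >= %g\n",
    x$prior_a, x$prior_b, if (x$direction == "ABOVE") ">" else "<",
    x$rate_threshold, x$posterior_trigger))
  invisible(x)
}

#' Calibrate a beta prior from its mean and one tail probability
#'
#' Solves for Beta(a, b) on the one-parameter family b = a(1 - m)/m (so
#' the mean is m) such that P(p >= tail_point) = tail_prob. Along this
#' family the tail probability is unimodal in a: it tends to m as a -> 0
#' (mass piling at 0 and 1) and to 0 (tail_point > m) or 1
#' (tail_point < m) as a -> infinity. When two solutions exist the one on
#' the concentrated (informative, larger effective-sample-size) branch is
#' returned. Integer hyperparameters are reported alongside the raw
#' solution when an integer (a, round(b)) reproduces the tail within
#' `snap_tol`.
#'
#' @param prior_mean m in (0, 1).
#' @param tail_point rate at which the tail is stated, in (0, 1).
#' @param tail_prob stated P(p >= tail_point), in (0, 1).
#' @param tol tolerance on the achieved tail probability (default 1e-6).
#' @param snap_tol tail-probability tolerance for integer snapping.
#' @return list with `a`, `b`, `tail_achieved`, and (when available)
#'   `a_int`, `b_int`, `tail_int`.
#' @export
calibrate_beta_prior <- function(prior_mean, tail_point, tail_prob,
                                 tol = 1e-6, snap_tol = 0.02) {
  stopifnot(prior_mean > 0, prior_mean < 1, tail_point > 0, tail_point < 1,
            tail_prob > 0, tail_prob < 1)
  ratio <- (1 - prior_mean) / prior_mean
  tail <- function(a) {
    stats::pbeta(tail_point, a, a * ratio, lower.tail = FALSE)
  }
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 400L))
  tg <- vapply(grid, tail, numeric(1))
  i_peak <- which.max(if (tail_point > prior_mean) tg else -tg)
  # concentrated branch: a beyond the turning point
  branch <- grid[i_peak:length(grid)]
  tb <- tg[i_peak:length(grid)]
  f <- function(a) tail(a) - tail_prob
  sgn <- sign(tb - tail_prob)
  cross <- which(diff(sgn) != 0)
  if (length(cross) == 0L) {
    # target beyond the attainable range on this branch; fall back to the
    # full grid before declaring failure
    sgn_all <- sign(tg - tail_prob)
    cross_all <- which(diff(sgn_all) != 0)
    if (length(cross_all) == 0L) {
      stop("calibration error: no (a, b) with mean ", prior_mean,
           " attains P(p >= ", tail_point, ") = ", tail_prob,
           " for a in (1e-3, 1e3); attainable range is (",
           signif(min(tg), 4), ", ", signif(max(tg), 4), ")")
    }
    lo <- grid[cross_all[1L]]; hi <- grid[cross_all[1L] + 1L]
  } else {
    lo <- branch[cross[1L]]; hi <- branch[cross[1L] + 1L]
  }
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  b <- a * ratio
  achieved <- tail(a)
  if (abs(achieved - tail_prob) > tol) {
    stop("calibration error: tail probability solved to ", achieved,
         ", outside tolerance ", tol)
  }
  out <- list(a = a, b = b, tail_achieved = achieved)
  # integer snapping: prefer the integer pair closest to the target tail
  cand_a <- unique(pmax(1L, c(floor(a), ceiling(a), round(a))))
  cand <- lapply(cand_a, function(ai) {
    bi <- max(1L, round(ai * ratio))
    list(a_int = ai, b_int = bi,
         tail_int = stats::pbeta(tail_point, ai, bi, lower.tail = FALSE))
  })
  errs <- vapply(cand, function(cc) abs(cc$tail_int - tail_prob), numeric(1))
  best <- cand[[which.min(errs)]]
  if (min(errs) <= snap_tol) out <- c(out, best)
  out
}

#' Posterior exceedance probability of a monitoring rule
#'
#' With x events in n patients the posterior is
#' Beta(a + x, b + n - x); the rule reports P(p > theta) (ABOVE) or
#' P(p < theta) (BELOW) and whether the trigger level is reached.
#'
#' @param rule a [monitoring_rule()].
#' @param x_events events observed, `0 <= x <= n`.
#' @param n_patients patients observed.
#' @return list with `probability`, `trigger`, `posterior_a`,
#'   `posterior_b`.
#' @export
posterior_exceedance <- function(rule, x_events, n_patients) {
  stopifnot(inherits(rule, "monitoring_rule"))
  if (n_patients < 0 || x_events < 0 || x_events > n_patients) {
    stop("validation error: need 0 <= x_events <= n_patients")
  }
  a <- rule$prior_a + x_events
  b <- rule$prior_b + n_patients - x_events
  p <- stats::pbeta(rule$rate_threshold, a, b,
                    lower.tail = (rule$direction == "BELOW"))
  list(probability = p, trigger = p >= rule$posterior_trigger,
       posterior_a = a, posterior_b = b)
}

#' Stopping boundary of a monitoring rule
#'
#' For each interim sample size n = 1..n_max, the smallest event count x
#' whose posterior reaches the trigger (NA when no x in 0..n does). For an
#' ABOVE rule the exceedance probability is increasing in x, so a direct
#' scan suffices and the boundary is non-decreasing in n.
#'
#' @param rule a [monitoring_rule()].
#' @param n_max largest interim sample size.
#' @return data.frame with `n`, `min_trigger_events`,
#'   `posterior_at_boundary`.
#' @export
stopping_boundary <- function(rule, n_max) {
  stopifnot(inherits(rule, "monitoring_rule"), n_max >= 1)
  rows <- lapply(seq_len(n_max), function(n) {
    xs <- 0:n
    probs <- vapply(xs, function(x) {
      posterior_exceedance(rule, x, n)$probability
    }, numeric(1))
    hit <- which(probs >= rule$posterior_trigger)
    data.frame(
      n = n,
      min_trigger_events = if (length(hit)) xs[hit[1L]] else NA_integer_,
      posterior_at_boundary = if (length(hit)) probs[hit[1L]] else NA_real_)
  })
  do.call(rbind, rows)
}
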