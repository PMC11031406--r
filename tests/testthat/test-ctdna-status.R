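# Build a small hand-wired cohort: one patient, one tumor variant, one CH
# variant, with full control over which timepoints carry the tumor MAF.
wire_cohort <- function(tumor_maf_by_tp, patient = "P1") {
  man <- mini_manifest(patient)
  tps <- c("BASELINE", "D14", "POST_ICI", "PREOP", "POSTOP")
  rows <- list()
  for (tp in names(tumor_maf_by_tp)) {
    m <- tumor_maf_by_tp[[tp]]
    if (m > 0) {
      rows[[length(rows) + 1L]] <-
        make_obs(m, patient = patient,
                 sample = paste0(patient, "_P_", tp))
    }
  }
  # stable CH variant in every plasma sample and WBC
  for (tp in tps) {
    rows[[length(rows) + 1L]] <-
      make_obs(0.01, patient = patient, pos = 900L, ref = "G", alt = "A",
               gene = "DNMT3A", sample = paste0(patient, "_P_", tp))
  }
  rows[[length(rows) + 1L]] <-
    make_obs(0.01, smc = 5L, patient = patient, pos = 900L, ref = "G",
             alt = "A", gene = "DNMT3A",
             sample = paste0(patient, "_WBC"))
  v <- validate_variant_table(do.call(rbind, rows))
  cos <- validate_cosmic_annotations(
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               total_occurrences = integer(0),
               heme_lymphoid_occurrences = integer(0)))
  cl <- classify_cohort(v, man, cos)
  list(variants = v, manifest = man, origins = cl$origins)
}

test_that("timepoint calls follow the any-MAF rule and cfTL definition", {
  w <- wire_cohort(list(BASELINE = 0.0008, D14 = 0, POST_ICI = 0,
                        PREOP = 0, POSTOP = 0))
  call <- call_timepoint("P1", "BASELINE", w$origins, w$variants,
                         w$manifest)
  expect_identical(call$status, "POSITIVE")
  expect_equal(call$cftl, 0.0008)        # detection at any MAF, no floor
  # CH variant alone does not make a timepoint positive
  call2 <- call_timepoint("P1", "PREOP", w$origins, w$variants,
                          w$manifest)
  expect_identical(call2$status, "NEGATIVE")
  expect_equal(call2$cftl, 0)
  # timepoint without a plasma sample is NOT_ASSESSED, not an error
  man2 <- w$manifest[w$manifest$timepoint != "D14" |
                       w$manifest$material != "PLASMA", ]
  call3 <- call_timepoint("P1", "D14", w$origins, w$variants, man2)
  expect_identical(call3$status, "NOT_ASSESSED")
})

test_that("cfTL is the max tumor MAF and is monotone under inclusion", {
  w <- wire_cohort(list(BASELINE = 0.004))
  extra <- make_obs(0.009, pos = 500L, ref = "C", alt = "T",
                    sample = "P1_P_BASELINE")
  v2 <- validate_variant_table(rbind(w$variants[, names(w$variants) !=
                                                  "key"], extra))
  cl2 <- classify_cohort(v2, w$manifest, validate_cosmic_annotations(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), total_occurrences = integer(0),
               heme_lymphoid_occurrences = integer(0))))
  c1 <- call_timepoint("P1", "BASELINE", w$origins, w$variants,
                       w$manifest)
  c2 <- call_timepoint("P1", "BASELINE", cl2$origins, v2, w$manifest)
  expect_equal(c1$cftl, 0.004)
  expect_equal(c2$cftl, 0.009)           # adding a variant never lowers cfTL
  expect_gte(c2$cftl, c1$cftl)
  c3 <- call_timepoint("P1", "BASELINE", cl2$origins, v2, w$manifest,
                       cftl_mode = "mean")
  expect_equal(c3$cftl, mean(c(0.004, 0.009)))
})

test_that("evaluability: UD iff never positive; all-missing errors", {
  expect_identical(classify_evaluability(
    c(rep("NEGATIVE", 5))), "UD")
  expect_identical(classify_evaluability(
    c("NEGATIVE", "NOT_ASSESSED", "NEGATIVE", "POSITIVE", "NEGATIVE")),
    "EVALUABLE")
  expect_error(classify_evaluability(rep("NOT_ASSESSED", 5)),
               "no assessed")
})

test_that("clearance patterns follow the precedence mapping", {
  tp <- c("BASELINE", "D14", "POST_ICI", "PREOP", "POSTOP")
  st <- function(...) stats::setNames(c(...), tp)
  P <- "POSITIVE"; N <- "NEGATIVE"; X <- "NOT_ASSESSED"
  expect_identical(summarize_clearance(st(P, N, N, N, N)),
                   "SUSTAINED_CLEARANCE")
  expect_identical(summarize_clearance(st(P, P, P, P, P)), "PERSISTENT")
  expect_identical(summarize_clearance(st(P, P, N, N, N)),
                   "CLEARED_POST_ICI")
  expect_identical(summarize_clearance(st(P, P, P, N, N)),
                   "CLEARED_PREOP")
  expect_identical(summarize_clearance(st(P, P, P, P, N)),
                   "CLEARED_POSTOP")
  # re-detection after a negative is MIXED
  expect_identical(summarize_clearance(st(P, X, N, P, N)), "MIXED")
  expect_identical(summarize_clearance(st(N, N, N, N, N)), "UD")
  # NOT_ASSESSED timepoints drop out of the quantifiers: with only two
  # assessed post-baseline draws, both negative, clearance is sustained
  expect_identical(summarize_clearance(st(P, X, N, X, N)),
                   "SUSTAINED_CLEARANCE")
})

test_that("trajectories and status tables are invariant to row order", {
  w <- wire_cohort(list(BASELINE = 0.004, D14 = 0.003))
  t1 <- build_trajectories(w$origins, w$variants, w$manifest)
  shuf <- w$variants[rev(seq_len(nrow(w$variants))), ]
  t2 <- build_trajectories(w$origins, shuf, w$manifest)
  expect_equal(t1$trajectories, t2$trajectories)
  expect_identical(t1$trajectories$pattern, "CLEARED_POST_ICI")
  # CH/germline MAF changes do not move status calls
  v3 <- w$variants
  v3$maf[v3$pos == 900L & grepl("_P_", v3$sample_id)] <- 0.04
  t3 <- build_trajectories(w$origins, v3, w$manifest)
  expect_equal(t1$trajectories$pattern, t3$trajectories$pattern)
})

test_that("cohort clearance counts match generator bookkeeping", {
  cc <- generate_cohort(sim_config(n_patients = 48L), seed = 23L)
  v <- validate_variant_table(transform(cc$variants,
                                        maf = maf_fraction))
  cl <- classify_cohort(v, cc$manifest,
                        validate_cosmic_annotations(cc$cosmic))
  tr <- build_trajectories(cl$origins, v, cc$manifest)
  tab <- cohort_status_table(tr$trajectories)
  truth <- cc$truth_patients
  base_pos <- truth$realized_baseline_detected
  for (tp in c("post_ici", "preop", "postop")) {
    want <- sum(base_pos & !truth[[paste0("realized_", tp,
                                          "_detected")]])
    got <- tab$n_undetectable[tab$timepoint == toupper(tp)]
    expect_equal(got, want, label = tp)
  }
  expect_equal(attr(tab, "n_baseline_positive"), sum(base_pos))
  # realized clearance patterns are recovered exactly
  j <- merge(tr$trajectories[, c("patient_id", "pattern")],
             truth[, c("patient_id", "realized_pattern")])
  expect_identical(j$pattern, j$realized_pattern)
})

test_that("a cohort where no one clears reports zero clearance", {
  cc <- generate_cohort(sim_config(n_patients = 24L, p_clear = 0,
                                   fn_at_band = 0, fn_at_floor = 0),
                        seed = 9L)
  v <- validate_variant_table(transform(cc$variants,
                                        maf = maf_fraction))
  cl <- classify_cohort(v, cc$manifest,
                        validate_cosmic_annotations(cc$cosmic))
  tr <- build_trajectories(cl$origins, v, cc$manifest)
  tab <- cohort_status_table(tr$trajectories)
  expect_true(all(tab$n_undetectable == 0L))
})
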