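test_that("hotspot annotation uses the inclusive 25-occurrence boundary", {
  hs <- annotate_hotspot(c(25L, 24L, 0L, 30L), c(0L, 0L, 0L, 4L))
  expect_equal(hs$is_hotspot, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(hs$heme_fraction, c(0, 0, 0, 4 / 30))
  expect_error(annotate_hotspot(3L, 5L), "exceed")
})

test_that("germline rule: nonhotspot, >=25% VAF in WBC and all plasma", {
  expect_true(apply_germline_rule(c(0.48, 0.51, 0.47), NULL, 0.52, FALSE))
  expect_false(apply_germline_rule(c(0.48, 0.20), NULL, 0.52, FALSE))
  # hotspots are never germline-eligible, even at 50% VAF everywhere
  expect_false(apply_germline_rule(c(0.5, 0.5), NULL, 0.5, TRUE))
  # inclusive boundary at exactly 25%
  expect_true(apply_germline_rule(c(0.25, 0.25), NULL, 0.25, FALSE))
  # dropout sample below the coverage floor does not veto
  expect_true(apply_germline_rule(c(0.5, 0.1), c(2000L, 5L), 0.5, FALSE))
  expect_false(apply_germline_rule(c(0.5, 0.1), c(2000L, 50L), 0.5, FALSE))
  expect_false(apply_germline_rule(c(0.5), NULL, NA_real_, FALSE))
  expect_error(apply_germline_rule(numeric(0), NULL, 0.5, FALSE),
               "no plasma")
})

test_that("classifier agrees with the brute-force rule table everywhere", {
  grid <- expand.grid(hotspot = c(TRUE, FALSE),
                      germline_pattern = c(TRUE, FALSE),
                      s = c(0L, 1L, 2L, 3L, 5L),
                      heme = c(0, 0.09, 0.10, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- classify_from_features(g$hotspot, g$germline_pattern, g$s,
                                  g$heme)
    want <- oracle_origin(g$hotspot, g$germline_pattern, g$s,
                          res$actual_heme_frac)
    expect_identical(res$call$origin, want,
                     label = sprintf("cell (hs=%s, germ=%s, s=%d, heme=%g): %s",
                                     g$hotspot, g$germline_pattern, g$s,
                                     g$heme, res$call$origin))
    expect_gt(length(res$call$rule_path), 0L)
  }
})

test_that("classifier matches the oracle on random feature tuples", {
  set.seed(41)
  for (i in 1:200) {
    hotspot <- runif(1) < 0.5
    germ <- runif(1) < 0.3
    s <- sample(0:6, 1L)
    heme <- sample(c(0, runif(1)), 1L)
    res <- classify_from_features(hotspot, germ, s, heme)
    expect_identical(res$call$origin,
                     oracle_origin(hotspot, germ, s,
                                   res$actual_heme_frac))
  }
})

test_that("worked example: hotspot 4/30 heme occurrences, s = 2 is CH", {
  # 4/30 = 0.133 >= 0.10 -> CH on the hotspot residual band
  plasma <- make_obs(c(0.004, 0.005))
  wbc <- make_obs(0.001, smc = 2L, sample = "W")
  call <- classify_variant(plasma, wbc, 30L, 4L)
  expect_identical(call$origin, "CH")
  expect_equal(call$heme_fraction, 4 / 30)
  expect_true("heme_fraction_ge10pct_ch" %in% call$rule_path)
})

test_that("monotonicity and germline-insensitivity properties hold", {
  plasma <- make_obs(c(0.003, 0.004))
  # raising the WBC super-mutant count never flips CH to TUMOR
  prev <- NULL
  for (s in 0:6) {
    wbc <- if (s > 0) make_obs(0.002, smc = s, sample = "W") else NULL
    o <- classify_variant(plasma, wbc, 100L, 5L)$origin  # hotspot, heme 5%
    if (!is.null(prev) && prev == "CH") expect_identical(o, "CH")
    prev <- o
  }
  # absent from WBC always lands on the tumor branch for nongermline
  expect_identical(classify_variant(plasma, NULL, 0L, 0L)$origin, "TUMOR")
  # germline pattern wins regardless of s and heme fraction
  gp <- make_obs(c(0.5, 0.49))
  for (s in c(0L, 2L, 5L)) {
    wbc <- make_obs(0.5, smc = s, sample = "W")
    expect_identical(classify_variant(gp, wbc, 20L, 10L)$origin,
                     "GERMLINE")
  }
})

test_that("classify_cohort partitions patient-variants and errors on missing WBC", {
  cc <- generate_cohort(sim_config(n_patients = 16L), seed = 5L)
  v <- validate_variant_table(transform(cc$variants,
                                        maf = maf_fraction))
  cos <- validate_cosmic_annotations(cc$cosmic)
  cl <- classify_cohort(v, cc$manifest, cos)
  expect_equal(sum(cl$summary$variant_counts), cl$summary$n_variants)
  expect_equal(anyDuplicated(paste(cl$origins$patient_id,
                                   cl$origins$key)), 0L)
  # planted origins are recovered exactly on well-separated features
  j <- merge(cl$origins[, c("patient_id", "key", "origin")],
             cc$truth_variants[, c("patient_id", "key", "true_origin")])
  expect_equal(nrow(j), nrow(cl$origins))
  expect_identical(j$origin, j$true_origin)
  # removing the WBC sample of a patient with plasma variants errors
  has_var <- unique(v$patient_id)[1L]
  man2 <- cc$manifest[!(cc$manifest$patient_id == has_var &
                          cc$manifest$material == "WBC"), ]
  expect_error(classify_cohort(v, man2, cos), "no WBC sample")
})

test_that("a germline-only cohort yields no CH or tumor calls", {
  man <- mini_manifest()
  plasma <- do.call(rbind, lapply(1:5, function(i) {
    make_obs(0.5, sample = man$sample_id[i])
  }))
  wbc <- make_obs(0.5, sample = "P1_WBC")
  cl <- classify_cohort(validate_variant_table(rbind(plasma, wbc)), man,
                        validate_cosmic_annotations(
                          data.frame(chrom = character(0),
                                     pos = integer(0), ref = character(0),
                                     alt = character(0),
                                     total_occurrences = integer(0),
                                     heme_lymphoid_occurrences = integer(0))))
  expect_equal(unname(cl$summary$variant_counts[c("CH", "TUMOR")]),
               c(0L, 0L))
  expect_equal(unname(cl$summary$variant_counts[["GERMLINE"]]), 1L)
})
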