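## Fully synthetic trial cohorts with ground-truth bookkeeping.
##
## The generator emulates the data shapes of a serial liquid-biopsy trial:
## per-patient plasma samples at five timepoints plus one matched baseline
## WBC sample; germline variants at ~50% VAF everywhere; CH variants
## present in WBC with nonzero super-mutant counts and stable plasma VAF;
## tumor variants with baseline MAF straddling the assay's stated
## 0.25-1.0% sensitivity band, stepping to zero at a per-patient clearance
## timepoint for responders; recurrence hazard multiplied for
## non-clearing patients. Detection applies a false-negative model below
## the sensitivity band (a stand-in for assay sensitivity, not a
## published value).

PANEL_GENES_TUMOR <- c("TP53", "KRAS", "PIK3CA", "ERBB2", "ARID1A",
                       "SMAD4", "CDKN2A", "CTNNB1", "APC", "FBXW7")
PANEL_GENES_CH <- c("DNMT3A", "TET2", "ASXL1", "PPM1D", "JAK2", "SF3B1")
COLLECTION_DAYS <- c(BASELINE = 0L, D14 = 14L, POST_ICI = 28L,
                     PREOP = 75L, POSTOP = 120L)

#' Synthetic cohort configuration
#'
#' Defaults echo the emulated trial: 32 patients; Poisson variant loads
#' with means 0.4 / 0.85 / 1.1 for germline / CH / tumor (the study's
#' 12 / 27 / 35 variants over 32 patients); germline VAF ~ Normal(0.5,
#' 0.03) truncated to \[0.3, 0.7\]; CH WBC super-mutant counts >= 1 with
#' P(count >= 3) = `ch_p_smc_ge3`; tumor baseline MAF log-uniform over
#' \[0.0005, 0.01\]; per-patient clearance with probability `p_clear` at a
#' uniformly drawn post-baseline timepoint; exponential recurrence-free
#' survival with the hazard multiplied by `hazard_ratio` for non-clearing
#' patients; administrative censoring at `horizon_months`.
#'
#' @param n_patients number of patients.
#' @param mean_germline,mean_ch,mean_tumor Poisson means of per-patient
#'   variant counts per origin class.
#' @param germline_vaf_mean,germline_vaf_sd,germline_vaf_range truncated
#'   normal for germline allele fractions.
#' @param ch_p_smc_ge3 probability a CH variant's WBC super-mutant count
#'   is >= 3 (otherwise 1 or 2, equiprobable).
#' @param ch_vaf_range log-uniform range of stable CH plasma VAF.
#' @param tumor_maf_range log-uniform range of tumor baseline MAF
#'   (fractions; default straddles the assay's 0.25-1.0% band).
#' @param p_hotspot_tumor,p_hotspot_ch probability a tumor / CH variant is
#'   a COSMIC hotspot.
#' @param p_wbc_contamination probability a hotspot tumor variant carries
#'   a WBC super-mutant count of 1-2 (buffy-coat contamination by
#'   circulating tumor cells).
#' @param fn_at_band,fn_floor_maf,fn_at_floor detection false-negative
#'   model: rate `fn_at_band` at MAF >= 0.25%, ramping linearly to
#'   `fn_at_floor` at `fn_floor_maf` and constant below (non-published
#'   stand-in for assay sensitivity).
#' @param p_clear probability a patient with tumor variants clears ctDNA.
#' @param rfs_median_cleared_months median RFS of clearing (and
#'   ctDNA-undetectable) patients; the exponential rate is log(2) / this.
#' @param hazard_ratio RFS hazard multiplier for non-clearing patients.
#' @param horizon_months administrative censoring horizon.
#' @param os_post_recurrence_mean_months mean exponential survival after
#'   recurrence (OS = RFS + this tail).
#' @param coverage_mu,coverage_size negative-binomial distinct-coverage
#'   model per observation.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 32L,
                       mean_germline = 0.4, mean_ch = 0.85,
                       mean_tumor = 1.1,
                       germline_vaf_mean = 0.5, germline_vaf_sd = 0.03,
                       germline_vaf_range = c(0.3, 0.7),
                       ch_p_smc_ge3 = 0.7,
                       ch_vaf_range = c(0.005, 0.05),
                       tumor_maf_range = c(0.0005, 0.01),
                       p_hotspot_tumor = 0.5, p_hotspot_ch = 0.3,
                       p_wbc_contamination = 0.3,
                       fn_at_band = 0.05, fn_floor_maf = 0.0005,
                       fn_at_floor = 0.5,
                       p_clear = 0.55,
                       rfs_median_cleared_months = 15,
                       hazard_ratio = 3,
                       horizon_months = 36,
                       os_post_recurrence_mean_months = 12,
                       coverage_mu = 2500, coverage_size = 20) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param cfg configuration list to validate.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stop("invalid config field: ", field)
  }
  chk(cfg$n_patients >= 1, "n_patients")
  for (f in c("mean_germline", "mean_ch", "mean_tumor")) chk(cfg[[f]] >= 0, f)
  for (f in c("ch_p_smc_ge3", "p_hotspot_tumor", "p_hotspot_ch",
              "p_wbc_contamination", "fn_at_band", "fn_at_floor",
              "p_clear")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  chk(cfg$hazard_ratio > 0, "hazard_ratio")
  chk(cfg$horizon_months > 0, "horizon_months")
  chk(cfg$rfs_median_cleared_months > 0, "rfs_median_cleared_months")
  chk(all(cfg$tumor_maf_range > 0) && diff(cfg$tumor_maf_range) >= 0,
      "tumor_maf_range")
  invisible(cfg)
}

.runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1L]), log(range[2L])))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

## detection false-negative probability as a function of MAF
.fn_rate <- function(maf, cfg) {
  band <- 0.0025  # lower edge of the stated 0.25-1.0% sensitivity band
  r <- cfg$fn_at_band +
    (cfg$fn_at_floor - cfg$fn_at_band) *
    pmax(0, pmin(1, (band - maf) / (band - cfg$fn_floor_maf)))
  pmin(pmax(r, 0), 1)
}

## independent bookkeeping of the clearance pattern implied by a logical
## detection vector over the five timepoints (deliberately coded apart
## from the analysis-side pattern mapping)
.pattern_from_detect <- function(det) {
  if (!any(det)) return("UD")
  post <- det[-1L]
  if (all(post)) return("PERSISTENT")
  if (!any(post)) return("SUSTAINED_CLEARANCE")
  runs <- rle(post)
  if (length(runs$values) > 2L || runs$values[1L] != TRUE) return("MIXED")
  first_clear <- sum(runs$lengths[1L]) + 2L  # index into TIMEPOINTS
  c("SUSTAINED_CLEARANCE", "SUSTAINED_CLEARANCE", "CLEARED_POST_ICI",
    "CLEARED_PREOP", "CLEARED_POSTOP")[first_clear]
}

#' Generate a synthetic trial cohort
#'
#' Emits the four analysis inputs (`variants.tsv`, `manifest.tsv`,
#' `cosmic.tsv`, `outcomes.tsv`) plus two truth tables
#' (`truth_variants.tsv`, `truth_patients.tsv`) that no analysis stage
#' ever reads. The truth tables record both the planted world (origins,
#' clearance timepoints, uncensored event times) and the realized
#' bookkeeping after detection sampling (which timepoints each patient's
#' ctDNA was actually emitted at), so pipeline recovery can be measured
#' against either.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; identical (config, seed) gives
#'   byte-identical outputs.
#' @param out_dir optional directory; when given, all six TSVs are
#'   written there.
#' @return list of data.frames: `variants`, `manifest`, `cosmic`,
#'   `outcomes`, `truth_variants`, `truth_patients`.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L,
                            out_dir = NULL) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n <- as.integer(config$n_patients)
  patients <- sprintf("SYN%03d", seq_len(n))

  ## manifest: five plasma draws plus one baseline WBC per patient
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      sample_id = c(paste0(patients[i], "_P_", TIMEPOINTS),
                    paste0(patients[i], "_WBC")),
      patient_id = patients[i],
      material = c(rep("PLASMA", 5L), "WBC"),
      timepoint = c(TIMEPOINTS, "BASELINE"),
      collection_day = c(unname(COLLECTION_DAYS), 0L),
      stringsAsFactors = FALSE)
  }))

  ## variant loads per patient and class
  n_germ <- stats::rpois(n, config$mean_germline)
  n_ch <- stats::rpois(n, config$mean_ch)
  n_tum <- stats::rpois(n, config$mean_tumor)
  n_var <- sum(n_germ) + sum(n_ch) + sum(n_tum)

  ## globally unique loci so COSMIC annotation is unambiguous
  pos_pool <- sample(1000000L:199000000L, n_var)
  bases <- c("A", "C", "G", "T")
  tv <- data.frame(
    patient_id = rep(patients, times = n_germ + n_ch + n_tum),
    true_origin = unlist(lapply(seq_len(n), function(i) {
      c(rep("GERMLINE", n_germ[i]), rep("CH", n_ch[i]),
        rep("TUMOR", n_tum[i]))
    })),
    chrom = as.character(sample(1:22, n_var, replace = TRUE)),
    pos = pos_pool,
    stringsAsFactors = FALSE)
  if (n_var > 0) {
    tv$ref <- sample(bases, n_var, replace = TRUE)
    tv$alt <- vapply(tv$ref, function(r) sample(setdiff(bases, r), 1L),
                     character(1))
    tv$gene <- ifelse(tv$true_origin == "CH",
                      sample(PANEL_GENES_CH, n_var, replace = TRUE),
                      sample(PANEL_GENES_TUMOR, n_var, replace = TRUE))
    tv$key <- paste(tv$chrom, tv$pos, tv$ref, tv$alt, sep = ":")
  } else {
    tv$ref <- tv$alt <- tv$gene <- tv$key <- character(0)
  }

  ## hotspot / heme-fraction plan and WBC super-mutant counts
  tv$is_hotspot <- FALSE
  tv$wbc_smc <- 0L
  is_ch <- tv$true_origin == "CH"
  is_tum <- tv$true_origin == "TUMOR"
  tv$is_hotspot[is_ch] <- stats::runif(sum(is_ch)) < config$p_hotspot_ch
  tv$is_hotspot[is_tum] <- stats::runif(sum(is_tum)) < config$p_hotspot_tumor
  ge3 <- stats::runif(sum(is_ch)) < config$ch_p_smc_ge3
  tv$wbc_smc[is_ch] <- ifelse(ge3, 3L + stats::rpois(sum(is_ch), 4),
                              sample(1:2, sum(is_ch), replace = TRUE))
  contam <- is_tum & tv$is_hotspot &
    stats::runif(nrow(tv)) < config$p_wbc_contamination
  tv$wbc_smc[contam] <- sample(1:2, sum(contam), replace = TRUE)

  cosmic <- .gen_cosmic(tv)

  ## per-patient clearance truth
  has_tumor <- n_tum > 0
  responder <- stats::runif(n) < config$p_clear
  clear_tp <- ifelse(responder & has_tumor,
                     sample(TIMEPOINTS[-1L], n, replace = TRUE), NA)
  clear_idx <- match(clear_tp, TIMEPOINTS)  # NA for non-clearing

  ## per-variant stable levels
  tv$level <- NA_real_
  tv$level[tv$true_origin == "GERMLINE"] <-
    .rtruncnorm(sum(tv$true_origin == "GERMLINE"), config$germline_vaf_mean,
                config$germline_vaf_sd, config$germline_vaf_range[1L],
                config$germline_vaf_range[2L])
  tv$level[is_ch] <- .runif_log(sum(is_ch), config$ch_vaf_range)
  tv$level[is_tum] <- .runif_log(sum(is_tum), config$tumor_maf_range)

  ## expand to variant x plasma-timepoint, apply presence + detection
  pat_idx <- match(tv$patient_id, patients)
  rows <- vector("list", 6L)
  present_mat <- detect_mat <- NULL
  if (n_var > 0) {
    long <- tv[rep(seq_len(n_var), each = 5L), ]
    long$timepoint <- rep(TIMEPOINTS, times = n_var)
    tp_idx <- match(long$timepoint, TIMEPOINTS)
    ci <- clear_idx[match(long$patient_id, patients)]
    long$present <- ifelse(long$true_origin == "TUMOR",
                           is.na(ci) | tp_idx < ci, TRUE)
    # per-sample jitter around the stable level
    jit <- exp(stats::rnorm(nrow(long), 0, 0.15))
    long$maf_obs <- ifelse(long$true_origin == "GERMLINE",
                           .rtruncnorm(nrow(long), config$germline_vaf_mean,
                                       config$germline_vaf_sd,
                                       config$germline_vaf_range[1L],
                                       config$germline_vaf_range[2L]),
                           pmin(long$level * jit, 0.95))
    long$detected <- long$present &
      stats::runif(nrow(long)) >= .fn_rate(long$maf_obs, config)
    plasma <- long[long$detected, , drop = FALSE]
    cov <- stats::rnbinom(nrow(plasma), mu = config$coverage_mu,
                          size = config$coverage_size) + 100L
    smc <- pmin(pmax(1L, as.integer(round(plasma$maf_obs * cov))), cov)
    plasma_df <- data.frame(
      patient_id = plasma$patient_id,
      sample_id = paste0(plasma$patient_id, "_P_", plasma$timepoint),
      chrom = plasma$chrom, pos = plasma$pos, ref = plasma$ref,
      alt = plasma$alt, gene = plasma$gene,
      maf_fraction = signif(plasma$maf_obs, 6),
      distinct_coverage = cov, super_mutant_count = smc,
      stringsAsFactors = FALSE)

    ## WBC rows: germline variants at germline VAF; CH and contaminated
    ## tumor variants at their planted super-mutant counts
    wbc_keep <- tv$true_origin == "GERMLINE" | tv$wbc_smc > 0L
    wb <- tv[wbc_keep, , drop = FALSE]
    wcov <- stats::rnbinom(nrow(wb), mu = config$coverage_mu,
                           size = config$coverage_size) + 100L
    wsmc <- ifelse(wb$true_origin == "GERMLINE",
                   as.integer(round(.rtruncnorm(nrow(wb),
                                                config$germline_vaf_mean,
                                                config$germline_vaf_sd,
                                                config$germline_vaf_range[1L],
                                                config$germline_vaf_range[2L])
                                    * wcov)),
                   wb$wbc_smc)
    wsmc <- pmin(pmax(wsmc, 0L), wcov)
    wbc_df <- data.frame(
      patient_id = wb$patient_id,
      sample_id = paste0(wb$patient_id, "_WBC"),
      chrom = wb$chrom, pos = wb$pos, ref = wb$ref, alt = wb$alt,
      gene = wb$gene,
      maf_fraction = signif(wsmc / wcov, 6),
      distinct_coverage = wcov, super_mutant_count = wsmc,
      stringsAsFactors = FALSE)
    variants <- rbind(plasma_df, wbc_df)

    ## realized tumor detection per patient x timepoint (bookkeeping)
    tum_long <- long[long$true_origin == "TUMOR", , drop = FALSE]
    detect_mat <- matrix(FALSE, n, 5L, dimnames = list(patients, TIMEPOINTS))
    present_mat <- detect_mat
    if (nrow(tum_long)) {
      di <- cbind(match(tum_long$patient_id, patients),
                  match(tum_long$timepoint, TIMEPOINTS))
      for (r in seq_len(nrow(tum_long))) {
        present_mat[di[r, 1L], di[r, 2L]] <-
          present_mat[di[r, 1L], di[r, 2L]] | tum_long$present[r]
        detect_mat[di[r, 1L], di[r, 2L]] <-
          detect_mat[di[r, 1L], di[r, 2L]] | tum_long$detected[r]
      }
    }
  } else {
    variants <- data.frame(patient_id = character(0),
                           sample_id = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), gene = character(0),
                           maf_fraction = numeric(0),
                           distinct_coverage = integer(0),
                           super_mutant_count = integer(0),
                           stringsAsFactors = FALSE)
    detect_mat <- present_mat <-
      matrix(FALSE, n, 5L, dimnames = list(patients, TIMEPOINTS))
  }

  ## survival: hazard multiplied for evaluable non-clearing patients
  rate0 <- log(2) / config$rfs_median_cleared_months
  rate <- ifelse(has_tumor & !responder, rate0 * config$hazard_ratio, rate0)
  rfs_u <- stats::rexp(n, rate)
  os_u <- rfs_u + stats::rexp(n, 1 / config$os_post_recurrence_mean_months)
  rfs_event <- rfs_u < config$horizon_months
  os_event <- os_u < config$horizon_months
  rfs_months <- round(pmin(rfs_u, config$horizon_months), 2)
  os_months <- round(pmin(os_u, config$horizon_months), 2)

  ## pathology correlates: responders regress more deeply
  good <- responder | !has_tumor
  residual <- integer(n)
  residual[good] <- sample(c(0L, 5L, 10L, 15L, 20L), sum(good),
                           replace = TRUE, prob = c(.4, .2, .2, .1, .1))
  residual[!good] <- sample(seq(30L, 95L, 5L), sum(!good), replace = TRUE)
  resected <- stats::runif(n) < 0.95
  residual[!resected] <- NA_integer_
  mpr_flag <- !is.na(residual) & residual <= 10L
  outcomes <- data.frame(
    patient_id = patients,
    arm = rep(c("A", "B"), length.out = n),
    resected = resected,
    residual_viable_tumor_pct = residual,
    rfs_months = rfs_months, rfs_event = rfs_event,
    os_months = os_months, os_event = os_event,
    pd_l1_cps = sample(c(0L, 1L, 2L, 5L, 10L, 20L, 35L, 50L), n,
                       replace = TRUE),
    lag3_log2_expression =
      round(stats::rnorm(n, 7 + 1.5 * mpr_flag, 1), 3),
    stringsAsFactors = FALSE)

  planted_pattern <- vapply(seq_len(n), function(i) {
    .pattern_from_detect(present_mat[i, ])
  }, character(1))
  realized_pattern <- vapply(seq_len(n), function(i) {
    .pattern_from_detect(detect_mat[i, ])
  }, character(1))
  truth_patients <- data.frame(
    patient_id = patients,
    n_tumor_variants = n_tum,
    responder = responder,
    clearance_timepoint = ifelse(is.na(clear_tp), "NONE", clear_tp),
    rfs_uncensored_months = round(rfs_u, 2),
    os_uncensored_months = round(os_u, 2),
    planted_pattern = planted_pattern,
    realized_pattern = realized_pattern,
    realized_baseline_detected = detect_mat[, "BASELINE"],
    realized_post_ici_detected = detect_mat[, "POST_ICI"],
    realized_preop_detected = detect_mat[, "PREOP"],
    realized_postop_detected = detect_mat[, "POSTOP"],
    stringsAsFactors = FALSE)

  truth_variants <- tv[, c("patient_id", "chrom", "pos", "ref", "alt",
                           "gene", "key", "true_origin", "is_hotspot",
                           "wbc_smc")]

  out <- list(variants = variants, manifest = manifest, cosmic = cosmic,
              outcomes = outcomes, truth_variants = truth_variants,
              truth_patients = truth_patients)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ord <- order(out$variants$patient_id, out$variants$sample_id,
                 out$variants$chrom, out$variants$pos)
    .write_tsv(out$variants[ord, ], file.path(out_dir, "variants.tsv"))
    .write_tsv(out$manifest, file.path(out_dir, "manifest.tsv"))
    .write_tsv(out$cosmic[order(out$cosmic$chrom, out$cosmic$pos), ],
               file.path(out_dir, "cosmic.tsv"))
    .write_tsv(out$outcomes, file.path(out_dir, "outcomes.tsv"))
    .write_tsv(out$truth_variants[order(out$truth_variants$patient_id,
                                        out$truth_variants$pos), ],
               file.path(out_dir, "truth_variants.tsv"))
    .write_tsv(out$truth_patients, file.path(out_dir, "truth_patients.tsv"))
  }
  invisible(out)
}

## COSMIC plan: hotspots get >= 25 occurrences; CH hotspots sit at
## heme fraction >= 0.10, tumor hotspots below it, so both sides of the
## 10% rule are exercised.
.gen_cosmic <- function(tv) {
  nv <- nrow(tv)
  if (nv == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      total_occurrences = integer(0),
                      heme_lymphoid_occurrences = integer(0),
                      stringsAsFactors = FALSE))
  }
  total <- integer(nv)
  heme <- integer(nv)
  hs <- tv$is_hotspot
  total[hs] <- sample(25:500, sum(hs), replace = TRUE)
  total[!hs] <- sample(0:24, sum(!hs), replace = TRUE,
                       prob = c(12, rep(1, 24)) / 36)
  ch <- tv$true_origin == "CH"
  # CH hotspots: heme fraction in [0.10, 0.60]
  i <- hs & ch
  heme[i] <- pmin(total[i],
                  as.integer(ceiling(total[i] *
                                       stats::runif(sum(i), 0.10, 0.60))))
  # non-CH hotspots: heme fraction strictly below 0.10
  i <- hs & !ch
  heme[i] <- as.integer(floor(total[i] * stats::runif(sum(i), 0, 0.0999)))
  # nonhotspots: arbitrary small heme counts
  i <- !hs
  heme[i] <- as.integer(round(total[i] * stats::runif(sum(i), 0, 0.5)))
  # keep only annotated variants (zero-occurrence keys stay unlisted,
  # exercising the implicit (0, 0) lookup default)
  keep <- total > 0L
  data.frame(chrom = tv$chrom[keep], pos = tv$pos[keep],
             ref = tv$ref[keep], alt = tv$alt[keep],
             total_occurrences = total[keep],
             heme_lymphoid_occurrences = heme[keep],
             stringsAsFactors = FALSE)
}

#' Generate a COSMIC-style annotation table for planted variants
#'
#' @param truth_variants truth table from [generate_cohort()] (columns
#'   `chrom`, `pos`, `ref`, `alt`, `true_origin`, `is_hotspot`).
#' @param seed RNG seed.
#' @return annotation data.frame in the `cosmic.tsv` dialect.
#' @export
generate_cosmic_table <- function(truth_variants, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  .gen_cosmic(truth_variants)
}
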