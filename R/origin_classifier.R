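## WBC-informed branched logic assigning each distinct patient-level plasma
## variant a cellular origin: GERMLINE, CH (clonal hematopoiesis) or TUMOR.
##
## Fixed rule order:
##   (1) hotspot annotation        (>= 25 COSMIC occurrences)
##   (2) germline rule             (nonhotspot, VAF >= 25% in WBC and in
##                                  every assessable plasma sample)
##   (3) WBC super-mutant count s: s >= 3          -> CH
##                                 s == 0          -> TUMOR
##                                 s in {1, 2}     -> nonhotspot: CH;
##                                   hotspot: CH if heme_fraction >= 0.10,
##                                   TUMOR otherwise.
## All thresholds are inclusive exactly as written.

HOTSPOT_MIN_OCCURRENCES <- 25L
GERMLINE_MIN_VAF <- 0.25
CH_MIN_SUPER_MUTANTS <- 3L
CH_MIN_HEME_FRACTION <- 0.10

#' Hotspot annotation from COSMIC occurrence counts
#'
#' A variant is a cancer hotspot when it has at least 25 recorded COSMIC
#' occurrences. The hematologic/lymphoid fraction is
#' `heme_lymphoid_occurrences / total_occurrences`, defined as 0 when the
#' total is 0.
#'
#' @param total_occurrences,heme_lymphoid_occurrences nonnegative integer
#'   vectors, heme <= total rowwise.
#' @return data.frame with `is_hotspot`, `total_occurrences`,
#'   `heme_fraction`.
#' @export
annotate_hotspot <- function(total_occurrences, heme_lymphoid_occurrences) {
  total <- as.integer(total_occurrences)
  heme <- as.integer(heme_lymphoid_occurrences)
  if (any(total < 0L | heme < 0L)) stop("occurrence counts must be nonnegative")
  if (any(heme > total)) {
    stop("heme_lymphoid_occurrences must not exceed total_occurrences")
  }
  data.frame(
    is_hotspot = total >= HOTSPOT_MIN_OCCURRENCES,
    total_occurrences = total,
    heme_fraction = ifelse(total == 0L, 0, heme / total)
  )
}

#' Germline rule for one patient-variant
#'
#' TRUE iff the variant is a nonhotspot and its allele fraction is at
#' least 25% in the matched WBC sample and in every assessable plasma
#' sample of the patient. A plasma sample is assessable when its distinct
#' error-corrected coverage at the locus is at least `coverage_floor`;
#' dropout samples are excluded from the all-quantifier so a failed
#' library cannot veto an otherwise obvious germline variant.
#'
#' @param plasma_maf numeric vector of plasma allele fractions for the
#'   variant (one per plasma sample where observed).
#' @param plasma_coverage distinct coverages parallel to `plasma_maf`
#'   (NA treated as assessable).
#' @param wbc_maf allele fraction in the matched WBC sample; NA or missing
#'   WBC observation fails the rule.
#' @param is_hotspot logical hotspot flag for the variant.
#' @param coverage_floor assessability floor on distinct coverage.
#' @return logical scalar.
#' @export
apply_germline_rule <- function(plasma_maf, plasma_coverage = NULL,
                                wbc_maf, is_hotspot,
                                coverage_floor = 10L) {
  if (length(plasma_maf) == 0L) stop("no plasma observations supplied")
  if (isTRUE(is_hotspot)) return(FALSE)
  if (is.null(wbc_maf) || length(wbc_maf) == 0L || is.na(wbc_maf)) return(FALSE)
  if (wbc_maf < GERMLINE_MIN_VAF) return(FALSE)
  if (is.null(plasma_coverage)) plasma_coverage <- rep(NA_real_, length(plasma_maf))
  assessable <- is.na(plasma_coverage) | plasma_coverage >= coverage_floor
  maf <- plasma_maf[assessable]
  if (length(maf) == 0L) return(FALSE)
  all(maf >= GERMLINE_MIN_VAF)
}

#' Classify one patient-variant
#'
#' Applies the fixed-order decision tree (hotspot annotation, germline
#' rule, WBC super-mutant-count bands) and records every rule evaluated in
#' `rule_path` for audit. The super-mutant count driving the CH decision
#' is taken from the matched WBC sample by default (`smc_source = "wbc"`);
#' a variant absent from WBC counts as 0 (tumor branch). The alternative
#' reading `smc_source = "max_plasma"` uses the maximum plasma
#' super-mutant count instead.
#'
#' @param plasma_obs data.frame of plasma observations for one
#'   patient-variant with columns `maf`, `distinct_coverage`,
#'   `super_mutant_count`.
#' @param wbc_obs single-row data.frame for the matched WBC observation of
#'   the variant, or `NULL` if not observed in WBC.
#' @param total_occurrences,heme_lymphoid_occurrences COSMIC occurrence
#'   counts for the variant (0, 0 when unlisted).
#' @param smc_source `"wbc"` or `"max_plasma"`.
#' @param coverage_floor passed to [apply_germline_rule()].
#' @return list with `origin`, `is_hotspot`, `total_occurrences`,
#'   `heme_fraction`, `wbc_super_mutant_count`, `smc_used`, `rule_path`
#'   (character vector of rule identifiers fired, in order).
#' @export
classify_variant <- function(plasma_obs, wbc_obs = NULL,
                             total_occurrences = 0L,
                             heme_lymphoid_occurrences = 0L,
                             smc_source = c("wbc", "max_plasma"),
                             coverage_floor = 10L) {
  smc_source <- match.arg(smc_source)
  hs <- annotate_hotspot(total_occurrences, heme_lymphoid_occurrences)
  path <- if (hs$is_hotspot) "hotspot" else "nonhotspot"

  wbc_maf <- if (!is.null(wbc_obs) && nrow(wbc_obs)) wbc_obs$maf[1L] else NA_real_
  wbc_smc <- if (!is.null(wbc_obs) && nrow(wbc_obs)) {
    as.integer(wbc_obs$super_mutant_count[1L])
  } else 0L

  germ <- apply_germline_rule(plasma_obs$maf, plasma_obs$distinct_coverage,
                              wbc_maf, hs$is_hotspot, coverage_floor)
  path <- c(path, if (germ) "germline_rule_pass" else "germline_rule_fail")
  if (hs$is_hotspot) path[length(path)] <- "germline_rule_ineligible_hotspot"

  if (germ) {
    return(list(origin = "GERMLINE", is_hotspot = hs$is_hotspot,
                total_occurrences = hs$total_occurrences,
                heme_fraction = hs$heme_fraction,
                wbc_super_mutant_count = wbc_smc, smc_used = NA_integer_,
                rule_path = path))
  }

  s <- if (smc_source == "wbc") {
    wbc_smc
  } else {
    max(c(0L, as.integer(plasma_obs$super_mutant_count)), na.rm = TRUE)
  }

  if (s >= CH_MIN_SUPER_MUTANTS) {
    origin <- "CH"
    path <- c(path, "smc_ge3_ch")
  } else if (s == 0L) {
    origin <- "TUMOR"
    path <- c(path, "smc_eq0_tumor")
  } else {
    path <- c(path, "smc_1_2")
    if (!hs$is_hotspot) {
      origin <- "CH"
      path <- c(path, "nonhotspot_ch")
    } else if (hs$heme_fraction >= CH_MIN_HEME_FRACTION) {
      origin <- "CH"
      path <- c(path, "heme_fraction_ge10pct_ch")
    } else {
      origin <- "TUMOR"
      path <- c(path, "heme_fraction_lt10pct_tumor")
    }
  }

  list(origin = origin, is_hotspot = hs$is_hotspot,
       total_occurrences = hs$total_occurrences,
       heme_fraction = hs$heme_fraction,
       wbc_super_mutant_count = wbc_smc, smc_used = s, rule_path = path)
}

#' Classify every distinct patient-variant in a cohort
#'
#' One origin call per distinct (patient, variant key) across all
#' timepoints jointly; plasma observations of the same variant at
#' different timepoints share a single label. Per-variant evaluation
#' errors (for example a patient without a WBC sample) are collected and
#' reported together with the offending keys.
#'
#' @param variants validated variant observation table
#'   ([read_variant_table()]).
#' @param manifest validated sample manifest ([read_sample_manifest()]).
#' @param cosmic COSMIC annotation table ([read_cosmic_annotations()]).
#' @param smc_source,coverage_floor see [classify_variant()].
#' @return list with `origins` (data.frame, one row per patient-variant:
#'   patient_id, chrom, pos, ref, alt, gene, origin, is_hotspot,
#'   total_occurrences, heme_fraction, wbc_super_mutant_count, rule_path)
#'   and `summary` (variant and patient counts per origin class).
#' @export
classify_cohort <- function(variants, manifest, cosmic,
                            smc_source = c("wbc", "max_plasma"),
                            coverage_floor = 10L) {
  smc_source <- match.arg(smc_source)
  wbc_ids <- manifest$sample_id[manifest$material == "WBC"]
  wbc_patient <- manifest$patient_id[manifest$material == "WBC"]
  patients_with_wbc <- unique(wbc_patient)

  is_wbc <- variants$sample_id %in% wbc_ids
  plasma <- variants[!is_wbc, , drop = FALSE]
  wbc <- variants[is_wbc, , drop = FALSE]

  pk <- paste(plasma$patient_id, plasma$key, sep = "\r")
  groups <- split(seq_len(nrow(plasma)), pk)

  missing_wbc <- setdiff(unique(plasma$patient_id), patients_with_wbc)
  if (length(missing_wbc)) {
    stop("evaluation error: no WBC sample for patient(s) ",
         paste(sort(missing_wbc), collapse = ", "))
  }

  wbc_key <- paste(wbc$patient_id, wbc$key, sep = "\r")
  ann <- cosmic_lookup(cosmic, plasma$key)

  rows <- vector("list", length(groups))
  errs <- character(0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    first <- idx[1L]
    wrow <- wbc[wbc_key == pk[first], , drop = FALSE]
    call <- tryCatch(
      classify_variant(plasma[idx, , drop = FALSE],
                       if (nrow(wrow)) wrow[1L, , drop = FALSE] else NULL,
                       ann$total_occurrences[first],
                       ann$heme_lymphoid_occurrences[first],
                       smc_source = smc_source,
                       coverage_floor = coverage_floor),
      error = function(e) e
    )
    if (inherits(call, "error")) {
      errs <- c(errs, paste0(plasma$patient_id[first], " ",
                             plasma$key[first], ": ", conditionMessage(call)))
      next
    }
    rows[[g]] <- data.frame(
      patient_id = plasma$patient_id[first],
      chrom = plasma$chrom[first], pos = plasma$pos[first],
      ref = plasma$ref[first], alt = plasma$alt[first],
      gene = plasma$gene[first], key = plasma$key[first],
      origin = call$origin, is_hotspot = call$is_hotspot,
      total_occurrences = call$total_occurrences,
      heme_fraction = call$heme_fraction,
      wbc_super_mutant_count = call$wbc_super_mutant_count,
      rule_path = paste(call$rule_path, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  if (length(errs)) {
    stop("classification failed for ", length(errs), " variant(s):\n  ",
         paste(errs, collapse = "\n  "))
  }
  origins <- do.call(rbind, rows)
  if (is.null(origins)) {
    origins <- data.frame(patient_id = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), gene = character(0),
                          key = character(0), origin = character(0),
                          is_hotspot = logical(0),
                          total_occurrences = integer(0),
                          heme_fraction = numeric(0),
                          wbc_super_mutant_count = integer(0),
                          rule_path = character(0), stringsAsFactors = FALSE)
  }
  origins <- origins[order(origins$patient_id, origins$chrom, origins$pos,
                           origins$ref, origins$alt), , drop = FALSE]
  rownames(origins) <- NULL

  counts <- sapply(ORIGINS, function(o) sum(origins$origin == o))
  pat_counts <- sapply(ORIGINS, function(o) {
    length(unique(origins$patient_id[origins$origin == o]))
  })
  list(origins = origins,
       summary = list(
         n_variants = nrow(origins),
         variant_counts = counts,
         patient_counts = pat_counts,
         n_patients = length(unique(c(origins$patient_id,
                                      manifest$patient_id)))
       ))
}
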