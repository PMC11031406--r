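# Shared in-code fixtures: tiny hand-built cohorts and writers for the
# TSV dialects. All fixtures are constructed programmatically.

make_obs <- function(maf, coverage = 2000L, smc = NULL,
                     patient = "P1", sample = "S1",
                     chrom = "1", pos = 100L, ref = "A", alt = "T",
                     gene = "TP53") {
  n <- length(maf)
  if (is.null(smc)) smc <- pmax(1L, as.integer(round(maf * coverage)))
  data.frame(patient_id = rep_len(patient, n),
             sample_id = rep_len(sample, n),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             gene = rep_len(gene, n),
             maf = maf, distinct_coverage = rep_len(coverage, n),
             super_mutant_count = rep_len(smc, n),
             stringsAsFactors = FALSE)
}

write_variant_tsv <- function(df, path, unit = "maf_fraction") {
  out <- df
  names(out)[names(out) == "maf"] <- unit
  if (unit == "maf_percent") out[[unit]] <- out[[unit]] * 100
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# one patient, five plasma timepoints + WBC
mini_manifest <- function(patient = "P1") {
  tps <- c("BASELINE", "D14", "POST_ICI", "PREOP", "POSTOP")
  data.frame(
    sample_id = c(paste0(patient, "_P_", tps), paste0(patient, "_WBC")),
    patient_id = patient,
    material = c(rep("PLASMA", 5), "WBC"),
    timepoint = c(tps, "BASELINE"),
    collection_day = c(0L, 14L, 28L, 75L, 120L, 0L),
    stringsAsFactors = FALSE)
}

# independently coded brute-force origin rule table (the oracle the
# classifier is checked against; deliberately a flat lookup, not a tree)
oracle_origin <- function(hotspot, germline_pattern, s, heme_frac) {
  if (!hotspot && germline_pattern) return("GERMLINE")
  if (s >= 3) return("CH")
  if (s == 0) return("TUMOR")
  # s is 1 or 2
  if (!hotspot) return("CH")
  if (heme_frac >= 0.10) return("CH")
  "TUMOR"
}

# drive classify_variant from an abstract feature tuple
classify_from_features <- function(hotspot, germline_pattern, s,
                                   heme_frac) {
  total <- if (hotspot) 100L else 20L
  heme <- as.integer(round(heme_frac * total))
  plasma_maf <- if (germline_pattern) c(0.48, 0.52, 0.50) else
    c(0.004, 0.006, 0.005)
  wbc_maf <- if (germline_pattern) 0.51 else 0.002
  plasma <- make_obs(plasma_maf,
                     sample = paste0("S", seq_along(plasma_maf)))
  wbc <- if (s > 0L || germline_pattern) {
    make_obs(wbc_maf, smc = as.integer(s), sample = "WBC1")
  } else NULL
  list(call = classify_variant(plasma, wbc, total, heme),
       actual_heme_frac = heme / total)
}
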