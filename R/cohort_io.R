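#' @keywords internal
"_PACKAGE"

## Trial timepoint enumeration, in chronological order. WBC samples are
## anchored at BASELINE (matched baseline buffy-coat DNA).
TIMEPOINTS <- c("BASELINE", "D14", "POST_ICI", "PREOP", "POSTOP")
MATERIALS <- c("PLASMA", "WBC")
ORIGINS <- c("GERMLINE", "CH", "TUMOR")

#' Canonical variant key string
#'
#' Builds the `chrom:pos:ref:alt` identifier used to join variant
#' observations to COSMIC annotations and truth tables. Alleles are
#' left-normalized first (see [normalize_alleles()]).
#'
#' @param chrom,pos,ref,alt vectors describing the variants (1-based,
#'   fully closed, VCF-style coordinates).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  norm <- normalize_alleles(pos, ref, alt)
  paste(chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

#' Reference-free allele normalization
#'
#' Trims bases shared by `ref` and `alt` — first from the right, then from
#' the left (advancing `pos`) — while keeping at least one base of each
#' allele. This is the parsimony-style left shift that is possible without
#' a reference genome; full left-alignment across repeat tracts needs the
#' reference sequence and is not attempted.
#'
#' @param pos,ref,alt parallel vectors; `ref != alt` rowwise.
#' @return list with components `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(ref == alt)) {
    stop("ref and alt must differ (rows: ",
         paste(which(ref == alt), collapse = ", "), ")")
  }
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # right trim
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # left trim, advancing the coordinate
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, na.strings = c("NA", ""))
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read a plasma/WBC variant observation table
#'
#' The native dialect is a TSV with columns `patient_id`, `sample_id`,
#' `chrom`, `pos`, `ref`, `alt`, `gene`, `maf_fraction` (or `maf_percent`),
#' `distinct_coverage`, `super_mutant_count`. The MAF unit is declared by
#' the column name: `maf_fraction` is a fraction in \[0, 1\],
#' `maf_percent` a percentage in \[0, 100\] converted on ingest. A VCF
#' (one sample per file) can be ingested instead: MAF is taken from the
#' `AF` FORMAT field, or computed as alt/total from `AD`; `distinct_coverage`
#' from `DP` and `super_mutant_count` from the alt `AD` count.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param patient_id,sample_id identifiers used for VCF ingest, where the
#'   file itself carries neither.
#' @return `data.frame` of validated variant observations with MAF stored
#'   as a fraction and a `key` column.
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf"),
                               patient_id = NULL, sample_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  df <- if (format == "vcf") {
    .read_variant_vcf(path, patient_id = patient_id, sample_id = sample_id)
  } else {
    .read_variant_tsv(path)
  }
  validate_variant_table(df)
}

.read_variant_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("patient_id", "sample_id", "chrom", "pos", "ref",
                         "alt", "gene", "distinct_coverage",
                         "super_mutant_count"), "variant table")
  if ("maf_fraction" %in% names(df)) {
    df$maf <- as.numeric(df$maf_fraction)
  } else if ("maf_percent" %in% names(df)) {
    df$maf <- as.numeric(df$maf_percent) / 100
  } else {
    stop("schema error in variant table: missing column maf_fraction (or maf_percent)")
  }
  df
}

.read_variant_vcf <- function(path, patient_id, sample_id) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF ingest requires the VariantAnnotation package")
  }
  if (is.null(patient_id) || is.null(sample_id)) {
    stop("VCF ingest needs explicit patient_id and sample_id")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) != 1L) stop("VCF ingest supports exactly one sample per file")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  geno <- VariantAnnotation::geno(vcf)
  n <- length(rr)
  dp <- if ("DP" %in% names(geno)) as.integer(geno$DP[, 1L]) else rep(NA_integer_, n)
  ad_alt <- rep(NA_integer_, n)
  if ("AD" %in% names(geno)) {
    ad <- geno$AD
    ad_alt <- vapply(seq_len(n), function(i) {
      v <- if (is.list(ad[, 1L])) ad[i, 1L][[1L]] else ad[i, , ]
      as.integer(v[2L])
    }, integer(1L))
  }
  maf <- if ("AF" %in% names(geno)) {
    as.numeric(unlist(geno$AF[, 1L]))
  } else if (!all(is.na(ad_alt))) {
    ad_alt / dp
  } else {
    stop("VCF has neither AF nor AD FORMAT fields; cannot derive MAF")
  }
  info_gene <- VariantAnnotation::info(vcf)$GENE
  data.frame(
    patient_id = patient_id, sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    gene = if (is.null(info_gene)) NA_character_ else as.character(info_gene),
    maf = maf,
    distinct_coverage = dp,
    super_mutant_count = ad_alt,
    stringsAsFactors = FALSE
  )
}

#' Validate a variant observation table
#'
#' Enforces the observation invariants: MAF in \[0, 1\], nonnegative
#' super-mutant counts no larger than distinct coverage, positive 1-based
#' positions, `ref != alt`. Rows are keyed and alleles normalized.
#'
#' @param df data.frame with at least the native-dialect columns and `maf`.
#' @return the validated data.frame (invisibly modified: `key` added,
#'   alleles normalized, canonical column order).
#' @export
validate_variant_table <- function(df) {
  cols <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt", "gene",
            "maf", "distinct_coverage", "super_mutant_count")
  .require_columns(df, cols, "variant table")
  df <- df[, cols, drop = FALSE]
  if (nrow(df) == 0L) {
    df$key <- character(0)
    return(df)
  }
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  df$distinct_coverage <- as.integer(df$distinct_coverage)
  df$super_mutant_count <- as.integer(df$super_mutant_count)
  bad <- which(!is.na(df$maf) & (df$maf < 0 | df$maf > 1))
  if (length(bad)) {
    stop("validation error: maf outside [0,1] at row(s) ",
         paste(bad, collapse = ", "))
  }
  bad <- which(df$pos < 1L)
  if (length(bad)) {
    stop("validation error: pos < 1 at row(s) ", paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(df$super_mutant_count) & df$super_mutant_count < 0L)
  if (length(bad)) {
    stop("validation error: negative super_mutant_count at row(s) ",
         paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(df$super_mutant_count) & !is.na(df$distinct_coverage) &
                 df$super_mutant_count > df$distinct_coverage)
  if (length(bad)) {
    stop("validation error: super_mutant_count > distinct_coverage at row(s) ",
         paste(bad, collapse = ", "))
  }
  norm <- normalize_alleles(df$pos, df$ref, df$alt)
  df$pos <- norm$pos
  df$ref <- norm$ref
  df$alt <- norm$alt
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df
}

#' Read the sample manifest
#'
#' TSV columns: `sample_id`, `patient_id`, `material` (PLASMA or WBC),
#' `timepoint` (BASELINE, D14, POST_ICI, PREOP, POSTOP), `collection_day`.
#' Exactly one WBC sample per patient (anchored at BASELINE) and at most
#' one plasma sample per patient-timepoint. The postoperative 3-12 week
#' collection window is recorded, not enforced.
#'
#' @param path file to read.
#' @return validated manifest data.frame.
#' @export
read_sample_manifest <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "patient_id", "material", "timepoint",
                         "collection_day"), "sample manifest")
  validate_sample_manifest(df)
}

#' @rdname read_sample_manifest
#' @param df manifest data.frame to validate in memory.
#' @export
validate_sample_manifest <- function(df) {
  bad_tp <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    stop("schema error: unknown timepoint label(s) ",
         paste(bad_tp, collapse = ", "))
  }
  bad_mat <- setdiff(unique(df$material), MATERIALS)
  if (length(bad_mat)) {
    stop("schema error: unknown material label(s) ",
         paste(bad_mat, collapse = ", "))
  }
  wbc <- df[df$material == "WBC", ]
  dup <- names(which(table(wbc$patient_id) > 1L))
  if (length(dup)) {
    stop("validation error: more than one WBC sample for patient(s) ",
         paste(dup, collapse = ", "))
  }
  plasma <- df[df$material == "PLASMA", ]
  pk <- paste(plasma$patient_id, plasma$timepoint)
  dup <- unique(pk[duplicated(pk)])
  if (length(dup)) {
    stop("validation error: duplicate plasma sample for (patient, timepoint) ",
         paste(dup, collapse = "; "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("validation error: duplicate sample_id ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$collection_day <- as.integer(df$collection_day)
  df
}

#' Read a COSMIC-style occurrence annotation table
#'
#' TSV columns: `chrom`, `pos`, `ref`, `alt`, `total_occurrences`,
#' `heme_lymphoid_occurrences`. The heme/lymphoid count pre-aggregates the
#' registry's hematologic and lymphoid histology classes upstream. Keys
#' absent from the table resolve to the implicit (0, 0) annotation via
#' [cosmic_lookup()], never to an error.
#'
#' @param path file to read.
#' @return data.frame keyed by `key` with occurrence counts.
#' @export
read_cosmic_annotations <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("chrom", "pos", "ref", "alt", "total_occurrences",
                         "heme_lymphoid_occurrences"), "cosmic table")
  validate_cosmic_annotations(df)
}

#' @rdname read_cosmic_annotations
#' @param df annotation data.frame to validate in memory.
#' @export
validate_cosmic_annotations <- function(df) {
  df$total_occurrences <- as.integer(df$total_occurrences)
  df$heme_lymphoid_occurrences <- as.integer(df$heme_lymphoid_occurrences)
  bad <- which(df$total_occurrences < 0L | df$heme_lymphoid_occurrences < 0L)
  if (length(bad)) {
    stop("validation error: negative occurrence count at row(s) ",
         paste(bad, collapse = ", "))
  }
  bad <- which(df$heme_lymphoid_occurrences > df$total_occurrences)
  if (length(bad)) {
    stop("validation error: heme_lymphoid_occurrences > total_occurrences ",
         "at row(s) ", paste(bad, collapse = ", "))
  }
  if (nrow(df)) {
    df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    if (anyDuplicated(df$key)) {
      stop("validation error: duplicate annotation for key(s) ",
           paste(unique(df$key[duplicated(df$key)]), collapse = ", "))
    }
  } else {
    df$key <- character(0)
  }
  df
}

#' Look up COSMIC occurrence counts for variant keys
#'
#' @param cosmic table from [read_cosmic_annotations()].
#' @param key character vector of variant keys.
#' @return data.frame with `total_occurrences` and
#'   `heme_lymphoid_occurrences`, (0, 0) for unlisted keys.
#' @export
cosmic_lookup <- function(cosmic, key) {
  i <- match(key, cosmic$key)
  data.frame(
    key = key,
    total_occurrences = ifelse(is.na(i), 0L, cosmic$total_occurrences[i]),
    heme_lymphoid_occurrences =
      ifelse(is.na(i), 0L, cosmic$heme_lymphoid_occurrences[i]),
    stringsAsFactors = FALSE
  )
}

#' Read the per-patient clinical outcome table
#'
#' TSV columns: `patient_id`, `arm` (A or B), `resected`,
#' `residual_viable_tumor_pct` (0-100 or NA for unresected patients),
#' `rfs_months`, `rfs_event`, `os_months`, `os_event`, `pd_l1_cps`,
#' `lag3_log2_expression`. Times are months from treatment initiation;
#' censoring means either ordering of RFS and OS times is legal.
#'
#' @param path file to read.
#' @return validated outcome data.frame.
#' @export
read_outcome_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("patient_id", "arm", "resected",
                         "residual_viable_tumor_pct", "rfs_months",
                         "rfs_event", "os_months", "os_event"),
                   "outcome table")
  df$resected <- as.logical(df$resected)
  df$rfs_event <- as.logical(df$rfs_event)
  df$os_event <- as.logical(df$os_event)
  for (col in c("rfs_months", "os_months")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      stop("validation error: negative ", col, " at row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  rv <- df$residual_viable_tumor_pct
  bad <- which(!is.na(rv) & (rv < 0 | rv > 100))
  if (length(bad)) {
    stop("validation error: residual_viable_tumor_pct outside [0,100] at ",
         "row(s) ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("validation error: duplicate patient_id in outcome table")
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
  path
}

#' Write pipeline result tables
#'
#' Writes `origins.tsv`, `status.tsv` and `trajectories.tsv` (plus
#' `outcomes_report.tsv` when outcome statistics are supplied) with a
#' deterministic column order and row sort, so identical inputs produce
#' byte-identical files.
#'
#' @param origins origin table from [classify_cohort()].
#' @param status,trajectories tables from [build_trajectories()].
#' @param outcome_stats optional data.frame of outcome comparisons.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_results <- function(origins = NULL, status = NULL, trajectories = NULL,
                          outcome_stats = NULL, out_dir = ".") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  written <- character(0)
  if (!is.null(origins)) {
    o <- origins[order(origins$patient_id, origins$chrom, origins$pos,
                       origins$ref, origins$alt), , drop = FALSE]
    written <- c(written, .write_tsv(o, file.path(out_dir, "origins.tsv")))
  }
  if (!is.null(status)) {
    s <- status[order(status$patient_id,
                      match(status$timepoint, TIMEPOINTS)), , drop = FALSE]
    written <- c(written, .write_tsv(s, file.path(out_dir, "status.tsv")))
  }
  if (!is.null(trajectories)) {
    tr <- trajectories[order(trajectories$patient_id), , drop = FALSE]
    written <- c(written,
                 .write_tsv(tr, file.path(out_dir, "trajectories.tsv")))
  }
  if (!is.null(outcome_stats)) {
    written <- c(written,
                 .write_tsv(outcome_stats,
                            file.path(out_dir, "outcomes_report.tsv")))
  }
  invisible(written)
}
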