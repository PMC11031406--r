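## Per-timepoint ctDNA detection calls, cell-free tumor load (cfTL),
## evaluability and clearance trajectory summaries.
##
## ctDNA is POSITIVE at a timepoint iff >= 1 tumor-derived variant is
## detected at any mutant allele frequency (no MAF floor); NEGATIVE when a
## plasma sample exists but carries no tumor-derived variant;
## NOT_ASSESSED when the timepoint has no plasma sample. Patients with no
## POSITIVE call at any assessed timepoint form the undetectable (UD)
## group and are nonevaluable for clearance analyses.

STATUS_LEVELS <- c("POSITIVE", "NEGATIVE", "NOT_ASSESSED")
CLEARING_PATTERNS <- c("SUSTAINED_CLEARANCE", "CLEARED_POST_ICI",
                       "CLEARED_PREOP", "CLEARED_POSTOP")
ALL_PATTERNS <- c(CLEARING_PATTERNS, "PERSISTENT", "MIXED", "UD")

#' Call ctDNA status at one timepoint
#'
#' @param patient_id,timepoint the patient-timepoint to call.
#' @param origins origin table from [classify_cohort()].
#' @param variants validated variant observation table.
#' @param manifest validated sample manifest.
#' @param cftl_mode cell-free tumor load summary: `"max"` (default;
#'   maximum MAF among detected tumor-derived variants) or `"mean"`.
#' @return list with `patient_id`, `timepoint`, `status`,
#'   `n_tumor_variants_detected`, `cftl` (fraction; 0 when none detected).
#' @export
call_timepoint <- function(patient_id, timepoint, origins, variants,
                           manifest, cftl_mode = c("max", "mean")) {
  cftl_mode <- match.arg(cftl_mode)
  if (!timepoint %in% TIMEPOINTS) stop("unknown timepoint: ", timepoint)
  samp <- manifest[manifest$patient_id == patient_id &
                     manifest$material == "PLASMA" &
                     manifest$timepoint == timepoint, , drop = FALSE]
  if (nrow(samp) == 0L) {
    return(list(patient_id = patient_id, timepoint = timepoint,
                status = "NOT_ASSESSED", n_tumor_variants_detected = 0L,
                cftl = 0))
  }
  tumor_keys <- origins$key[origins$patient_id == patient_id &
                              origins$origin == "TUMOR"]
  obs <- variants[variants$sample_id == samp$sample_id[1L] &
                    variants$key %in% tumor_keys &
                    !is.na(variants$maf) & variants$maf > 0, , drop = FALSE]
  n <- nrow(obs)
  cftl <- if (n == 0L) 0 else switch(cftl_mode,
                                     max = max(obs$maf),
                                     mean = mean(obs$maf))
  list(patient_id = patient_id, timepoint = timepoint,
       status = if (n >= 1L) "POSITIVE" else "NEGATIVE",
       n_tumor_variants_detected = n, cftl = cftl)
}

#' Evaluability from a vector of timepoint statuses
#'
#' `UD` iff there is no POSITIVE call at any assessed timepoint;
#' `EVALUABLE` otherwise. All-NOT_ASSESSED trajectories are an error.
#'
#' @param status character vector of per-timepoint statuses.
#' @return `"EVALUABLE"` or `"UD"`.
#' @export
classify_evaluability <- function(status) {
  assessed <- status[status != "NOT_ASSESSED"]
  if (length(assessed) == 0L) {
    stop("evaluability error: no assessed timepoints")
  }
  if (any(assessed == "POSITIVE")) "EVALUABLE" else "UD"
}

#' Clearance pattern from a named status vector
#'
#' Precedence: `UD` when nothing is ever POSITIVE; else `PERSISTENT` when
#' every assessed post-baseline timepoint is POSITIVE;
#' `SUSTAINED_CLEARANCE` when every assessed post-baseline timepoint is
#' NEGATIVE; else, provided no POSITIVE call follows a NEGATIVE one
#' (no re-detection), `CLEARED_POST_ICI` / `CLEARED_PREOP` /
#' `CLEARED_POSTOP` by the earliest timepoint from which all later
#' assessed calls are NEGATIVE (a trailing-negative run starting at D14
#' counts as sustained clearance); any re-detection is `MIXED`.
#'
#' @param status named character vector, names drawn from the timepoint
#'   enumeration.
#' @return one of the pattern labels.
#' @export
summarize_clearance <- function(status) {
  stopifnot(all(names(status) %in% TIMEPOINTS))
  status <- status[TIMEPOINTS[TIMEPOINTS %in% names(status)]]
  if (classify_evaluability(status) == "UD") return("UD")
  post <- status[setdiff(names(status), "BASELINE")]
  post <- post[post != "NOT_ASSESSED"]
  if (length(post) == 0L) return("MIXED")  # only baseline assessed
  if (all(post == "POSITIVE")) return("PERSISTENT")
  if (all(post == "NEGATIVE")) return("SUSTAINED_CLEARANCE")
  pos_idx <- which(post == "POSITIVE")
  neg_idx <- which(post == "NEGATIVE")
  if (any(pos_idx > min(neg_idx))) return("MIXED")  # re-detection
  first_neg <- names(post)[min(neg_idx)]
  switch(first_neg,
         D14 = "SUSTAINED_CLEARANCE",
         POST_ICI = "CLEARED_POST_ICI",
         PREOP = "CLEARED_PREOP",
         POSTOP = "CLEARED_POSTOP",
         "MIXED")
}

#' Build per-patient status tables and clearance trajectories
#'
#' Calls every manifest patient at every timepoint of the enumeration and
#' summarizes each patient's trajectory (evaluability and clearance
#' pattern). D14 participates in trajectory patterns but the three
#' headline grouping flags exported for survival analysis are the
#' post-ICI, preoperative and postoperative statuses.
#'
#' @inheritParams call_timepoint
#' @return list with `status` (patient x timepoint long table) and
#'   `trajectories` (one row per patient: evaluability, pattern, and the
#'   five per-timepoint statuses as columns).
#' @export
build_trajectories <- function(origins, variants, manifest,
                               cftl_mode = c("max", "mean")) {
  cftl_mode <- match.arg(cftl_mode)
  patients <- sort(unique(manifest$patient_id))
  status_rows <- vector("list", length(patients) * length(TIMEPOINTS))
  traj_rows <- vector("list", length(patients))
  k <- 0L
  for (i in seq_along(patients)) {
    p <- patients[i]
    st <- character(length(TIMEPOINTS))
    names(st) <- TIMEPOINTS
    for (tp in TIMEPOINTS) {
      call <- call_timepoint(p, tp, origins, variants, manifest, cftl_mode)
      st[tp] <- call$status
      k <- k + 1L
      status_rows[[k]] <- data.frame(
        patient_id = p, timepoint = tp, status = call$status,
        n_tumor_variants_detected = call$n_tumor_variants_detected,
        cftl = call$cftl, stringsAsFactors = FALSE)
    }
    evaluability <- classify_evaluability(st)
    pattern <- if (evaluability == "UD") "UD" else summarize_clearance(st)
    traj_rows[[i]] <- data.frame(
      patient_id = p, evaluability = evaluability, pattern = pattern,
      baseline_status = st[["BASELINE"]], d14_status = st[["D14"]],
      post_ici_status = st[["POST_ICI"]], preop_status = st[["PREOP"]],
      postop_status = st[["POSTOP"]], stringsAsFactors = FALSE)
  }
  status <- do.call(rbind, status_rows[seq_len(k)])
  trajectories <- do.call(rbind, traj_rows)
  rownames(status) <- rownames(trajectories) <- NULL
  list(status = status, trajectories = trajectories)
}

#' End-of-treatment clearance grouping for survival comparisons
#'
#' Dichotomizes evaluable patients into `CLEARED` — a clearing trajectory
#' pattern, or ctDNA undetectable at both the preoperative and
#' postoperative draws (which recovers patients whose mid-course
#' trajectory was MIXED only because of an isolated missed detection) —
#' versus `NOT_CLEARED`. UD patients get `NA` (they join survival
#' analyses only as their own stratum).
#'
#' @param trajectories trajectory table from [build_trajectories()].
#' @return character vector parallel to the rows: `"CLEARED"`,
#'   `"NOT_CLEARED"` or `NA`.
#' @export
clearance_group <- function(trajectories) {
  ev <- trajectories$evaluability == "EVALUABLE"
  ends_neg <- trajectories$preop_status == "NEGATIVE" &
    trajectories$postop_status == "NEGATIVE"
  cleared <- ends_neg | trajectories$pattern %in% CLEARING_PATTERNS
  ifelse(ev, ifelse(cleared, "CLEARED", "NOT_CLEARED"), NA_character_)
}

#' Clearance counts among baseline-positive patients
#'
#' For each of the post-ICI, preoperative and postoperative timepoints,
#' counts patients with NEGATIVE status among those POSITIVE at baseline.
#' Denominators drop patients NOT_ASSESSED at the queried timepoint.
#' `baseline_definition = "any"` instead conditions on patients ever
#' POSITIVE (the evaluable group), since a patient first positive after
#' baseline is counted there by some conventions.
#'
#' @param trajectories trajectory table from [build_trajectories()].
#' @param baseline_definition `"baseline"` (POSITIVE at the baseline
#'   draw) or `"any"` (POSITIVE at any assessed timepoint).
#' @return data.frame with one row per queried timepoint: `timepoint`,
#'   `n_undetectable`, `n_assessed`, `fraction`.
#' @export
cohort_status_table <- function(trajectories,
                                baseline_definition = c("baseline", "any")) {
  baseline_definition <- match.arg(baseline_definition)
  base_pos <- if (baseline_definition == "baseline") {
    trajectories$baseline_status == "POSITIVE"
  } else {
    trajectories$evaluability == "EVALUABLE"
  }
  cols <- c(POST_ICI = "post_ici_status", PREOP = "preop_status",
            POSTOP = "postop_status")
  rows <- lapply(names(cols), function(tp) {
    st <- trajectories[[cols[[tp]]]][base_pos]
    st <- st[st != "NOT_ASSESSED"]
    data.frame(timepoint = tp,
               n_undetectable = sum(st == "NEGATIVE"),
               n_assessed = length(st),
               fraction = if (length(st)) sum(st == "NEGATIVE") / length(st)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_baseline_positive") <- sum(base_pos)
  out
}
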