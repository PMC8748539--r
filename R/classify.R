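#' Classify a patient's insertions as germline or somatic
#'
#' Tumor and matched-normal call sets (after consensus and polymorphic
#' filtering) are compared with a pairing window: a tumor call with a
#' same-chromosome, same-family normal call within `window_bp` (inclusive)
#' is a germline insertion, reported once at the tumor call's position;
#' unmatched tumor calls are tumor-specific somatic and unmatched normal
#' calls are normal-specific somatic. Pairing is one-to-one greedy
#' nearest-first with the same tie rules as [match_consensus()].
#'
#' @param tumor_calls,normal_calls TE-call data.frames for one patient.
#' @param window_bp Pairing window in bp (inclusive).
#' @return A data.frame of classified insertions with a `patient_class`
#'   column over `{germline, tumor_somatic, normal_somatic}`; germline rows
#'   additionally carry `normal_pos`, the matched normal call's position.
#' @export
classify_patient <- function(tumor_calls, normal_calls, window_bp = 100L) {
  if (window_bp <= 0L) stop("window_bp must be > 0", call. = FALSE)
  pats <- unique(c(tumor_calls$patient_id, normal_calls$patient_id))
  if (length(pats) > 1L) {
    stop("classify_patient: calls from mixed patients: ",
         paste(pats, collapse = ", "), call. = FALSE)
  }
  if (nrow(tumor_calls) > 0L && any(tumor_calls$tissue != "tumor")) {
    stop("tumor_calls must all have tissue == 'tumor'", call. = FALSE)
  }
  if (nrow(normal_calls) > 0L && any(normal_calls$tissue != "normal")) {
    stop("normal_calls must all have tissue == 'normal'", call. = FALSE)
  }
  pairs <- greedy_pair_match(tumor_calls, normal_calls, window_bp)

  germ <- tumor_calls[pairs$i, , drop = FALSE]
  if (nrow(germ) > 0L) {
    germ$patient_class <- "germline"
    germ$normal_pos <- normal_calls$pos[pairs$j]
  } else {
    germ$patient_class <- character(0)
    germ$normal_pos <- integer(0)
  }
  ts <- tumor_calls[setdiff(seq_len(nrow(tumor_calls)), pairs$i), , drop = FALSE]
  ns <- normal_calls[setdiff(seq_len(nrow(normal_calls)), pairs$j), , drop = FALSE]
  if (nrow(ts) > 0L) { ts$patient_class <- "tumor_somatic"; ts$normal_pos <- NA_integer_ }
  else { ts$patient_class <- character(0); ts$normal_pos <- integer(0) }
  if (nrow(ns) > 0L) { ns$patient_class <- "normal_somatic"; ns$normal_pos <- NA_integer_ }
  else { ns$patient_class <- character(0); ns$normal_pos <- integer(0) }

  out <- rbind(germ, ts, ns)
  out <- out[order(out$chrom, out$pos, out$patient_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a classified cohort
#'
#' @param classified Data.frame of classified insertions (rows from
#'   [classify_patient()] over all patients).
#' @return A list of class `classification_summary` with:
#'   * `per_patient`: one row per patient (sorted by `patient_id`) with
#'     germline / tumor_somatic / normal_somatic / total counts;
#'   * `totals`: cohort counts plus `somatic` (tumor + normal specific),
#'     `n_patients`, `n_patients_with_tumor_somatic`,
#'     `pct_patients_with_tumor_somatic` (half-up, 0 decimals), and the
#'     min/max per-patient tumor-somatic counts.
#' @export
summarize_classification <- function(classified) {
  classes <- c("germline", "tumor_somatic", "normal_somatic")
  if (nrow(classified) == 0L) {
    per_patient <- data.frame(patient_id = character(0),
                              germline = integer(0), tumor_somatic = integer(0),
                              normal_somatic = integer(0), total = integer(0))
    totals <- list(germline = 0L, tumor_somatic = 0L, normal_somatic = 0L,
                   somatic = 0L, total = 0L, n_patients = 0L,
                   n_patients_with_tumor_somatic = 0L,
                   pct_patients_with_tumor_somatic = NA_real_,
                   min_tumor_somatic_per_patient = NA_integer_,
                   max_tumor_somatic_per_patient = NA_integer_)
    return(structure(list(per_patient = per_patient, totals = totals),
                     class = "classification_summary"))
  }
  stopifnot(all(classified$patient_class %in% classes))
  tab <- table(factor(classified$patient_id),
               factor(classified$patient_class, levels = classes))
  per_patient <- data.frame(
    patient_id = rownames(tab),
    germline = as.integer(tab[, "germline"]),
    tumor_somatic = as.integer(tab[, "tumor_somatic"]),
    normal_somatic = as.integer(tab[, "normal_somatic"]),
    stringsAsFactors = FALSE
  )
  per_patient$total <- per_patient$germline + per_patient$tumor_somatic +
    per_patient$normal_somatic
  per_patient <- per_patient[order(per_patient$patient_id), ]
  rownames(per_patient) <- NULL

  n_with <- sum(per_patient$tumor_somatic >= 1L)
  totals <- list(
    germline = sum(per_patient$germline),
    tumor_somatic = sum(per_patient$tumor_somatic),
    normal_somatic = sum(per_patient$normal_somatic),
    somatic = sum(per_patient$tumor_somatic) + sum(per_patient$normal_somatic),
    total = sum(per_patient$total),
    n_patients = nrow(per_patient),
    n_patients_with_tumor_somatic = n_with,
    pct_patients_with_tumor_somatic =
      round_half_up(100 * n_with / nrow(per_patient), 0),
    min_tumor_somatic_per_patient = min(per_patient$tumor_somatic),
    max_tumor_somatic_per_patient = max(per_patient$tumor_somatic)
  )
  structure(list(per_patient = per_patient, totals = totals),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  t <- x$totals
  cat("classification_summary:", t$total, "insertions across", t$n_patients,
      "patients\n  germline:", t$germline, " tumor_somatic:", t$tumor_somatic,
      " normal_somatic:", t$normal_somatic, "\n")
  invisible(x)
}
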