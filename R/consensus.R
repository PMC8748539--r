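#' Reconcile two callers' MEI calls into consensus insertions
#'
#' Calls from the two callers are considered the same insertion when they lie
#' on the same chromosome, report the same TE family, and are within
#' `window_bp` of each other (inclusive). Matching is one-to-one, greedy
#' nearest-first: candidate pairs are ranked by distance (ties broken by the
#' smaller primary then secondary position) and accepted while both calls are
#' unused. The consensus position (`final_pos`) is the primary caller's
#' position, since the primary caller reports precise, evidence-backed sites
#' while the secondary caller reports imprecise sites with confidence
#' intervals.
#'
#' @param primary_calls,secondary_calls TE-call data.frames from
#'   [read_mei_calls()] for one sample.
#' @param window_bp Maximum pairing distance in bp (inclusive).
#' @return A list of class `consensus_result`:
#'   * `consensus`: data.frame of consensus insertions (`pos` equals
#'     `final_pos`, the primary position; `secondary_pos`, `ci_lo`, `ci_hi`
#'     carried from the secondary call; `subfamily` from the primary caller
#'     when both report one and disagree, with disagreements counted in
#'     `attr(, "subfamily_disagreements")`).
#'   * `unmatched_primary`, `unmatched_secondary`: calls without a partner,
#'     excluded downstream.
#' @export
match_consensus <- function(primary_calls, secondary_calls, window_bp = 100L) {
  if (window_bp <= 0L) stop("window_bp must be > 0", call. = FALSE)
  samples <- unique(c(primary_calls$sample_id, secondary_calls$sample_id))
  if (length(samples) > 1L) {
    stop("match_consensus: calls from mixed samples: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  pairs <- greedy_pair_match(primary_calls, secondary_calls, window_bp)

  cons <- primary_calls[pairs$i, , drop = FALSE]
  sec <- secondary_calls[pairs$j, , drop = FALSE]
  cons$final_pos <- cons$pos
  cons$secondary_pos <- sec$pos
  cons$ci_lo <- sec$ci_lo
  cons$ci_hi <- sec$ci_hi
  disagree <- !is.na(cons$subfamily) & !is.na(sec$subfamily) &
    cons$subfamily != sec$subfamily
  cons$subfamily <- ifelse(is.na(cons$subfamily), sec$subfamily, cons$subfamily)
  cons$caller <- rep("consensus", nrow(cons))
  rownames(cons) <- NULL
  attr(cons, "subfamily_disagreements") <- sum(disagree)

  up <- primary_calls[setdiff(seq_len(nrow(primary_calls)), pairs$i), , drop = FALSE]
  us <- secondary_calls[setdiff(seq_len(nrow(secondary_calls)), pairs$j), , drop = FALSE]
  rownames(up) <- rownames(us) <- NULL
  structure(list(consensus = cons, unmatched_primary = up,
                 unmatched_secondary = us),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result:", nrow(x$consensus), "consensus insertions;",
      nrow(x$unmatched_primary), "unmatched primary,",
      nrow(x$unmatched_secondary), "unmatched secondary\n")
  invisible(x)
}
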