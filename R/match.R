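# One-to-one greedy nearest-first matching of two call sets.
#
# Candidate pairs require identical chromosome and TE family and
# |pos_a - pos_b| <= window_bp (inclusive). Pairs are ranked by distance
# ascending, ties broken by the smaller position in `a`, then the smaller
# position in `b`, and accepted greedily, consuming each call once. The
# ranking makes the result deterministic and order-independent.
#
# Returns a data.frame with columns `i` (row index in a) and `j` (row index
# in b) for the accepted pairs.
greedy_pair_match <- function(a, b, window_bp) {
  stopifnot(window_bp > 0)
  empty <- data.frame(i = integer(0), j = integer(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)

  key_a <- paste(a$chrom, a$te_family, sep = "\r")
  key_b <- paste(b$chrom, b$te_family, sep = "\r")
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- integer(0)
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k)
    ib <- which(key_b == k)
    dm <- abs(outer(a$pos[ia], b$pos[ib], "-"))
    ok <- which(dm <= window_bp, arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    pairs_i <- c(pairs_i, ia[ok[, 1L]])
    pairs_j <- c(pairs_j, ib[ok[, 2L]])
    pairs_d <- c(pairs_d, dm[ok])
  }
  if (length(pairs_i) == 0L) return(empty)

  ord <- order(pairs_d, a$pos[pairs_i], b$pos[pairs_j], pairs_i, pairs_j)
  used_a <- rep(FALSE, nrow(a)); used_b <- rep(FALSE, nrow(b))
  keep <- logical(length(ord))
  for (idx in seq_along(ord)) {
    p <- ord[idx]
    i <- pairs_i[p]; j <- pairs_j[p]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      keep[idx] <- TRUE
    }
  }
  sel <- ord[keep]
  data.frame(i = pairs_i[sel], j = pairs_j[sel])
}
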