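# Independent brute-force oracles used to validate the matching and
# filtering operations.

# Exhaustive maximum-cardinality, minimum-total-distance bipartite matching.
# Candidate pairs are restricted to same chrom/family within the window; the
# instance is split into connected components and each is enumerated
# recursively. Returns a data.frame(i, j) sorted by i.
oracle_bipartite_match <- function(a, b, window_bp) {
  key_a <- paste(a$chrom, a$te_family, sep = "\r")
  key_b <- paste(b$chrom, b$te_family, sep = "\r")
  pairs <- NULL
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k); ib <- which(key_b == k)
    dm <- abs(outer(a$pos[ia], b$pos[ib], "-"))
    ok <- which(dm <= window_bp, arr.ind = TRUE)
    if (nrow(ok) == 0L) next
    pairs <- rbind(pairs, data.frame(i = ia[ok[, 1L]], j = ib[ok[, 2L]],
                                     d = dm[ok]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  # connected components via union-find over a-nodes (i) and b-nodes (-j)
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    k <- as.character(x)
    p <- get0(k, envir = parent, ifnotfound = x)
    if (identical(p, x)) return(x)
    r <- find(p); assign(k, r, envir = parent); r
  }
  union <- function(x, y) assign(as.character(find(x)), find(y), envir = parent)
  for (r in seq_len(nrow(pairs))) union(pairs$i[r], -pairs$j[r])
  comp <- vapply(seq_len(nrow(pairs)), function(r) find(pairs$i[r]), numeric(1))

  enum_best <- function(p) {
    if (nrow(p) == 0L) {
      return(list(size = 0L, dist = 0, match = data.frame(i = integer(0),
                                                          j = integer(0))))
    }
    i0 <- p$i[1L]
    best <- enum_best(p[p$i != i0, , drop = FALSE])  # leave i0 unmatched
    for (r in which(p$i == i0)) {
      sub <- enum_best(p[p$i != i0 & p$j != p$j[r], , drop = FALSE])
      size <- sub$size + 1L
      dist <- sub$dist + p$d[r]
      if (size > best$size || (size == best$size && dist < best$dist)) {
        best <- list(size = size, dist = dist,
                     match = rbind(p[r, c("i", "j")], sub$match))
      }
    }
    best
  }
  res <- do.call(rbind, lapply(split(pairs, comp), function(p) {
    enum_best(p)$match
  }))
  res <- res[order(res$i), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# O(n * m) brute-force polymorphic-filter count: calls with no same-family,
# same-chrom catalog entry within distance d (HERV-K always remains).
oracle_remaining_count <- function(calls, catalog, d) {
  n_remaining <- 0L
  for (i in seq_len(nrow(calls))) {
    if (calls$te_family[i] == "HERVK") {
      n_remaining <- n_remaining + 1L
      next
    }
    hit <- FALSE
    for (j in seq_len(nrow(catalog))) {
      if (calls$chrom[i] == catalog$chrom[j] &&
          calls$te_family[i] == catalog$te_family[j] &&
          abs(calls$pos[i] - catalog$pos[j]) <= d) {
        hit <- TRUE
        break
      }
    }
    if (!hit) n_remaining <- n_remaining + 1L
  }
  n_remaining
}

# Exact two-sided permutation p-value for the Spearman correlation of x, y
# (n small, no ties): proportion of the n! orderings of y with |rho| at
# least the observed |rho|.
oracle_spearman_perm_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  rho_obs <- stats::cor(rank(x), rank(y))
  all_p <- perms(rank(y))
  rhos <- vapply(all_p, function(p) stats::cor(rank(x), p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
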