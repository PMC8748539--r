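# Distance from each call to the nearest same-chromosome, same-family
# catalog entry (Inf when none exists).
nearest_catalog_distance <- function(calls, catalog) {
  n <- nrow(calls)
  d <- rep(Inf, n)
  if (n == 0L || nrow(catalog) == 0L) return(d)
  key_calls <- paste(calls$chrom, calls$te_family, sep = "\r")
  key_cat <- paste(catalog$chrom, catalog$te_family, sep = "\r")
  for (k in intersect(unique(key_calls), unique(key_cat))) {
    ic <- which(key_calls == k)
    cp <- sort(catalog$pos[key_cat == k])
    idx <- findInterval(calls$pos[ic], cp)
    lo <- ifelse(idx >= 1L, cp[pmax(idx, 1L)], NA_integer_)
    hi <- ifelse(idx < length(cp), cp[pmin(idx + 1L, length(cp))], NA_integer_)
    d[ic] <- pmin(abs(calls$pos[ic] - lo), abs(calls$pos[ic] - hi), na.rm = TRUE)
  }
  d
}

#' Scan polymorphic-filter distance thresholds
#'
#' For each distance `d`, counts the calls that have no same-family catalog
#' entry on the same chromosome within `|delta pos| <= d`. The resulting
#' table shows how aggressively each threshold removes catalogued polymorphic
#' insertions; counts are non-increasing in `d`. HERV-K calls are never
#' filtered (population catalogs of LINE-1-mediated insertions do not report
#' HERV-K), so they count as remaining at every distance.
#'
#' @param calls TE-call data.frame.
#' @param catalog Catalog data.frame from [read_polymorphic_catalog()].
#' @param distances Integer distances (bp), sorted ascending, all >= 0.
#' @return A data.frame with columns `distance` and `remaining`.
#' @export
scan_filter_distances <- function(calls, catalog, distances = seq(0L, 100L, 5L)) {
  if (any(distances < 0L)) stop("distances must be >= 0", call. = FALSE)
  if (is.unsorted(distances)) stop("distances must be sorted ascending", call. = FALSE)
  d <- nearest_catalog_distance(calls, catalog)
  exempt <- calls$te_family == "HERVK"
  remaining <- vapply(distances, function(x) sum(exempt | d > x), integer(1))
  data.frame(distance = as.integer(distances), remaining = remaining)
}

#' Remove polymorphic insertions by distance to a population catalog
#'
#' A call is removed when any same-family catalog entry on the same
#' chromosome lies within `distance_bp` (inclusive); matching is not
#' one-to-one — one catalog entry can absorb several nearby calls, since this
#' is filtering, not pairing. HERV-K calls always pass.
#'
#' @param calls TE-call data.frame.
#' @param catalog Catalog data.frame.
#' @param distance_bp Distance threshold in bp (>= 0).
#' @return The subset of `calls` that are patient-specific (survive the
#'   filter), with a `patient_specific` logical column set to `TRUE`.
#' @export
filter_polymorphic <- function(calls, catalog, distance_bp = 20L) {
  if (distance_bp < 0L) stop("distance_bp must be >= 0", call. = FALSE)
  d <- nearest_catalog_distance(calls, catalog)
  keep <- calls$te_family == "HERVK" | d > distance_bp
  out <- calls[keep, , drop = FALSE]
  out$patient_specific <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
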