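#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))`: strictly increasing, with
#' `M(1 - b) = -M(b)` and `M(0.5) = 0`. Apply [clamp_beta()] first when beta
#' values may touch the endpoints.
#'
#' @param beta Numeric vector/matrix of beta values in the open interval
#'   (0, 1).
#' @return M-values, same shape.
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  log2(beta / (1 - beta))
}

#' Inverse of [beta_to_m()]
#' @param m Numeric M-values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Select full-length LINE-1 elements
#'
#' An intact LINE-1 is about 6 kb; only (near) full-length elements retain an
#' internal promoter and autonomous activity. The default threshold is
#' slightly permissive at 5900 bp.
#'
#' @param repeats A `repeat_set` from [read_repeats()].
#' @param min_length_bp Minimum element length in bp.
#' @return The LINE-1 subset with `length >= min_length_bp`.
#' @export
select_full_length_line1 <- function(repeats, min_length_bp = 5900L) {
  out <- repeats[repeats$family == "LINE1" & repeats$length >= min_length_bp, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS windows around the most-5' ends of TE elements
#'
#' For a '+' strand element the most-5' end is its start; for '-' strand it
#' is its end. The window spans `flank_bp` on either side of that base (total
#' width `2 * flank_bp`), clamped at contig bounds when lengths are supplied.
#'
#' @param elements A `repeat_set` subset (stranded).
#' @param flank_bp Window half-width in bp.
#' @param contig_lengths Optional named integer vector of contig lengths for
#'   clamping.
#' @return Data.frame with `element_id`, `chrom`, `start`, `end` (1-based
#'   closed), `strand`, `subfamily`, `family`, `truncated`.
#' @export
te_tss_windows <- function(elements, flank_bp = 500L, contig_lengths = NULL) {
  n <- nrow(elements)
  plus <- elements$strand != "-"
  tss <- ifelse(plus, elements$start, elements$end)
  start <- ifelse(plus, tss - flank_bp, tss - flank_bp + 1L)
  end <- ifelse(plus, tss + flank_bp - 1L, tss + flank_bp)
  truncated <- rep(FALSE, n)
  clip_lo <- start < 1L
  start[clip_lo] <- 1L
  truncated <- truncated | clip_lo
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[elements$chrom]
    clip_hi <- !is.na(lim) & end > lim
    end[clip_hi] <- lim[clip_hi]
    truncated <- truncated | clip_hi
  }
  data.frame(
    element_id = sprintf("%s:%d-%d:%s", elements$chrom, elements$start,
                         elements$end, elements$subfamily),
    chrom = elements$chrom, start = as.integer(start), end = as.integer(end),
    strand = elements$strand, subfamily = elements$subfamily,
    family = elements$family, truncated = truncated,
    stringsAsFactors = FALSE
  )
}

#' Map methylation probes to TE TSS windows
#'
#' Each probe's single CpG coordinate is tested against the Alu and LINE-1
#' TSS windows. A probe inside windows of two or more distinct subfamilies of
#' one family is excluded (`multi_subfamily`); a probe inside both a LINE-1
#' and an Alu window is excluded (`cross_family`); a probe inside multiple
#' windows of a single subfamily is assigned to that subfamily. Remaining
#' probes are `assigned` or `unassigned`. Statuses partition the probe set.
#'
#' @param manifest Probe manifest data.frame (`probe_id`, `chrom`, `pos`).
#' @param alu_windows,line1_windows Window data.frames from
#'   [te_tss_windows()].
#' @return Data.frame with one row per probe: `probe_id`, `status`
#'   (`assigned`/`excluded`/`unassigned`), `family`, `subfamily`, `reason`
#'   (`multi_subfamily`/`cross_family` for exclusions).
#' @export
map_probes_to_windows <- function(manifest, alu_windows, line1_windows) {
  windows <- rbind(alu_windows, line1_windows)
  p_gr <- GenomicRanges::GRanges(manifest$chrom,
                                 IRanges::IRanges(manifest$pos, manifest$pos))
  out <- data.frame(probe_id = manifest$probe_id, status = "unassigned",
                    family = NA_character_, subfamily = NA_character_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (nrow(windows) > 0L) {
    w_gr <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start, windows$end))
    hits <- GenomicRanges::findOverlaps(p_gr, w_gr)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (i in unique(qi)) {
      fams <- unique(windows$family[si[qi == i]])
      subs <- unique(windows$subfamily[si[qi == i]])
      if (length(fams) > 1L) {
        out$status[i] <- "excluded"; out$reason[i] <- "cross_family"
      } else if (length(subs) > 1L) {
        out$status[i] <- "excluded"; out$reason[i] <- "multi_subfamily"
        out$family[i] <- fams
      } else {
        out$status[i] <- "assigned"
        out$family[i] <- fams
        out$subfamily[i] <- subs
      }
    }
  }
  out
}

#' Mean M-value per subfamily and sample
#'
#' @param assignment Probe assignment from [map_probes_to_windows()]; only
#'   `status == "assigned"` probes contribute.
#' @param m_matrix M-value matrix (probes x samples, rownames = probe ids).
#' @return Numeric matrix subfamily x sample of arithmetic means; subfamilies
#'   with zero assigned probes are absent. Attribute `"family"` maps each
#'   subfamily row to its TE family.
#' @export
subfamily_sample_means <- function(assignment, m_matrix) {
  a <- assignment[assignment$status == "assigned", , drop = FALSE]
  if (nrow(a) == 0L) {
    res <- matrix(numeric(0), nrow = 0L, ncol = ncol(m_matrix),
                  dimnames = list(NULL, colnames(m_matrix)))
    attr(res, "family") <- character(0)
    return(res)
  }
  missing <- setdiff(a$probe_id, rownames(m_matrix))
  if (length(missing) > 0L) {
    stop("assigned probe(s) missing from M-value matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  m <- m_matrix[a$probe_id, , drop = FALSE]
  grp <- factor(a$subfamily)
  sums <- rowsum(m, grp)
  counts <- as.vector(table(grp))
  res <- sums / counts
  fam <- vapply(levels(grp), function(s) a$family[match(s, a$subfamily)], "")
  attr(res, "family") <- fam
  res
}

#' Evolutionary age category of a TE subfamily
#'
#' LINE-1: `L1HS` and the `L1PA` subfamilies are young, other `L1P` names are
#' intermediate, `L1M` names are old. Alu: `AluY*` young, `AluS*`
#' intermediate, all other Alu-family names (AluJ, FLAM, FRAM, ...) old.
#'
#' @param subfamily Character vector of subfamily names.
#' @param family Matching TE families (`"LINE1"` or `"ALU"`), recycled if
#'   length 1.
#' @return Character vector over `{"young", "intermediate", "old"}`.
#' @export
age_category <- function(subfamily, family) {
  if (length(family) == 1L) family <- rep(family, length(subfamily))
  stopifnot(length(family) == length(subfamily))
  out <- character(length(subfamily))
  for (k in seq_along(subfamily)) {
    s <- subfamily[k]
    out[k] <- switch(family[k],
      LINE1 = {
        if (s == "L1HS" || startsWith(s, "L1PA")) "young"
        else if (startsWith(s, "L1P")) "intermediate"
        else if (startsWith(s, "L1M")) "old"
        else stop("cannot assign an age category to LINE-1 subfamily '", s,
                  "'", call. = FALSE)
      },
      ALU = {
        if (startsWith(s, "AluY")) "young"
        else if (startsWith(s, "AluS")) "intermediate"
        else if (startsWith(s, "Alu") || startsWith(s, "FLAM") ||
                 startsWith(s, "FRAM")) "old"
        else stop("cannot assign an age category to Alu subfamily '", s, "'",
                  call. = FALSE)
      },
      stop("age_category: family must be LINE1 or ALU, got '", family[k],
           "'", call. = FALSE)
    )
  }
  out
}

#' Mean M-value per age category and sample
#'
#' Two-step aggregation: probes are first averaged within each subfamily
#' ([subfamily_sample_means()]), then subfamily means are averaged
#' (unweighted) within each age category. Invariant to subfamily ordering.
#'
#' @param subfamily_means Matrix from [subfamily_sample_means()].
#' @return Matrix with rows named `<family>_<age>` and one column per sample.
#' @export
age_category_means <- function(subfamily_means) {
  fam <- attr(subfamily_means, "family")
  if (is.null(fam) || nrow(subfamily_means) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(subfamily_means),
                  dimnames = list(NULL, colnames(subfamily_means))))
  }
  age <- age_category(rownames(subfamily_means), fam)
  grp <- factor(paste(fam, age, sep = "_"))
  sums <- rowsum(subfamily_means, grp)
  counts <- as.vector(table(grp))
  sums / counts
}

# The six manifest region annotations, highest priority first.
REGION_PRIORITY <- c("TSS1500", "TSS200", "5UTR", "FirstExon", "Body", "3UTR")

#' Collapse a probe's region annotations to a single region
#'
#' Probes annotated to several gene regions are assigned the
#' highest-priority one: TSS1500, then TSS200, 5'UTR, the first exon, the
#' gene body, and lastly the 3'UTR.
#'
#' @param region_annotations Character vector of region names for one probe,
#'   or a single semicolon-separated string.
#' @return A single region name.
#' @export
region_priority_label <- function(region_annotations) {
  if (length(region_annotations) == 1L && grepl(";", region_annotations)) {
    region_annotations <- strsplit(region_annotations, ";", fixed = TRUE)[[1L]]
  }
  region_annotations <- region_annotations[nzchar(region_annotations)]
  if (length(region_annotations) == 0L) {
    stop("empty region annotation list", call. = FALSE)
  }
  idx <- match(region_annotations, REGION_PRIORITY)
  if (any(is.na(idx))) {
    stop("unknown region annotation(s): ",
         paste(region_annotations[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  REGION_PRIORITY[min(idx)]
}

#' Unpaired two-sample Wilcoxon (rank-sum) comparison
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]: exact null
#' enumeration for small untied samples, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @return List with `statistic` (the rank-sum U for the first group) and
#'   `p_value`.
#' @export
group_compare_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (all(values_a == values_a[1L]) && all(values_b == values_b[1L]) &&
      values_a[1L] == values_b[1L]) {
    # identical constant groups: every ranking equally extreme
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Region-prioritized overall methylation summary
#'
#' Collapses each probe's region annotations via [region_priority_label()]
#' and reports the mean M-value per region for each sample group, mirroring
#' the genome-wide region comparison that contextualizes the TE-specific
#' analysis.
#'
#' @param manifest Probe manifest with `region_annotations`.
#' @param m_matrix M-value matrix (probes x samples).
#' @param groups Named list mapping group name -> sample ids.
#' @return Data.frame with `region`, one mean-M column per group, and
#'   `n_probes`.
#' @export
region_methylation_summary <- function(manifest, m_matrix, groups) {
  keep <- manifest$probe_id %in% rownames(m_matrix) &
    !is.na(manifest$region_annotations) & nzchar(manifest$region_annotations)
  m <- manifest[keep, , drop = FALSE]
  region <- vapply(m$region_annotations, region_priority_label, "")
  out <- data.frame(region = REGION_PRIORITY, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    vals <- m_matrix[m$probe_id, groups[[g]], drop = FALSE]
    out[[paste0("mean_m_", g)]] <- vapply(REGION_PRIORITY, function(r) {
      sel <- region == r
      if (!any(sel)) NA_real_ else mean(vals[sel, , drop = FALSE])
    }, numeric(1))
  }
  out$n_probes <- vapply(REGION_PRIORITY, function(r) sum(region == r),
                         integer(1))
  rownames(out) <- NULL
  out
}
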