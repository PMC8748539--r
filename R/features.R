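#' Target-site duplication length histogram
#'
#' LINE-1-mediated integration leaves a short direct repeat (TSD) at the
#' insertion site; the length distribution of genuine events peaks around
#' 15 bp. Calls without a TSD are skipped and counted.
#'
#' @param calls TE-call data.frame with a `tsd_sequence` column.
#' @return List with `histogram` (data.frame `length`/`count`), `mode`
#'   (smallest length attaining the maximum count; `NA` when no call carries
#'   a TSD), `n_with_tsd` and `n_without_tsd`.
#' @export
tsd_length_histogram <- function(calls) {
  tsd <- calls$tsd_sequence
  len <- nchar(tsd[!is.na(tsd)])
  if (length(len) == 0L) {
    return(list(histogram = data.frame(length = integer(0), count = integer(0)),
                mode = NA_integer_, n_with_tsd = 0L,
                n_without_tsd = nrow(calls)))
  }
  tab <- table(len)
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab))
  hist <- hist[order(hist$length), ]
  rownames(hist) <- NULL
  mode <- hist$length[which.max(hist$count)]  # ties -> smallest length
  list(histogram = hist, mode = mode, n_with_tsd = length(len),
       n_without_tsd = nrow(calls) - length(len))
}

#' Base composition flanking insertion sites
#'
#' Computes per-position A/C/G/T fractions over a window of
#' `+/- flank_bp` around each insertion coordinate (position 0 is the base
#' at the insertion coordinate on the reference strand). Sites whose window
#' would run off a contig edge are excluded and counted; N bases are dropped
#' from the per-position denominator.
#'
#' @param genome A named `DNAStringSet` or a FASTA path.
#' @param calls TE-call data.frame.
#' @param flank_bp Window half-width in bp.
#' @return Data.frame with columns `position` (-flank..flank), `A`, `C`,
#'   `G`, `T` (fractions summing to 1 per position) and `n_sites`; the
#'   number of edge-excluded sites is in `attr(, "n_excluded")`.
#' @export
flanking_composition <- function(genome, calls, flank_bp = 50L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(calls$chrom), names(genome))
  if (length(missing) > 0L) {
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- Biostrings::width(genome)[match(calls$chrom, names(genome))]
  ok <- calls$pos - flank_bp >= 1L & calls$pos + flank_bp <= w
  cc <- calls[ok, , drop = FALSE]
  if (nrow(cc) == 0L) {
    out <- data.frame(position = seq(-flank_bp, flank_bp),
                      A = NA_real_, C = NA_real_, G = NA_real_, T = NA_real_,
                      n_sites = 0L)
    attr(out, "n_excluded") <- sum(!ok)
    return(out)
  }
  pieces <- lapply(unique(cc$chrom), function(ch) {
    idx <- cc$chrom == ch
    Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(cc$pos[idx] - flank_bp, cc$pos[idx] + flank_bp))
  })
  set <- do.call(c, pieces)
  cm <- Biostrings::consensusMatrix(set, baseOnly = TRUE)
  acgt <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  denom <- colSums(acgt)
  out <- data.frame(
    position = seq(-flank_bp, flank_bp),
    A = acgt["A", ] / denom, C = acgt["C", ] / denom,
    G = acgt["G", ] / denom, T = acgt["T", ] / denom,
    n_sites = as.integer(denom)
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  out
}

# Context label precedence, highest first.
CONTEXT_PRECEDENCE <- c("CDS", "UTR5", "UTR3", "intron", "intergenic")

#' Assign a genomic context to each insertion
#'
#' Each insertion is evaluated against the representative (longest)
#' transcript of every gene whose span it overlaps. Within one gene the label
#' precedence is CDS > UTR5 > UTR3 > intron (exonic positions of transcripts
#' without an annotated CDS fall through to intron, since the vocabulary has
#' no non-coding-exon class). Across multiple overlapped genes, the
#' insertion's summary label is the highest-precedence label among them; an
#' insertion overlapping representative transcripts of two or more distinct
#' genes has `overlapping_flag = TRUE`. No overlap at all is intergenic.
#'
#' @param calls TE-call data.frame.
#' @param genes A `gene_set` from [read_gene_models()].
#' @return Data.frame with one row per call: the call's identifying columns,
#'   `label`, `gene_ids` (comma-separated), `n_genes`, `overlapping_flag`.
#'   Per-gene labels are kept in `attr(, "gene_hits")` (`call` row index,
#'   `gene_id`, `gene_label`).
#' @export
assign_genomic_context <- function(calls, genes) {
  stopifnot(inherits(genes, "gene_set"))
  g <- genes$genes
  g_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$tx_start, g$tx_end))
  c_gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(c_gr, g_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  exons_by_gene <- split(genes$exons[, c("start", "end")], genes$exons$gene_id)
  cds_by_gene <- split(genes$cds[, c("start", "end")], genes$cds$gene_id)

  gene_label <- character(length(qi))
  for (h in seq_along(qi)) {
    pos <- calls$pos[qi[h]]
    gid <- g$gene_id[si[h]]
    cds <- cds_by_gene[[gid]]
    if (!is.null(cds) && nrow(cds) > 0L && any(cds$start <= pos & pos <= cds$end)) {
      gene_label[h] <- "CDS"
      next
    }
    ex <- exons_by_gene[[gid]]
    in_exon <- !is.null(ex) && nrow(ex) > 0L && any(ex$start <= pos & pos <= ex$end)
    if (in_exon && !is.null(cds) && nrow(cds) > 0L) {
      upstream_of_cds <- pos < min(cds$start)
      downstream_of_cds <- pos > max(cds$end)
      plus <- g$strand[si[h]] != "-"
      if (upstream_of_cds) gene_label[h] <- if (plus) "UTR5" else "UTR3"
      else if (downstream_of_cds) gene_label[h] <- if (plus) "UTR3" else "UTR5"
      else gene_label[h] <- "intron"  # exonic gap inside the CDS span
    } else {
      gene_label[h] <- "intron"
    }
  }

  n <- nrow(calls)
  label <- rep("intergenic", n)
  gene_ids <- rep(NA_character_, n)
  n_genes <- integer(n)
  if (length(qi) > 0L) {
    prec <- match(gene_label, CONTEXT_PRECEDENCE)
    for (i in unique(qi)) {
      sel <- qi == i
      label[i] <- CONTEXT_PRECEDENCE[min(prec[sel])]
      ids <- sort(unique(g$gene_id[si[sel]]))
      gene_ids[i] <- paste(ids, collapse = ",")
      n_genes[i] <- length(ids)
    }
  }
  keep <- intersect(c("patient_id", "tissue", "chrom", "pos", "te_family",
                      "subfamily", "patient_class"), names(calls))
  out <- cbind(calls[, keep, drop = FALSE],
               data.frame(label = label, gene_ids = gene_ids,
                          n_genes = n_genes,
                          overlapping_flag = n_genes >= 2L,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "gene_hits") <- data.frame(call = qi, gene_id = g$gene_id[si],
                                       gene_label = gene_label,
                                       stringsAsFactors = FALSE)
  out
}

#' Summarize genomic-context labels
#'
#' @param labels Output of [assign_genomic_context()].
#' @param by_family Also tabulate counts per TE family.
#' @return Data.frame with `label`, `count`, `pct` (percent of labeled
#'   insertions, rounded half-up to 2 decimals), plus one count column per TE
#'   family when `by_family = TRUE`. Also reports the number of insertions in
#'   overlapping genomic regions in `attr(, "n_overlapping")`.
#' @export
context_summary <- function(labels, by_family = FALSE) {
  lv <- factor(labels$label, levels = CONTEXT_PRECEDENCE)
  tab <- table(lv)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- round_half_up(100 * out$count / max(sum(out$count), 1L), 2)
  if (by_family && "te_family" %in% names(labels)) {
    ft <- table(lv, factor(labels$te_family))
    for (fam in colnames(ft)) out[[fam]] <- as.integer(ft[, fam])
  }
  attr(out, "n_overlapping") <- sum(labels$overlapping_flag)
  out
}

#' Gene-length distributions of inserted vs non-inserted genes
#'
#' A gene is "inserted" when at least one insertion overlaps its
#' representative-transcript span. Lengths are representative-transcript
#' genomic spans.
#'
#' @param genes A `gene_set`.
#' @param labels Output of [assign_genomic_context()].
#' @return List with `inserted_lengths`, `noninserted_lengths`, medians of
#'   each (`NA` when a stratum is empty), `n_inserted`, `n_genes` and
#'   `pct_inserted` (half-up, 2 decimals).
#' @export
gene_length_strata <- function(genes, labels) {
  stopifnot(inherits(genes, "gene_set"))
  hits <- attr(labels, "gene_hits")
  inserted <- unique(hits$gene_id)
  g <- genes$genes
  ins <- g$tx_length[g$gene_id %in% inserted]
  non <- g$tx_length[!g$gene_id %in% inserted]
  list(
    inserted_lengths = ins,
    noninserted_lengths = non,
    median_inserted = if (length(ins)) stats::median(ins) else NA_real_,
    median_noninserted = if (length(non)) stats::median(non) else NA_real_,
    n_inserted = length(ins),
    n_genes = nrow(g),
    pct_inserted = round_half_up(100 * length(ins) / max(nrow(g), 1L), 2)
  )
}

#' Overlap of insertions with common fragile sites
#'
#' @param calls TE-call data.frame.
#' @param cfs_intervals Interval data.frame from [read_intervals()].
#' @return List with `n_in_cfs`, `frac_in_cfs` (percent, half-up 2 dp),
#'   `n_cfs_hit` (intervals containing >= 1 insertion), `frac_cfs_hit`
#'   (percent of intervals). With no intervals all counts are zero and the
#'   fractions `NA`.
#' @export
cfs_overlap_summary <- function(calls, cfs_intervals) {
  if (nrow(cfs_intervals) == 0L) {
    return(list(n_in_cfs = 0L, frac_in_cfs = NA_real_,
                n_cfs_hit = 0L, frac_cfs_hit = NA_real_))
  }
  cfs_gr <- GenomicRanges::GRanges(
    cfs_intervals$chrom,
    IRanges::IRanges(cfs_intervals$start, cfs_intervals$end))
  c_gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(c_gr, cfs_gr)
  n_in <- length(unique(S4Vectors::queryHits(hits)))
  n_hit <- length(unique(S4Vectors::subjectHits(hits)))
  list(
    n_in_cfs = n_in,
    frac_in_cfs = round_half_up(100 * n_in / max(nrow(calls), 1L), 2),
    n_cfs_hit = n_hit,
    frac_cfs_hit = round_half_up(100 * n_hit / nrow(cfs_intervals), 2)
  )
}

#' Genes recurrently affected across patients
#'
#' A patient "affects" a gene when at least one of that patient's insertions
#' overlaps the gene's representative transcript; per-patient multiplicity is
#' collapsed (a patient counts once per gene).
#'
#' @param classified Classified cohort data.frame (with `patient_id`).
#' @param genes A `gene_set`.
#' @param min_patients Minimum distinct-patient count to report.
#' @return Data.frame of genes with `n_patients >= min_patients`, sorted by
#'   `n_patients` descending then gene name, with `n_insertions` and the
#'   insertion classes observed.
#' @export
recurrent_gene_report <- function(classified, genes, min_patients = 3L) {
  labels <- assign_genomic_context(classified, genes)
  hits <- attr(labels, "gene_hits")
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(0), name = character(0),
                      n_patients = integer(0), n_insertions = integer(0),
                      classes = character(0), stringsAsFactors = FALSE))
  }
  hits$patient_id <- classified$patient_id[hits$call]
  hits$patient_class <- if ("patient_class" %in% names(classified)) {
    classified$patient_class[hits$call]
  } else NA_character_
  agg <- do.call(rbind, lapply(split(hits, hits$gene_id), function(h) {
    data.frame(gene_id = h$gene_id[1L],
               n_patients = length(unique(h$patient_id)),
               n_insertions = nrow(h),
               classes = paste(sort(unique(h$patient_class)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n_patients >= min_patients, , drop = FALSE]
  agg$name <- genes$genes$name[match(agg$gene_id, genes$genes$gene_id)]
  agg <- agg[order(-agg$n_patients, agg$name), c("gene_id", "name",
                                                 "n_patients", "n_insertions",
                                                 "classes")]
  rownames(agg) <- NULL
  agg
}

#' Intersect affected genes with an external gene list
#'
#' Symbols are matched case-insensitively.
#'
#' @param affected_genes Data.frame with a `name` column (e.g. from
#'   [recurrent_gene_report()], or any gene table with per-gene provenance).
#' @param external_gene_list Character vector of gene symbols, or a path to a
#'   one-symbol-per-line file.
#' @return The rows of `affected_genes` whose symbol appears in the list,
#'   with a `list_symbol` column giving the matched external spelling.
#' @export
gene_list_intersection <- function(affected_genes, external_gene_list) {
  if (length(external_gene_list) == 1L && file.exists(external_gene_list)) {
    external_gene_list <- readLines(external_gene_list)
  }
  external_gene_list <- trimws(external_gene_list)
  external_gene_list <- external_gene_list[nzchar(external_gene_list)]
  idx <- match(toupper(affected_genes$name), toupper(external_gene_list))
  out <- affected_genes[!is.na(idx), , drop = FALSE]
  out$list_symbol <- external_gene_list[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}

#' Intronic insertions near exon boundaries
#'
#' For insertions labeled intronic, the distance to the nearest exon boundary
#' of the host gene's representative transcript is computed (minimum over
#' host genes where several overlap); insertions with distance
#' `<= max_dist_bp` (inclusive) are returned.
#'
#' @param labels Output of [assign_genomic_context()].
#' @param genes A `gene_set`.
#' @param max_dist_bp Inclusive distance threshold in bp.
#' @return Data.frame of qualifying insertions with `gene_id` and
#'   `exon_distance` columns.
#' @export
exon_proximity <- function(labels, genes, max_dist_bp = 100L) {
  hits <- attr(labels, "gene_hits")
  hits <- hits[hits$gene_label == "intron", , drop = FALSE]
  empty <- cbind(labels[0, , drop = FALSE],
                 data.frame(gene_id = character(0),
                            exon_distance = integer(0)))
  if (nrow(hits) == 0L) return(empty)
  exons_by_gene <- split(genes$exons[, c("start", "end")], genes$exons$gene_id)
  hits$exon_distance <- vapply(seq_len(nrow(hits)), function(k) {
    pos <- labels$pos[hits$call[k]]
    ex <- exons_by_gene[[hits$gene_id[k]]]
    if (is.null(ex) || nrow(ex) == 0L) return(NA_integer_)
    d <- pmax(ex$start - pos, pos - ex$end, 0L)
    as.integer(min(d))
  }, integer(1))
  # one row per call: nearest host-gene exon
  best <- do.call(rbind, lapply(split(hits, hits$call), function(h) {
    h[which.min(h$exon_distance), , drop = FALSE]
  }))
  best <- best[!is.na(best$exon_distance) &
                 best$exon_distance <= max_dist_bp, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  out <- cbind(labels[best$call, , drop = FALSE],
               data.frame(gene_id = best$gene_id,
                          exon_distance = best$exon_distance,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
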