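#' Read a VCF-like MEI call file from one caller
#'
#' Parses the minimal VCF-like carrier format used for mobile-element
#' insertion calls. Each record row carries `CHROM`, `POS` (1-based insertion
#' coordinate) and an INFO field with keys `MEITYPE` (required; one of LINE1,
#' ALU, SVA, HERVK), and optionally `SUBFAMILY`, `TSD` (target-site
#' duplication sequence), and `CILO`/`CIHI` (1-based confidence-interval
#' bounds, as reported by imprecise callers).
#'
#' @param path Path to the call file.
#' @param caller `"primary_caller"` (precise positions + TSD) or
#'   `"secondary_caller"` (positions + confidence interval).
#' @param patient_id Patient identifier the calls belong to.
#' @param tissue `"tumor"` or `"normal"`.
#' @param chr_style Chromosome-name normalization (see [pipeline_config()]).
#' @return A data.frame of TE calls with columns `patient_id`, `sample_id`,
#'   `tissue`, `chrom`, `pos`, `te_family`, `subfamily`, `tsd_sequence`,
#'   `caller`, `ci_lo`, `ci_hi`, `call_id`.
#' @export
read_mei_calls <- function(path, caller = c("primary_caller", "secondary_caller"),
                           patient_id, tissue = c("tumor", "normal"),
                           chr_style = "exact") {
  caller <- match.arg(caller)
  tissue <- match.arg(tissue)
  lines <- readLines(path)
  is_rec <- !startsWith(lines, "#") & nzchar(trimws(lines))
  recs <- lines[is_rec]
  lineno <- which(is_rec)
  n <- length(recs)
  out <- data.frame(
    patient_id = rep(patient_id, n),
    sample_id = rep(paste(patient_id, tissue, sep = "."), n),
    tissue = rep(tissue, n),
    chrom = character(n), pos = integer(n),
    te_family = character(n), subfamily = NA_character_,
    tsd_sequence = NA_character_, caller = rep(caller, n),
    ci_lo = NA_integer_, ci_hi = NA_integer_, call_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  for (k in seq_len(n)) {
    f <- strsplit(recs[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      stop("malformed MEI record (fewer than 8 fields) at line ", lineno[k],
           " of ", path, call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L) {
      stop("malformed MEI record (POS not a positive integer) at line ",
           lineno[k], " of ", path, call. = FALSE)
    }
    info <- parse_info(f[8L])
    fam <- info[["MEITYPE"]]
    if (is.null(fam)) {
      stop("malformed MEI record (missing MEITYPE) at line ", lineno[k],
           " of ", path, call. = FALSE)
    }
    if (!fam %in% TE_FAMILIES) {
      stop("unknown TE family '", fam, "' at line ", lineno[k], " of ", path,
           "; accepted values: ", paste(TE_FAMILIES, collapse = ", "),
           call. = FALSE)
    }
    tsd <- info[["TSD"]]
    if (!is.null(tsd) && !grepl("^[ACGTN]+$", tsd)) {
      stop("malformed TSD sequence '", tsd, "' at line ", lineno[k], " of ",
           path, call. = FALSE)
    }
    ci_lo <- info[["CILO"]]; ci_hi <- info[["CIHI"]]
    if (!is.null(ci_lo) || !is.null(ci_hi)) {
      ci_lo <- suppressWarnings(as.integer(ci_lo))
      ci_hi <- suppressWarnings(as.integer(ci_hi))
      if (is.na(ci_lo) || is.na(ci_hi) || ci_lo > pos || pos > ci_hi) {
        stop("malformed confidence interval at line ", lineno[k], " of ",
             path, " (require CILO <= POS <= CIHI)", call. = FALSE)
      }
      out$ci_lo[k] <- ci_lo; out$ci_hi[k] <- ci_hi
    }
    out$chrom[k] <- f[1L]
    out$pos[k] <- pos
    out$te_family[k] <- fam
    out$subfamily[k] <- info[["SUBFAMILY"]] %||% NA_character_
    out$tsd_sequence[k] <- tsd %||% NA_character_
    out$call_id[k] <- if (f[3L] == ".") NA_character_ else f[3L]
  }
  out$chrom <- normalize_chrom(out$chrom, chr_style)
  out
}

parse_info <- function(s) {
  if (s == "." || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2L) x[2L] else TRUE)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Write MEI calls in the VCF-like carrier format
#'
#' @param calls A TE-call data.frame as returned by [read_mei_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mei_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MEITYPE,Number=1,Type=String,Description=\"TE family\">",
    "##INFO=<ID=SUBFAMILY,Number=1,Type=String,Description=\"TE subfamily\">",
    "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication sequence\">",
    "##INFO=<ID=CILO,Number=1,Type=Integer,Description=\"Confidence interval lower bound\">",
    "##INFO=<ID=CIHI,Number=1,Type=Integer,Description=\"Confidence interval upper bound\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- paste0("MEITYPE=", calls$te_family)
  add <- function(info, key, val) {
    ifelse(is.na(val), info, paste0(info, ";", key, "=", val))
  }
  info <- add(info, "SUBFAMILY", calls$subfamily)
  info <- add(info, "TSD", calls$tsd_sequence)
  info <- add(info, "CILO", calls$ci_lo)
  info <- add(info, "CIHI", calls$ci_hi)
  recs <- paste(calls$chrom, calls$pos,
                ifelse(is.na(calls$call_id), ".", calls$call_id),
                "N", paste0("<INS:ME:", calls$te_family, ">"), ".", "PASS",
                info, sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds a gene set keyed by the representative transcript of each gene: the
#' transcript of maximal genomic span, with ties broken by the
#' lexicographically smallest transcript id. GFF3 1-based closed coordinates
#' are kept in the 1-based closed convention used throughout the package.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon (optional CDS) rows.
#' @param chr_style Chromosome-name normalization.
#' @return An object of class `gene_set`: a list with data.frames `genes`
#'   (one row per gene, representative transcript span), `exons` and `cds`
#'   (representative transcript only).
#' @export
read_gene_models <- function(path, chr_style = "exact") {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, "")

  gi <- which(type == "gene")
  ti <- which(type %in% c("mRNA", "transcript"))
  ei <- which(type == "exon")
  ci <- which(type == "CDS")

  tx_ids <- id[ti]
  if (any(is.na(parent[ei])) || !all(parent[ei] %in% tx_ids)) {
    bad <- setdiff(unique(parent[ei]), tx_ids)
    stop("orphan exon(s) in ", path, ": parent transcript(s) ",
         paste(stats::na.omit(c(bad, if (any(is.na(parent[ei]))) "<missing>")),
               collapse = ", "),
         " not found", call. = FALSE)
  }
  if (length(ci) > 0L && !all(parent[ci] %in% tx_ids)) {
    stop("orphan CDS in ", path, call. = FALSE)
  }
  if (!all(parent[ti] %in% id[gi])) {
    stop("transcript with unknown parent gene in ", path, call. = FALSE)
  }

  tx <- data.frame(
    tx_id = tx_ids,
    gene_id = parent[ti],
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))[ti], chr_style),
    strand = as.character(GenomicRanges::strand(gr))[ti],
    start = GenomicRanges::start(gr)[ti],
    end = GenomicRanges::end(gr)[ti],
    stringsAsFactors = FALSE
  )
  tx$span <- tx$end - tx$start + 1L
  # representative transcript: maximal span, ties -> smallest tx id
  ord <- order(tx$gene_id, -tx$span, tx$tx_id)
  tx_o <- tx[ord, ]
  rep_tx <- tx_o[!duplicated(tx_o$gene_id), ]

  gene_names <- as.character(gr$Name %||% id)[gi]
  gene_names[is.na(gene_names)] <- id[gi][is.na(gene_names)]
  gmap <- data.frame(gene_id = id[gi], name = gene_names,
                     stringsAsFactors = FALSE)
  genes <- merge(rep_tx, gmap, by = "gene_id", sort = TRUE)
  genes <- data.frame(
    gene_id = genes$gene_id, name = genes$name, chrom = genes$chrom,
    strand = genes$strand, tx_id = genes$tx_id,
    tx_start = genes$start, tx_end = genes$end, tx_length = genes$span,
    stringsAsFactors = FALSE
  )

  keep_feature <- function(idx) {
    d <- data.frame(
      tx_id = parent[idx],
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))[idx], chr_style),
      start = GenomicRanges::start(gr)[idx],
      end = GenomicRanges::end(gr)[idx],
      stringsAsFactors = FALSE
    )
    d <- d[d$tx_id %in% genes$tx_id, , drop = FALSE]
    d$gene_id <- genes$gene_id[match(d$tx_id, genes$tx_id)]
    d <- d[order(d$gene_id, d$start, d$end), ]
    rownames(d) <- NULL
    d[, c("gene_id", "tx_id", "chrom", "start", "end")]
  }
  exons <- keep_feature(ei)
  cds <- keep_feature(ci)

  # exon intervals must be sorted and non-overlapping within a transcript
  for (t in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == t, ]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)])) {
      stop("overlapping exons within transcript ", t, " in ", path,
           call. = FALSE)
    }
  }

  structure(list(genes = genes, exons = exons, cds = cds,
                 n_transcripts = nrow(tx)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes (", x$n_transcripts,
      "transcripts),", nrow(x$exons), "representative exons\n")
  invisible(x)
}

#' Read a repeat-annotation table
#'
#' Expects a tab-separated table with header columns `chrom`, `start`, `end`
#' (0-based half-open, RepeatMasker/BED convention), `strand`, `subfamily`.
#' Families are inferred from the subfamily prefix via [repeat_family()].
#'
#' @param path Path to the table.
#' @param chr_style Chromosome-name normalization.
#' @return An object of class `repeat_set`: a data.frame with 1-based closed
#'   `start`/`end`, `strand`, `subfamily`, `family` and `length` columns.
#' @export
read_repeats <- function(path, chr_style = "exact") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "subfamily")
  if (!all(need %in% names(d))) {
    stop("repeat table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$start >= d$end)) {
    stop("repeat table has start >= end at row(s) ",
         paste(utils::head(which(d$start >= d$end), 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = normalize_chrom(as.character(d$chrom), chr_style),
    start = as.integer(d$start) + 1L,
    end = as.integer(d$end),
    strand = as.character(d$strand),
    subfamily = as.character(d$subfamily),
    stringsAsFactors = FALSE
  )
  out$family <- repeat_family(out$subfamily)
  out$length <- out$end - out$start + 1L
  class(out) <- c("repeat_set", "data.frame")
  out
}

#' Write a repeat-annotation table (inverse of [read_repeats()])
#' @param repeats A `repeat_set` data.frame.
#' @param path Output path.
#' @export
write_repeats <- function(repeats, path) {
  d <- data.frame(chrom = repeats$chrom, start = repeats$start - 1L,
                  end = repeats$end, strand = repeats$strand,
                  subfamily = repeats$subfamily)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3+ rows (0-based half-open) converted to the package's 1-based closed
#' convention, so an interval written `chr1 0 10` has `start = 1`, `end = 10`
#' and length 10.
#'
#' @param path Path to a BED file.
#' @param chr_style Chromosome-name normalization.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path, chr_style = "exact") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("BED rows need >= 3 fields: ", path, call. = FALSE)
  start0 <- vapply(f, `[`, "", 2L)
  end0 <- vapply(f, `[`, "", 3L)
  if (any(!grepl("^-?[0-9]+$", c(start0, end0)))) {
    stop("non-integer BED bounds in ", path, call. = FALSE)
  }
  start0 <- as.integer(start0); end0 <- as.integer(end0)
  if (any(start0 < 0L)) stop("negative BED start in ", path, call. = FALSE)
  if (any(start0 >= end0)) stop("BED start >= end in ", path, call. = FALSE)
  data.frame(
    chrom = normalize_chrom(vapply(f, `[`, "", 1L), chr_style),
    start = start0 + 1L,
    end = end0,
    name = vapply(f, function(x) if (length(x) >= 4L) x[4L] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED (inverse of [read_intervals()])
#' @param intervals Data.frame with `chrom`, `start`, `end` (1-based closed)
#'   and optional `name`.
#' @param path Output path.
#' @export
write_intervals <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start - 1L, intervals$end)
  if (!is.null(intervals$name) && !all(is.na(intervals$name))) {
    cols <- c(cols, list(ifelse(is.na(intervals$name), ".", intervals$name)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a polymorphic-insertion catalog (BED-like)
#'
#' Columns: chrom, start, end (0-based half-open single-base sites), family,
#' and optionally subfamily. The catalog position used for distance filtering
#' is the 1-based site coordinate.
#'
#' @param path Path to the catalog.
#' @param chr_style Chromosome-name normalization.
#' @return A data.frame with `chrom`, `pos`, `te_family`, `subfamily`.
#' @export
read_polymorphic_catalog <- function(path, chr_style = "exact") {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "family",
                                       "subfamily")[1:5],
                         fill = TRUE)
  if (ncol(d) < 4L) stop("catalog needs >= 4 columns", call. = FALSE)
  bad <- setdiff(unique(d$family), TE_FAMILIES)
  if (length(bad) > 0L) {
    stop("unknown TE family in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    chrom = normalize_chrom(as.character(d$chrom), chr_style),
    pos = as.integer(d$start) + 1L,
    te_family = as.character(d$family),
    subfamily = if ("subfamily" %in% names(d)) as.character(d$subfamily) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Clamp beta values away from 0 and 1
#'
#' The logit2 M-value transform is undefined at the endpoints; beta values at
#' or beyond them are clamped to `[eps, 1 - eps]`.
#' @param beta Numeric vector/matrix of methylation beta values in `[0, 1]`.
#' @param eps Clamp margin.
#' @return Clamped values, same shape.
#' @export
clamp_beta <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(beta, eps), 1 - eps)
}

#' Read a beta-value matrix and its probe manifest
#'
#' @param beta_csv CSV with first column `probe_id` and one column per sample.
#' @param manifest_csv CSV with columns `probe_id`, `chrom`, `pos` (1-based
#'   CpG coordinate) and `region_annotations` (semicolon-separated subset of
#'   TSS1500, TSS200, 5UTR, FirstExon, Body, 3UTR).
#' @param chr_style Chromosome-name normalization.
#' @return List with `beta` (numeric matrix, probes x samples, clamped into
#'   the open unit interval) and `manifest` (data.frame).
#' @export
read_beta_and_manifest <- function(beta_csv, manifest_csv, chr_style = "exact") {
  b <- utils::read.csv(beta_csv, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(b)[1L] != "probe_id") stop("beta CSV must start with 'probe_id'", call. = FALSE)
  if (anyDuplicated(b$probe_id)) {
    stop("duplicated probe_id in beta matrix: ",
         paste(unique(b$probe_id[duplicated(b$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  beta <- as.matrix(b[, -1L, drop = FALSE])
  rownames(beta) <- b$probe_id
  m <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "region_annotations")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(m$probe_id)) stop("duplicated probe_id in manifest", call. = FALSE)
  missing <- setdiff(rownames(beta), m$probe_id)
  if (length(missing) > 0L) {
    stop("probe(s) in beta matrix absent from manifest: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  m$chrom <- normalize_chrom(m$chrom, chr_style)
  list(beta = clamp_beta(beta), manifest = m)
}

#' Read the clinical table
#'
#' @param path CSV with columns `patient_id`, `efs_time` (event-free survival
#'   in days, > 0), `event` (0/1), `age_dx` (years), `disease_status_dx`,
#'   `primary_site`.
#' @return A data.frame keyed by `patient_id`.
#' @export
read_clinical <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "efs_time", "event", "age_dx",
            "disease_status_dx", "primary_site")
  if (!all(need %in% names(d))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$efs_time <= 0)) stop("efs_time must be > 0", call. = FALSE)
  if (!all(d$event %in% c(0L, 1L))) stop("event must be 0 or 1", call. = FALSE)
  if (anyDuplicated(d$patient_id)) stop("duplicated patient_id in clinical table", call. = FALSE)
  d
}

#' Write a named list of tables as TSV reports
#'
#' Deterministic: tables are written in sorted name order, without quoting or
#' row names, so identical inputs yield byte-identical files.
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in sort(names(tables))) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
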