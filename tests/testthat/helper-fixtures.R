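# Shared fixtures: quick call constructors, a tiny GFF3 builder, and cached
# synthetic bundles (generated once per test run).

make_calls <- function(chrom, pos, te_family, patient_id = "P001",
                       tissue = "tumor", caller = "primary_caller",
                       subfamily = NA_character_, tsd = NA_character_) {
  n <- length(pos)
  data.frame(
    patient_id = rep(patient_id, n),
    sample_id = rep(paste(patient_id, tissue, sep = "."), n),
    tissue = rep(tissue, n),
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    te_family = rep_len(te_family, n),
    subfamily = rep_len(subfamily, n),
    tsd_sequence = rep_len(tsd, n),
    caller = rep(caller, n),
    ci_lo = rep(NA_integer_, n), ci_hi = rep(NA_integer_, n),
    call_id = sprintf("c%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

make_catalog <- function(chrom, pos, te_family, subfamily = NA_character_) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             te_family = rep_len(te_family, length(pos)),
             subfamily = rep_len(subfamily, length(pos)),
             stringsAsFactors = FALSE)
}

# Build a gene_set from a compact spec:
# genes: list(list(id, name?, chrom, strand, transcripts = list(
#   list(id, exons = 2-col matrix of 1-based closed intervals,
#        cds = optional matrix))))
make_gene_set <- function(genes) {
  lines <- "##gff-version 3"
  for (g in genes) {
    tx_spans <- t(vapply(g$transcripts, function(t) range(t$exons), numeric(2)))
    g_lo <- min(tx_spans); g_hi <- max(tx_spans)
    lines <- c(lines, sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      g$chrom, g_lo, g_hi, g$strand, g$id, g$name %||% g$id))
    for (t in g$transcripts) {
      lo <- min(t$exons); hi <- max(t$exons)
      lines <- c(lines, sprintf(
        "%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, lo, hi, g$strand, t$id, g$id))
      for (e in seq_len(nrow(t$exons))) {
        lines <- c(lines, sprintf(
          "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, t$exons[e, 1], t$exons[e, 2], g$strand, t$id, e, t$id))
      }
      if (!is.null(t$cds)) {
        for (e in seq_len(nrow(t$cds))) {
          lines <- c(lines, sprintf(
            "%s\ttest\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.c%d;Parent=%s",
            g$chrom, t$cds[e, 1], t$cds[e, 2], g$strand, t$id, e, t$id))
        }
      }
    }
  }
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  read_gene_models(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cached synthetic bundles ----------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

# Noiseless study-condition cohort: no caller errors, jitter within the
# consensus window, catalog jitter within the filter distance. The clinical
# table is removed so the pipeline run exercises the insertion/feature/
# methylation stages; the survival stage needs larger cohorts and is tested
# against its own simulations.
noiseless_bundle <- function() {
  if (is.null(.fixture_cache$noiseless)) {
    params <- sim_params(n_patients = 20L, fn_primary = 0, fn_secondary = 0,
                         fp_primary = 0, fp_secondary = 0)
    dir <- file.path(tempdir(), "teinsight-noiseless")
    b <- generate_cohort(params, seed = 20260924, out_dir = dir)
    file.remove(b$paths$clinical)
    .fixture_cache$noiseless <- b
  }
  .fixture_cache$noiseless
}

noiseless_pipeline <- function() {
  if (is.null(.fixture_cache$noiseless_run)) {
    b <- noiseless_bundle()
    .fixture_cache$noiseless_run <- suppressMessages(suppressWarnings(
      run_pipeline(b$dir, pipeline_config(),
                   out_dir = file.path(tempdir(), "teinsight-noiseless-out"))))
  }
  .fixture_cache$noiseless_run
}

# Small, fast parameter set for determinism and plumbing tests.
tiny_params <- function(...) {
  sim_params(n_patients = 3L,
             chrom_lengths = c(chr1 = 250000L, chr2 = 250000L),
             n_genes = 30L, mean_germline = 15, mean_tumor_somatic = 2,
             mean_normal_somatic = 1, n_polymorphic_sites = 10L,
             n_line1_elements = 16L, n_alu_elements = 30L, n_cfs = 4L,
             n_background_probes = 20L, ...)
}
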