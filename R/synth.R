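#' Simulation parameters for a synthetic tumor/normal MEI cohort
#'
#' Defines the study conditions the generator emulates: a small diploid-free
#' toy genome, paired tumor/normal two-caller call sets with planted
#' germline, somatic and polymorphic insertions, TSD lengths peaked at 15 bp,
#' AT-enriched flanks, gene-length-biased intronic targeting, TE TSS
#' methylation with young-LINE-1 tumor hypomethylation against a hypermethylated
#' background, and burden-dependent event-free survival.
#'
#' @param n_patients Number of patients (paired tumor/normal).
#' @param chrom_lengths Named integer vector of contig lengths.
#' @param n_genes Number of genes to place.
#' @param mean_germline,burden_dispersion Negative-binomial mean/size of the
#'   per-patient germline insertion count (the cohort shows strong
#'   between-patient burden heterogeneity; the dispersion is exposed rather
#'   than fixed).
#' @param mean_tumor_somatic,mean_normal_somatic Poisson means of per-patient
#'   somatic counts.
#' @param n_polymorphic_sites Cohort-level polymorphic insertion sites, also
#'   written (with jitter) to the population catalog.
#' @param polymorphic_carrier_prob Probability a patient carries a given
#'   polymorphic site (in both tissues).
#' @param family_probs Named probabilities over LINE1/ALU/SVA/HERVK for
#'   planted insertions (polymorphic sites are drawn from the
#'   LINE-1-mediated families only, since the catalog does not report
#'   HERV-K).
#' @param tsd_mode,tsd_sd,tsd_max TSD length distribution: probabilities
#'   proportional to a normal density at the integers `0..tsd_max`.
#' @param at_enrichment,at_flank_bp Excess A+T probability (over the 0.5
#'   background) applied to the genome within `+/- at_flank_bp` of each
#'   planted site.
#' @param p_genic,gene_length_bias_exponent Probability that a planted site
#'   targets a gene, and the exponent of the length bias (gene chosen with
#'   probability proportional to representative-transcript length to this
#'   power).
#' @param jitter_bp Secondary-caller position jitter, discrete uniform on
#'   `[-jitter_bp, jitter_bp]`; also the reported CI half-width.
#' @param fn_primary,fn_secondary,fp_primary,fp_secondary Per-caller
#'   false-negative and false-positive rates.
#' @param catalog_jitter_bp Independent jitter (uniform on +/- this) applied
#'   to polymorphic sites when written to the catalog, mimicking cross-study
#'   coordinate noise.
#' @param n_line1_elements,full_length_frac,n_alu_elements Repeat-annotation
#'   landscape used by the methylation stage.
#' @param n_cfs Number of common-fragile-site intervals.
#' @param n_background_probes Methylation probes outside TE TSS windows.
#' @param n_control_samples Normal-control methylation samples.
#' @param m_baseline_mean,m_probe_sd,m_noise_sd Per-probe baseline M-value
#'   distribution and per-measurement noise.
#' @param m_shift_young_line1,m_shift_alu,m_shift_background Planted
#'   tumor-minus-control mean M shifts: negative (hypomethylation) at young
#'   LINE-1 and Alu TSS probes, positive elsewhere (the background trends
#'   hypermethylated in tumors).
#' @param baseline_hazard Baseline event hazard per day.
#' @param burden_loghr Planted log hazard ratio per SD of insertion burden
#'   (negative: high burden is protective).
#' @param censor_rate Target censoring fraction (independent censoring).
#' @param min_site_separation Minimum bp between planted sites within a
#'   patient and from polymorphic sites.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 39L,
                       chrom_lengths = c(chr1 = 1500000L, chr2 = 1500000L),
                       n_genes = 240L,
                       mean_germline = 80, burden_dispersion = 5,
                       mean_tumor_somatic = 5, mean_normal_somatic = 1,
                       n_polymorphic_sites = 60L,
                       polymorphic_carrier_prob = 0.6,
                       family_probs = c(LINE1 = 0.33, ALU = 0.63,
                                        SVA = 0.035, HERVK = 0.005),
                       tsd_mode = 15L, tsd_sd = 1.5, tsd_max = 30L,
                       at_enrichment = 0.15, at_flank_bp = 10L,
                       p_genic = 0.5, gene_length_bias_exponent = 1,
                       jitter_bp = 30L,
                       fn_primary = 0.05, fn_secondary = 0.05,
                       fp_primary = 0.02, fp_secondary = 0.02,
                       catalog_jitter_bp = 5L,
                       n_line1_elements = 60L, full_length_frac = 0.4,
                       n_alu_elements = 150L,
                       n_cfs = 12L,
                       n_background_probes = 100L,
                       n_control_samples = 3L,
                       m_baseline_mean = 2, m_probe_sd = 0.4, m_noise_sd = 0.5,
                       m_shift_young_line1 = 0.5, m_shift_alu = 0.25,
                       m_shift_background = 0.2,
                       baseline_hazard = 0.001, burden_loghr = -0.7,
                       censor_rate = 0.2,
                       min_site_separation = 200L) {
  p <- as.list(environment())
  rates <- c(p$fn_primary, p$fn_secondary, p$fp_primary, p$fp_secondary,
             p$polymorphic_carrier_prob, p$censor_rate, p$p_genic)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p$family_probs) - 1) > 1e-8 || any(p$family_probs < 0)) {
    stop("family_probs must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(p$family_probs), TE_FAMILIES)) {
    stop("family_probs must be named over ", paste(TE_FAMILIES, collapse = ", "),
         call. = FALSE)
  }
  if (p$baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (p$n_patients < 1L) stop("need at least one patient", call. = FALSE)
  structure(p, class = "sim_params")
}

# TSD length sampler: discretized unimodal distribution on 0..tsd_max with
# the configured mode.
sample_tsd_lengths <- function(n, params) {
  support <- 0:params$tsd_max
  pr <- stats::dnorm(support, mean = params$tsd_mode, sd = params$tsd_sd)
  sample(support, n, replace = TRUE, prob = pr / sum(pr))
}

random_dna <- function(n_each) {
  vapply(n_each, function(k) {
    if (k == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, "")
}

# Subfamily vocabulary for planted insertions (patient-specific insertions
# are dominated by evolutionarily young subfamilies).
SUBFAMILY_POOL <- list(
  LINE1 = list(names = c("L1HS", "L1PA2", "L1PA3", "L1P1", "L1MA4"),
               probs = c(0.45, 0.30, 0.20, 0.03, 0.02)),
  ALU = list(names = c("AluYa5", "AluYb8", "AluY", "AluSx", "AluJb"),
             probs = c(0.30, 0.25, 0.25, 0.15, 0.05)),
  SVA = list(names = c("SVA_D", "SVA_E", "SVA_F"), probs = c(0.5, 0.3, 0.2)),
  HERVK = list(names = c("HERVK10", "HERVK11"), probs = c(0.6, 0.4))
)

sample_subfamily <- function(families) {
  vapply(families, function(f) {
    pool <- SUBFAMILY_POOL[[f]]
    sample(pool$names, 1L, prob = pool$probs)
  }, "")
}

# Rejection-sample `n` insertion sites respecting a minimum separation from
# `occupied` (list chrom -> positions) and, optionally, gene-length-biased
# genic targeting. Returns data.frame(chrom, pos, gene_id).
place_sites <- function(n, params, genes, occupied, edge = 700L,
                        max_try = 200L) {
  chroms <- names(params$chrom_lengths)
  gene_w <- if (!is.null(genes)) {
    genes$tx_length^params$gene_length_bias_exponent
  }
  chrom <- character(n); pos <- integer(n); gene_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      genic <- !is.null(genes) && stats::runif(1) < params$p_genic
      if (genic) {
        g <- sample(nrow(genes), 1L, prob = gene_w)
        ch <- genes$chrom[g]
        p <- sample(genes$tx_start[g]:genes$tx_end[g], 1L)
        gid <- genes$gene_id[g]
      } else {
        ch <- sample(chroms, 1L, prob = params$chrom_lengths)
        p <- sample(seq(edge, params$chrom_lengths[[ch]] - edge), 1L)
        gid <- NA_character_
      }
      if (p < edge || p > params$chrom_lengths[[ch]] - edge) next
      occ <- occupied[[ch]]
      if (is.null(occ) || !any(abs(occ - p) < params$min_site_separation)) {
        occupied[[ch]] <- c(occ, p)
        chrom[i] <- ch; pos[i] <- p; gene_id[i] <- gid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " insertion sites: genome capacity ",
           "exceeded at the configured minimum separation", call. = FALSE)
    }
  }
  list(sites = data.frame(chrom = chrom, pos = pos, gene_id = gene_id,
                          stringsAsFactors = FALSE),
       occupied = occupied)
}

# Build the toy gene annotation: non-overlapping genes laid down per
# chromosome with 2-8 exons, a CDS for ~80% of genes, and a shorter second
# transcript for ~30% (so representative-transcript selection is exercised).
synth_gene_models <- function(params) {
  chroms <- names(params$chrom_lengths)
  cursors <- stats::setNames(rep(6000L, length(chroms)), chroms)
  rows <- list()
  gi <- 0L
  while (gi < params$n_genes) {
    ch <- chroms[which.min(cursors / params$chrom_lengths[chroms])]
    span <- as.integer(round(exp(stats::rnorm(1, log(4500), 0.8))))
    span <- max(1500L, min(40000L, span))
    gap <- sample(1500L:4000L, 1L)
    start <- cursors[[ch]] + gap
    end <- start + span - 1L
    if (end > params$chrom_lengths[[ch]] - 6000L) {
      cursors[[ch]] <- params$chrom_lengths[[ch]]  # chromosome full
      if (all(cursors >= params$chrom_lengths[chroms] - 12000L)) break
      next
    }
    gi <- gi + 1L
    cursors[[ch]] <- end
    gene_id <- sprintf("g%04d", gi)
    name <- sprintf("GENE%04d", gi)
    strand <- sample(c("+", "-"), 1L)
    k <- sample(2:8, 1L)
    ew <- max(50L, as.integer(round(span * 0.08 / k)))
    ex_start <- start + as.integer(floor((span - ew) * (seq_len(k) - 1L) / (k - 1L)))
    ex_end <- ex_start + ew - 1L
    coding <- stats::runif(1) < 0.8
    rows[[length(rows) + 1L]] <- list(
      gene_id = gene_id, name = name, chrom = ch, strand = strand,
      start = start, end = end, ex_start = ex_start, ex_end = ex_end,
      coding = coding,
      alt_tx = stats::runif(1) < 0.3
    )
  }
  rows
}

write_gff3 <- function(gene_rows, path) {
  lines <- "##gff-version 3"
  for (g in gene_rows) {
    a <- function(feature, start, end, attrs) {
      sprintf("%s\tteinsight\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, feature, start, end, g$strand, attrs)
    }
    tx1 <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               a("gene", g$start, g$end,
                 sprintf("ID=%s;Name=%s", g$gene_id, g$name)),
               a("mRNA", g$start, g$end,
                 sprintf("ID=%s;Parent=%s", tx1, g$gene_id)))
    for (e in seq_along(g$ex_start)) {
      lines <- c(lines, a("exon", g$ex_start[e], g$ex_end[e],
                          sprintf("ID=%s.e%d;Parent=%s", tx1, e, tx1)))
    }
    if (g$coding) {
      ew <- g$ex_end[1L] - g$ex_start[1L] + 1L
      cds_lo <- g$ex_start[1L] + ew %/% 2L
      cds_hi <- g$ex_end[length(g$ex_end)] - ew %/% 2L
      ci <- 0L
      for (e in seq_along(g$ex_start)) {
        lo <- max(g$ex_start[e], cds_lo); hi <- min(g$ex_end[e], cds_hi)
        if (lo <= hi) {
          ci <- ci + 1L
          lines <- c(lines, a("CDS", lo, hi,
                              sprintf("ID=%s.c%d;Parent=%s", tx1, ci, tx1)))
        }
      }
    }
    if (g$alt_tx) {
      tx2 <- paste0(g$gene_id, ".t2")
      span <- g$end - g$start + 1L
      lo <- g$start + as.integer(span * 0.2)
      hi <- g$end - as.integer(span * 0.2)
      lines <- c(lines,
                 a("mRNA", lo, hi, sprintf("ID=%s;Parent=%s", tx2, g$gene_id)),
                 a("exon", lo, hi, sprintf("ID=%s.e1;Parent=%s", tx2, tx2)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Place repeat elements with well-separated TSSs so TE TSS windows are
# unambiguous.
synth_repeats <- function(params) {
  n_fl <- as.integer(round(params$n_line1_elements * params$full_length_frac))
  n_tr <- params$n_line1_elements - n_fl
  lens <- c(sample(6000:6150, n_fl, replace = TRUE),
            sample(500:3000, n_tr, replace = TRUE),
            sample(280:320, params$n_alu_elements, replace = TRUE))
  subs <- c(sample(c("L1HS", "L1PA2", "L1PA4", "L1P1", "L1MA3"), n_fl,
                   replace = TRUE, prob = c(0.35, 0.25, 0.15, 0.15, 0.10)),
            sample(c("L1HS", "L1PA3", "L1P2", "L1MA4", "L1MB3"), n_tr,
                   replace = TRUE),
            sample(c("AluYa5", "AluYb8", "AluY", "AluSx", "AluSp", "AluJb",
                     "AluJo", "FLAM_C"), params$n_alu_elements,
                   replace = TRUE,
                   prob = c(0.17, 0.13, 0.15, 0.20, 0.10, 0.12, 0.08, 0.05)))
  n <- length(lens)
  chroms <- names(params$chrom_lengths)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  chrom <- character(n); start <- integer(n)
  for (i in seq_len(n)) {
    for (try in seq_len(500L)) {
      ch <- sample(chroms, 1L, prob = params$chrom_lengths)
      lo <- sample(seq(1200L, params$chrom_lengths[[ch]] - lens[i] - 1200L), 1L)
      occ <- occupied[[ch]]
      # separate element ends (possible TSSs) by > 2 * the 500 bp TSS flank
      if (is.null(occ) ||
          (!any(abs(occ - lo) < 1200L) &&
           !any(abs(occ - (lo + lens[i])) < 1200L))) {
        occupied[[ch]] <- c(occ, lo, lo + lens[i])
        chrom[i] <- ch; start[i] <- lo
        break
      }
      if (try == 500L) stop("could not place repeat elements", call. = FALSE)
    }
  }
  out <- data.frame(
    chrom = chrom, start = start + 1L, end = start + lens,
    strand = sample(c("+", "-"), n, replace = TRUE),
    subfamily = subs, stringsAsFactors = FALSE
  )
  out$family <- repeat_family(out$subfamily)
  out$length <- out$end - out$start + 1L
  class(out) <- c("repeat_set", "data.frame")
  out
}

#' Emit one caller's call set for a sample from planted truth
#'
#' The primary caller reports exact positions and TSD strings; the secondary
#' caller reports jittered positions (discrete uniform on
#' `[-jitter_bp, jitter_bp]`) with a confidence interval of half-width
#' `jitter_bp`. False negatives drop each true call independently; false
#' positives add `Binomial(n_true, fp_rate)` spurious calls at random
#' positions, identified by a `fp_` call-id prefix. Draws come from the
#' current RNG stream.
#'
#' @param sample_truth Data.frame of the sample's true insertions
#'   (`insertion_id`, `chrom`, `pos`, `te_family`, `subfamily`,
#'   `tsd_sequence`).
#' @param caller `"primary_caller"` or `"secondary_caller"`.
#' @param params A `sim_params` object (jitter and error rates).
#' @param patient_id,tissue Sample identity.
#' @return A TE-call data.frame in [read_mei_calls()] layout.
#' @export
emit_caller_calls <- function(sample_truth, caller, params, patient_id, tissue) {
  fn <- if (caller == "primary_caller") params$fn_primary else params$fn_secondary
  fp <- if (caller == "primary_caller") params$fp_primary else params$fp_secondary
  n <- nrow(sample_truth)
  keep <- if (n > 0L) stats::runif(n) >= fn else logical(0)
  tt <- sample_truth[keep, , drop = FALSE]
  m <- nrow(tt)
  if (caller == "primary_caller") {
    pos <- tt$pos
    tsd <- tt$tsd_sequence
    ci_lo <- rep(NA_integer_, m); ci_hi <- rep(NA_integer_, m)
  } else {
    jit <- if (m > 0L) sample(seq(-params$jitter_bp, params$jitter_bp), m,
                              replace = TRUE) else integer(0)
    pos <- tt$pos + jit
    tsd <- rep(NA_character_, m)
    ci_lo <- pos - params$jitter_bp; ci_hi <- pos + params$jitter_bp
  }
  calls <- data.frame(
    patient_id = rep(patient_id, m),
    sample_id = rep(paste(patient_id, tissue, sep = "."), m),
    tissue = rep(tissue, m), chrom = tt$chrom, pos = as.integer(pos),
    te_family = tt$te_family, subfamily = tt$subfamily,
    tsd_sequence = tsd, caller = rep(caller, m),
    ci_lo = as.integer(ci_lo), ci_hi = as.integer(ci_hi),
    call_id = tt$insertion_id, stringsAsFactors = FALSE
  )
  n_fp <- if (n > 0L && fp > 0) stats::rbinom(1L, n, fp) else 0L
  if (n_fp > 0L) {
    chroms <- names(params$chrom_lengths)
    ch <- sample(chroms, n_fp, replace = TRUE, prob = params$chrom_lengths)
    p <- vapply(ch, function(c_) {
      sample(seq(700L, params$chrom_lengths[[c_]] - 700L), 1L)
    }, integer(1))
    fam <- sample(names(params$family_probs), n_fp, replace = TRUE,
                  prob = params$family_probs)
    fpc <- data.frame(
      patient_id = rep(patient_id, n_fp),
      sample_id = rep(paste(patient_id, tissue, sep = "."), n_fp),
      tissue = rep(tissue, n_fp), chrom = ch, pos = as.integer(p),
      te_family = fam, subfamily = sample_subfamily(fam),
      tsd_sequence = NA_character_, caller = rep(caller, n_fp),
      ci_lo = if (caller == "secondary_caller") as.integer(p - params$jitter_bp) else NA_integer_,
      ci_hi = if (caller == "secondary_caller") as.integer(p + params$jitter_bp) else NA_integer_,
      call_id = sprintf("fp_%s_%s_%s_%03d", patient_id, tissue,
                        substr(caller, 1, 4), seq_len(n_fp)),
      stringsAsFactors = FALSE
    )
    calls <- rbind(calls, fpc)
  }
  ord <- order(calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Simulate clinical event-free-survival records from insertion burdens
#'
#' Event times are exponential with hazard
#' `h0 * exp(beta * standardized burden)`; censoring is independent
#' exponential calibrated so that roughly `censor_rate` of records are
#' censored when the burden effect is null. Draws come from the current RNG
#' stream.
#'
#' @param burdens Data.frame with `patient_id` and `burden`.
#' @param params A `sim_params` object (`baseline_hazard`, `burden_loghr`,
#'   `censor_rate`).
#' @return A clinical data.frame ([read_clinical()] layout).
#' @export
simulate_clinical <- function(burdens, params) {
  if (params$baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  n <- nrow(burdens)
  b <- burdens$burden
  z <- if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else rep(0, n)
  rate <- params$baseline_hazard * exp(params$burden_loghr * z)
  t_event <- stats::rexp(n, rate)
  cr <- params$censor_rate
  if (cr <= 0) {
    time <- t_event; event <- rep(1L, n)
  } else {
    c_rate <- params$baseline_hazard * cr / max(1 - cr, 1e-12)
    t_cens <- stats::rexp(n, c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  data.frame(
    patient_id = burdens$patient_id,
    efs_time = pmax(time, 1e-3),
    event = event,
    age_dx = round(stats::runif(n, 8, 30), 1),
    disease_status_dx = sample(c("non_metastatic", "metastatic"), n,
                               replace = TRUE, prob = c(0.75, 0.25)),
    primary_site = sample(c("leg", "arm", "other"), n, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic cohort bundle with planted truth
#'
#' Writes a toy genome (FASTA), gene models (GFF3), repeat annotation, CFS
#' intervals (BED), a polymorphic catalog (BED), per-sample two-caller MEI
#' call sets (VCF-like), methylation beta matrix + probe manifest (CSV), a
#' per-patient expression table (CSV), a clinical table (CSV), and a truth
#' ledger (TSV) sufficient to recompute every downstream summary.
#' Deterministic given `(params, seed)`.
#'
#' @param params A `sim_params` object.
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `dir`, a named `paths` list, the `truth`
#'   ledger (`insertions`, `patients`, `probes`), `params`, and the in-memory
#'   `genome`.
#' @export
generate_cohort <- function(params, seed, out_dir) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dir.create(file.path(out_dir, "calls"), showWarnings = FALSE)
  patients <- sprintf("P%03d", seq_len(params$n_patients))

  # --- genome ---------------------------------------------------------------
  chroms <- names(params$chrom_lengths)
  genome_chars <- lapply(params$chrom_lengths, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })

  # --- annotations ----------------------------------------------------------
  gene_rows <- synth_gene_models(params)
  genes_df <- do.call(rbind, lapply(gene_rows, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, tx_start = g$start,
               tx_end = g$end, tx_length = g$end - g$start + 1L,
               name = g$name, stringsAsFactors = FALSE)
  }))
  repeats <- synth_repeats(params)
  cfs <- data.frame(
    chrom = sample(chroms, params$n_cfs, replace = TRUE,
                   prob = params$chrom_lengths),
    stringsAsFactors = FALSE
  )
  cfs$len <- sample(20000:60000, params$n_cfs, replace = TRUE)
  cfs$start <- vapply(seq_len(params$n_cfs), function(i) {
    sample(seq(1L, params$chrom_lengths[[cfs$chrom[i]]] - cfs$len[i]), 1L)
  }, integer(1))
  cfs <- data.frame(chrom = cfs$chrom, start = cfs$start,
                    end = cfs$start + cfs$len - 1L,
                    name = sprintf("CFS%02d", seq_len(params$n_cfs)),
                    stringsAsFactors = FALSE)

  # --- polymorphic sites + catalog -----------------------------------------
  lm_probs <- params$family_probs[c("LINE1", "ALU", "SVA")]
  lm_probs <- lm_probs / sum(lm_probs)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  ps <- place_sites(params$n_polymorphic_sites, params, genes_df, occupied)
  poly_occupied <- ps$occupied
  poly <- ps$sites
  poly$te_family <- sample(names(lm_probs), nrow(poly), replace = TRUE,
                           prob = lm_probs)
  poly$subfamily <- sample_subfamily(poly$te_family)
  poly$tsd_length <- sample_tsd_lengths(nrow(poly), params)
  poly$tsd_sequence <- random_dna(poly$tsd_length)
  poly$insertion_id <- sprintf("poly%04d", seq_len(nrow(poly)))
  cat_jit <- sample(seq(-params$catalog_jitter_bp, params$catalog_jitter_bp),
                    nrow(poly), replace = TRUE)
  catalog <- data.frame(chrom = poly$chrom, start = poly$pos + cat_jit - 1L,
                        end = poly$pos + cat_jit, family = poly$te_family,
                        subfamily = poly$subfamily, stringsAsFactors = FALSE)

  # --- per-patient planted insertions --------------------------------------
  ins_list <- list()
  carried <- matrix(FALSE, nrow(poly), params$n_patients,
                    dimnames = list(poly$insertion_id, patients))
  iid <- 0L
  for (pi in seq_along(patients)) {
    pid <- patients[pi]
    n_g <- stats::rnbinom(1L, size = params$burden_dispersion,
                          mu = params$mean_germline)
    n_ts <- stats::rpois(1L, params$mean_tumor_somatic)
    n_ns <- stats::rpois(1L, params$mean_normal_somatic)
    n_all <- n_g + n_ts + n_ns
    pl <- place_sites(n_all, params, genes_df, poly_occupied)
    sites <- pl$sites  # patient-specific occupancy is not added globally
    cls <- c(rep("germline", n_g), rep("tumor_somatic", n_ts),
             rep("normal_somatic", n_ns))
    fam <- sample(names(params$family_probs), n_all, replace = TRUE,
                  prob = params$family_probs)
    tsd_len <- sample_tsd_lengths(n_all, params)
    ids <- sprintf("ins%06d", iid + seq_len(n_all))
    iid <- iid + n_all
    ins_list[[pid]] <- data.frame(
      insertion_id = ids, patient_id = pid, chrom = sites$chrom,
      pos = sites$pos, te_family = fam, subfamily = sample_subfamily(fam),
      true_class = cls, tsd_length = tsd_len,
      tsd_sequence = random_dna(tsd_len),
      target_gene_id = sites$gene_id, stringsAsFactors = FALSE
    )
    carried[, pi] <- stats::runif(nrow(poly)) < params$polymorphic_carrier_prob
  }
  ins <- do.call(rbind, ins_list)
  rownames(ins) <- NULL
  poly_truth <- data.frame(
    insertion_id = poly$insertion_id, patient_id = "cohort",
    chrom = poly$chrom, pos = poly$pos, te_family = poly$te_family,
    subfamily = poly$subfamily, true_class = "polymorphic",
    tsd_length = poly$tsd_length, tsd_sequence = poly$tsd_sequence,
    target_gene_id = poly$gene_id, stringsAsFactors = FALSE
  )
  truth_insertions <- rbind(ins, poly_truth)

  # --- AT enrichment at planted sites --------------------------------------
  all_sites <- unique(rbind(ins[, c("chrom", "pos")],
                            poly[, c("chrom", "pos")]))
  pr_at <- c((0.5 + params$at_enrichment) / 2, (0.5 - params$at_enrichment) / 2)
  base_probs <- c(A = pr_at[1L], C = pr_at[2L], G = pr_at[2L], T = pr_at[1L])
  for (ch in chroms) {
    sp <- sort(all_sites$pos[all_sites$chrom == ch])
    if (length(sp) == 0L) next
    idx <- unique(as.vector(outer(sp, seq(-params$at_flank_bp,
                                          params$at_flank_bp), "+")))
    idx <- idx[idx >= 1L & idx <= params$chrom_lengths[[ch]]]
    genome_chars[[ch]][idx] <- sample(names(base_probs), length(idx),
                                      replace = TRUE, prob = base_probs)
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            "", collapse = ""))
  names(genome) <- chroms

  # --- caller call sets -----------------------------------------------------
  call_paths <- list()
  for (pid in patients) {
    p_ins <- ins[ins$patient_id == pid, , drop = FALSE]
    p_poly <- poly_truth[carried[, pid], , drop = FALSE]
    truth_by_tissue <- list(
      tumor = rbind(p_ins[p_ins$true_class %in% c("germline", "tumor_somatic"), ],
                    p_poly),
      normal = rbind(p_ins[p_ins$true_class %in% c("germline", "normal_somatic"), ],
                     p_poly)
    )
    for (tissue in c("tumor", "normal")) {
      for (caller in c("primary_caller", "secondary_caller")) {
        calls <- emit_caller_calls(truth_by_tissue[[tissue]], caller, params,
                                   pid, tissue)
        f <- file.path(out_dir, "calls",
                       sprintf("%s.%s.%s.vcf", pid, tissue,
                               sub("_caller$", "", caller)))
        write_mei_vcf(calls, f)
        call_paths[[sprintf("%s.%s.%s", pid, tissue, caller)]] <- f
      }
    }
  }

  # --- methylation ----------------------------------------------------------
  fl_line1 <- select_full_length_line1(repeats)
  alu <- repeats[repeats$family == "ALU", , drop = FALSE]
  win_l1 <- te_tss_windows(fl_line1, 500L, params$chrom_lengths)
  win_alu <- te_tss_windows(alu, 500L, params$chrom_lengths)
  te_windows <- rbind(win_l1, win_alu)
  probe_rows <- list()
  for (w in seq_len(nrow(te_windows))) {
    pp <- sort(sample(te_windows$start[w]:te_windows$end[w], 2L))
    shift <- if (te_windows$family[w] == "LINE1") {
      age <- age_category(te_windows$subfamily[w], "LINE1")
      if (age == "young") -params$m_shift_young_line1 else 0
    } else {
      -params$m_shift_alu
    }
    probe_rows[[w]] <- data.frame(
      chrom = te_windows$chrom[w], pos = pp,
      region_annotations = "Body", planted_shift = shift,
      te_family = te_windows$family[w], te_subfamily = te_windows$subfamily[w],
      stringsAsFactors = FALSE
    )
  }
  bg_ch <- sample(chroms, params$n_background_probes, replace = TRUE,
                  prob = params$chrom_lengths)
  bg <- data.frame(
    chrom = bg_ch,
    pos = vapply(bg_ch, function(c_) sample(params$chrom_lengths[[c_]], 1L),
                 integer(1)),
    region_annotations = vapply(seq_len(params$n_background_probes),
                                function(i) {
      paste(sample(REGION_PRIORITY, sample(1:3, 1L)), collapse = ";")
    }, ""),
    planted_shift = params$m_shift_background,
    te_family = NA_character_, te_subfamily = NA_character_,
    stringsAsFactors = FALSE
  )
  probes <- rbind(do.call(rbind, probe_rows), bg)
  probes <- data.frame(probe_id = sprintf("cg%07d", seq_len(nrow(probes))),
                       probes, stringsAsFactors = FALSE)
  n_probes <- nrow(probes)
  samples <- c(patients, sprintf("CTRL%02d", seq_len(params$n_control_samples)))
  is_tumor <- samples %in% patients
  mu <- stats::rnorm(n_probes, params$m_baseline_mean, params$m_probe_sd)
  m_mat <- matrix(stats::rnorm(n_probes * length(samples), mean = mu,
                               sd = params$m_noise_sd),
                  nrow = n_probes, ncol = length(samples),
                  dimnames = list(probes$probe_id, samples))
  m_mat[, is_tumor] <- m_mat[, is_tumor] + probes$planted_shift
  beta <- m_to_beta(m_mat)

  # --- expression table -----------------------------------------------------
  expr_feats <- c("LINE1_young", "LINE1_intermediate", "LINE1_old",
                  "ALU_young", "ALU_intermediate", "ALU_old")
  expr <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (f in expr_feats) expr[[f]] <- round(stats::rnorm(length(patients), 5, 1), 4)

  # --- clinical -------------------------------------------------------------
  per_pat <- do.call(rbind, lapply(patients, function(pid) {
    p <- ins[ins$patient_id == pid, ]
    data.frame(
      patient_id = pid,
      n_germline = sum(p$true_class == "germline"),
      n_tumor_somatic = sum(p$true_class == "tumor_somatic"),
      n_normal_somatic = sum(p$true_class == "normal_somatic"),
      n_polymorphic_carried = sum(carried[, pid]),
      stringsAsFactors = FALSE
    )
  }))
  per_pat$burden <- per_pat$n_germline + per_pat$n_tumor_somatic
  clinical <- simulate_clinical(
    data.frame(patient_id = per_pat$patient_id, burden = per_pat$burden),
    params)

  # --- write the bundle -----------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes = file.path(out_dir, "genes.gff3"),
    repeats = file.path(out_dir, "repeats.tsv"),
    cfs = file.path(out_dir, "cfs.bed"),
    catalog = file.path(out_dir, "catalog.bed"),
    beta = file.path(out_dir, "beta.csv"),
    manifest = file.path(out_dir, "probes.csv"),
    expression = file.path(out_dir, "expression.csv"),
    clinical = file.path(out_dir, "clinical.csv"),
    cancer_genes = file.path(out_dir, "cancer_genes.txt"),
    truth_insertions = file.path(out_dir, "truth_insertions.tsv"),
    truth_patients = file.path(out_dir, "truth_patients.tsv"),
    truth_probes = file.path(out_dir, "truth_probes.tsv"),
    params = file.path(out_dir, "params.json"),
    calls_dir = file.path(out_dir, "calls")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  write_gff3(gene_rows, paths$genes)
  write_repeats(repeats, paths$repeats)
  write_intervals(cfs, paths$cfs)
  utils::write.table(catalog, paths$catalog, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  beta_df <- data.frame(probe_id = rownames(beta),
                        round(beta, 6), check.names = FALSE)
  utils::write.csv(beta_df, paths$beta, row.names = FALSE, quote = FALSE)
  utils::write.csv(probes[, c("probe_id", "chrom", "pos",
                              "region_annotations")],
                   paths$manifest, row.names = FALSE, quote = FALSE)
  utils::write.csv(expr, paths$expression, row.names = FALSE, quote = FALSE)
  utils::write.csv(clinical, paths$clinical, row.names = FALSE, quote = FALSE)
  writeLines(sort(sample(genes_df$name, min(30L, nrow(genes_df)))),
             paths$cancer_genes)
  utils::write.table(truth_insertions, paths$truth_insertions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(per_pat, paths$truth_patients, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(probes[, c("probe_id", "planted_shift", "te_family",
                                "te_subfamily")],
                     paths$truth_probes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_echo <- unclass(params)
  p_echo$seed <- as.integer(seed)
  jsonlite::write_json(p_echo, paths$params, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(dir = out_dir, paths = paths, call_paths = call_paths,
                 truth = list(insertions = truth_insertions,
                              patients = per_pat, probes = probes),
                 params = params, genome = genome, patients = patients))
}
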