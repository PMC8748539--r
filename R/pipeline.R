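#' Run the full TE-insertion analysis pipeline
#'
#' Orchestrates every stage over a cohort bundle: per-sample two-caller
#' consensus, polymorphic filtering against the population catalog (with the
#' distance-scan table), per-patient germline/somatic classification,
#' insertional-feature characterization, TE TSS methylation aggregation and
#' group comparison, and the TE-activity/survival association. All report
#' tables are written as TSV together with a manifest of input checksums and
#' the resolved configuration; identical inputs and configuration reproduce
#' byte-identical outputs.
#'
#' @param input Either a bundle directory in the layout written by
#'   [generate_cohort()], or a named list of paths (`genome`, `genes`,
#'   `repeats`, `cfs`, `catalog`, `beta`, `manifest`, `expression`,
#'   `clinical`, `cancer_genes`, `calls_dir`). Missing optional inputs
#'   (methylation, expression, clinical, cancer genes) disable the dependent
#'   stages.
#' @param config A [pipeline_config()].
#' @param out_dir Directory for the report bundle (created).
#' @return Invisibly, a list with the per-stage results (`consensus`,
#'   `scan`, `classified`, `summary`, `features`, `methylation`,
#'   `association`) and the written `tables`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir) {
  paths <- resolve_bundle_paths(input)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tables <- list()

  # --- consensus ------------------------------------------------------------
  cons <- stage("consensus", {
    files <- sort(list.files(paths$calls_dir, pattern = "\\.vcf$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no caller VCFs found in ", paths$calls_dir)
    meta <- do.call(rbind, lapply(basename(files), function(f) {
      p <- strsplit(sub("\\.vcf$", "", f), ".", fixed = TRUE)[[1L]]
      if (length(p) != 3L) stop("unexpected call file name: ", f)
      data.frame(patient_id = p[1L], tissue = p[2L], caller = p[3L],
                 file = f, stringsAsFactors = FALSE)
    }))
    samples <- unique(meta[, c("patient_id", "tissue")])
    out <- list(); counts <- list()
    for (k in seq_len(nrow(samples))) {
      pid <- samples$patient_id[k]; tis <- samples$tissue[k]
      fp <- meta$file[meta$patient_id == pid & meta$tissue == tis &
                        meta$caller == "primary"]
      fs <- meta$file[meta$patient_id == pid & meta$tissue == tis &
                        meta$caller == "secondary"]
      if (length(fp) != 1L || length(fs) != 1L) {
        stop("sample ", pid, ".", tis, " lacks one caller's file")
      }
      prim <- read_mei_calls(file.path(paths$calls_dir, fp), "primary_caller",
                             pid, tis, config$chr_style)
      sec <- read_mei_calls(file.path(paths$calls_dir, fs), "secondary_caller",
                            pid, tis, config$chr_style)
      cr <- match_consensus(prim, sec, config$consensus_window_bp)
      out[[paste(pid, tis, sep = ".")]] <- cr$consensus
      counts[[k]] <- data.frame(
        patient_id = pid, tissue = tis, n_primary = nrow(prim),
        n_secondary = nrow(sec), n_consensus = nrow(cr$consensus),
        n_unmatched_primary = nrow(cr$unmatched_primary),
        n_unmatched_secondary = nrow(cr$unmatched_secondary),
        stringsAsFactors = FALSE)
    }
    list(calls = do.call(rbind, c(out, list(make.row.names = FALSE))),
         counts = do.call(rbind, counts))
  })
  tables$consensus_counts <- cons$counts
  message("consensus: ", nrow(cons$calls), " consensus insertions across ",
          nrow(cons$counts), " samples")

  # --- polymorphic filtering ------------------------------------------------
  catalog <- stage("specificity", read_polymorphic_catalog(paths$catalog,
                                                           config$chr_style))
  scan <- stage("specificity", {
    scan_filter_distances(cons$calls, catalog, seq(0L, 100L, 5L))
  })
  specific <- stage("specificity", {
    filter_polymorphic(cons$calls, catalog, config$polymorphic_distance_bp)
  })
  tables$scan_table <- scan
  message("specificity: ", nrow(specific), " of ", nrow(cons$calls),
          " consensus insertions are patient-specific at d = ",
          config$polymorphic_distance_bp)

  # --- germline/somatic classification -------------------------------------
  classified <- stage("classification", {
    do.call(rbind, c(lapply(sort(unique(specific$patient_id)), function(pid) {
      classify_patient(
        specific[specific$patient_id == pid & specific$tissue == "tumor", ],
        specific[specific$patient_id == pid & specific$tissue == "normal", ],
        config$somatic_window_bp)
    }), list(make.row.names = FALSE)))
  })
  summary <- summarize_classification(classified)
  tables$classification_per_patient <- summary$per_patient
  tables$classification_totals <- data.frame(
    metric = names(summary$totals),
    value = unlist(summary$totals, use.names = FALSE))
  message("classification: ", summary$totals$germline, " germline / ",
          summary$totals$tumor_somatic, " tumor-somatic / ",
          summary$totals$normal_somatic, " normal-somatic")

  # --- insertional features -------------------------------------------------
  genes <- stage("features", read_gene_models(paths$genes, config$chr_style))
  features <- stage("features", {
    tsd <- tsd_length_histogram(classified)
    flank <- flanking_composition(paths$genome, classified, config$flank_bp)
    ctx <- assign_genomic_context(classified, genes)
    ctx_sum <- context_summary(ctx, by_family = TRUE)
    strata <- gene_length_strata(genes, ctx)
    cfs <- read_intervals(paths$cfs, config$chr_style)
    cfs_sum <- cfs_overlap_summary(classified, cfs)
    recur <- recurrent_gene_report(classified, genes,
                                   config$recurrence_min_patients)
    cancer <- if (!is.null(paths$cancer_genes)) {
      gene_list_intersection(recurrent_gene_report(classified, genes, 1L),
                             paths$cancer_genes)
    }
    prox <- exon_proximity(ctx, genes, 100L)
    list(tsd = tsd, flank = flank, context = ctx, context_summary = ctx_sum,
         strata = strata, cfs_summary = cfs_sum, recurrent = recur,
         cancer_intersection = cancer, exon_proximity = prox)
  })
  tables$tsd_histogram <- features$tsd$histogram
  tables$flanking_composition <- features$flank
  tables$context_summary <- features$context_summary
  tables$gene_length_strata <- data.frame(
    metric = c("median_inserted", "median_noninserted", "n_inserted",
               "n_genes", "pct_inserted"),
    value = c(features$strata$median_inserted,
              features$strata$median_noninserted, features$strata$n_inserted,
              features$strata$n_genes, features$strata$pct_inserted))
  tables$cfs_summary <- data.frame(
    metric = names(features$cfs_summary),
    value = unlist(features$cfs_summary, use.names = FALSE))
  tables$recurrent_genes <- features$recurrent
  if (!is.null(features$cancer_intersection)) {
    tables$cancer_gene_intersection <- features$cancer_intersection
  }
  tables$exon_proximity <- features$exon_proximity
  message("features: TSD mode ", features$tsd$mode, "; ",
          nrow(features$recurrent), " recurrently affected genes")

  # --- methylation ----------------------------------------------------------
  methylation <- NULL
  if (!is.null(paths$beta) && !is.null(paths$manifest) &&
      !is.null(paths$repeats)) {
    methylation <- stage("methylation", {
      bm <- read_beta_and_manifest(paths$beta, paths$manifest,
                                   config$chr_style)
      repeats <- read_repeats(paths$repeats, config$chr_style)
      fl <- select_full_length_line1(repeats, config$full_length_line1_min_bp)
      win_l1 <- te_tss_windows(fl, config$tss_flank_bp)
      win_alu <- te_tss_windows(repeats[repeats$family == "ALU", ],
                                config$tss_flank_bp)
      assign <- map_probes_to_windows(bm$manifest, win_alu, win_l1)
      m_mat <- beta_to_m(bm$beta)
      sub_means <- subfamily_sample_means(assign, m_mat)
      age_means <- age_category_means(sub_means)
      tumor_samples <- intersect(colnames(m_mat),
                                 unique(classified$patient_id))
      control_samples <- setdiff(colnames(m_mat), tumor_samples)
      tests <- if (length(tumor_samples) && length(control_samples) &&
                   nrow(age_means)) {
        do.call(rbind, lapply(rownames(age_means), function(cat) {
          a <- age_means[cat, tumor_samples]; b <- age_means[cat, control_samples]
          w <- group_compare_wilcoxon(a, b)
          data.frame(category = cat, n_tumor = length(a),
                     n_control = length(b), mean_tumor = mean(a),
                     mean_control = mean(b), statistic = w$statistic,
                     p_value = w$p_value, stringsAsFactors = FALSE)
        }))
      }
      region <- region_methylation_summary(
        bm$manifest, m_mat,
        list(tumor = tumor_samples, control = control_samples))
      list(assignment = assign, subfamily_means = sub_means,
           age_means = age_means, group_tests = tests, region = region,
           tumor_samples = tumor_samples, control_samples = control_samples)
    })
    tables$probe_mapping <- as.data.frame(
      table(status = methylation$assignment$status,
            reason = addNA(methylation$assignment$reason)))
    am <- methylation$age_means
    tables$methylation_age_means <- data.frame(category = rownames(am),
                                               am, check.names = FALSE)
    if (!is.null(methylation$group_tests)) {
      tables$methylation_group_tests <- methylation$group_tests
    }
    tables$region_methylation <- methylation$region
    message("methylation: ",
            sum(methylation$assignment$status == "assigned"),
            " probes assigned, ",
            sum(methylation$assignment$status == "excluded"), " excluded")
  }

  # --- association / survival ----------------------------------------------
  association <- NULL
  if (!is.null(paths$clinical)) {
    association <- stage("association", {
      clinical <- read_clinical(paths$clinical)
      tumor_specific <- classified[
        classified$patient_class %in% c("germline", "tumor_somatic"), ]
      burdens <- data.frame(
        patient_id = sort(unique(specific$patient_id)),
        stringsAsFactors = FALSE)
      burdens$burden <- vapply(burdens$patient_id, function(p) {
        sum(tumor_specific$patient_id == p)
      }, integer(1))
      expression <- if (!is.null(paths$expression)) {
        utils::read.csv(paths$expression, stringsAsFactors = FALSE)
      }
      meth_means <- if (!is.null(methylation) &&
                        nrow(methylation$age_means) > 0L) {
        methylation$age_means[, methylation$tumor_samples, drop = FALSE]
      }
      fm <- build_feature_matrix(expression, meth_means, burdens, clinical)
      dummies <- grep("^(disease_status_dx|primary_site)_", names(fm),
                      value = TRUE)
      fm_std <- suppressWarnings(standardize_features(fm, skip = dummies))
      te_cols <- grep("^(expr_|meth_|insertion_burden)", names(fm_std),
                      value = TRUE)
      sp <- if (length(te_cols) >= 2L && nrow(fm_std) >= 3L) {
        spearman_matrix(fm_std[, te_cols, drop = FALSE], config$alpha)
      }
      cox <- fit_cox_efs(fm_std, clinical)
      km <- km_logrank_by_burden(clinical, burdens, config$burden_threshold)
      list(burdens = burdens, features = fm_std, spearman = sp, cox = cox,
           km = km)
    })
    tables$burdens <- association$burdens
    if (!is.null(association$spearman)) {
      tables$spearman_rho <- data.frame(
        feature = rownames(association$spearman$rho),
        association$spearman$rho, check.names = FALSE)
    }
    tables$cox_table <- association$cox$table
    tables$cox_lrt <- data.frame(
      metric = c("statistic", "df", "p", "n", "n_events"),
      value = c(association$cox$lrt$statistic, association$cox$lrt$df,
                association$cox$lrt$p, association$cox$n,
                association$cox$n_events))
    tables$km_curves <- association$km$curves
    tables$logrank <- data.frame(
      metric = c("chisq", "df", "p", "n_high", "n_low"),
      value = c(association$km$chisq, association$km$df, association$km$p,
                association$km$n_high, association$km$n_low))
    message("association: Cox LRT = ",
            format(association$cox$lrt$statistic, digits = 4),
            " on ", association$cox$lrt$df, " df; log-rank p = ",
            format(association$km$p, digits = 3))
  }

  # --- manifest + reports ---------------------------------------------------
  input_files <- unlist(paths[!vapply(paths, is.null, TRUE)])
  input_files <- input_files[!vapply(input_files, dir.exists, TRUE)]
  call_files <- sort(list.files(paths$calls_dir, pattern = "\\.vcf$",
                                full.names = TRUE))
  sums <- tools::md5sum(c(unname(input_files), call_files))
  tables$run_manifest <- rbind(
    data.frame(key = paste0("config.", names(unclass(config))),
               value = vapply(unclass(config), as.character, ""),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("md5.", basename(names(sums))),
               value = unname(sums), stringsAsFactors = FALSE))
  write_report(tables, out_dir)

  invisible(list(consensus = cons, scan = scan, specific = specific,
                 classified = classified, summary = summary,
                 features = features, methylation = methylation,
                 association = association, tables = tables,
                 genes = genes, out_dir = out_dir))
}

# Resolve a bundle directory (generate_cohort layout) or a user-supplied
# named list of paths into the canonical path list; required entries must
# exist, optional ones may be NULL.
resolve_bundle_paths <- function(input) {
  if (is.character(input) && length(input) == 1L) {
    if (!dir.exists(input)) stop("bundle directory not found: ", input,
                                 call. = FALSE)
    cand <- list(
      genome = "genome.fa", genes = "genes.gff3", repeats = "repeats.tsv",
      cfs = "cfs.bed", catalog = "catalog.bed", beta = "beta.csv",
      manifest = "probes.csv", expression = "expression.csv",
      clinical = "clinical.csv", cancer_genes = "cancer_genes.txt",
      calls_dir = "calls")
    paths <- lapply(cand, function(f) {
      p <- file.path(input, f)
      if (file.exists(p)) p else NULL
    })
  } else {
    paths <- as.list(input)
  }
  for (req in c("genome", "genes", "cfs", "catalog", "calls_dir")) {
    if (is.null(paths[[req]])) {
      stop("pipeline input is missing required element '", req, "'",
           call. = FALSE)
    }
    if (!file.exists(paths[[req]])) {
      stop("pipeline input '", req, "' not found: ", paths[[req]],
           call. = FALSE)
    }
  }
  paths
}
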