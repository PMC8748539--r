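#' Pipeline configuration
#'
#' Collects the tunable constants used across the pipeline stages. The defaults
#' are the working values of the analysis: a 100 bp window for calling two
#' caller records the same insertion, a 20 bp distance for discarding
#' catalogued polymorphic insertions, a 100 bp tumor/normal pairing window,
#' +/- 50 bp flanks for base-composition profiles, +/- 500 bp TE TSS windows
#' for methylation probes, recurrence at >= 3 patients, and a burden threshold
#' of 100 insertions for survival stratification.
#'
#' @param consensus_window_bp Maximum distance (bp) between the two callers'
#'   positions for a consensus pair.
#' @param polymorphic_distance_bp Distance (bp) to a same-family catalog entry
#'   at or below which a call is considered polymorphic.
#' @param somatic_window_bp Tumor/normal pairing window (bp) for germline
#'   classification.
#' @param flank_bp Half-width (bp) of the flanking base-composition profile.
#' @param tss_flank_bp Half-width (bp) of the TE TSS window used for probe
#'   mapping.
#' @param recurrence_min_patients Minimum number of distinct patients for a
#'   gene to count as recurrently affected.
#' @param burden_threshold Insertion-burden cut for the high/low survival
#'   groups (burden > threshold is "high").
#' @param full_length_line1_min_bp Minimum element length (bp) for a LINE-1 to
#'   count as full length.
#' @param alpha Significance level for reported tests.
#' @param rng_seed Integer seed used by simulation entry points.
#' @param chr_style Chromosome-name handling: `"exact"` (no normalization),
#'   `"strip"` (remove a leading "chr"), or `"add"` (prepend "chr" when
#'   absent). Applied by readers before any matching.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(consensus_window_bp = 100L,
                            polymorphic_distance_bp = 20L,
                            somatic_window_bp = 100L,
                            flank_bp = 50L,
                            tss_flank_bp = 500L,
                            recurrence_min_patients = 3L,
                            burden_threshold = 100L,
                            full_length_line1_min_bp = 5900L,
                            alpha = 0.05,
                            rng_seed = 1L,
                            chr_style = c("exact", "strip", "add")) {
  chr_style <- match.arg(chr_style)
  cfg <- list(
    consensus_window_bp = as.integer(consensus_window_bp),
    polymorphic_distance_bp = as.integer(polymorphic_distance_bp),
    somatic_window_bp = as.integer(somatic_window_bp),
    flank_bp = as.integer(flank_bp),
    tss_flank_bp = as.integer(tss_flank_bp),
    recurrence_min_patients = as.integer(recurrence_min_patients),
    burden_threshold = as.integer(burden_threshold),
    full_length_line1_min_bp = as.integer(full_length_line1_min_bp),
    alpha = as.numeric(alpha),
    rng_seed = as.integer(rng_seed),
    chr_style = chr_style
  )
  positive <- c("consensus_window_bp", "polymorphic_distance_bp",
                "somatic_window_bp", "flank_bp", "tss_flank_bp",
                "recurrence_min_patients", "burden_threshold",
                "full_length_line1_min_bp")
  for (nm in positive) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop("pipeline_config: '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  # polymorphic_distance_bp = 0 is a legal degenerate scan point but the
  # config default is the positive working threshold; allow 0 explicitly.
  if (as.integer(polymorphic_distance_bp) < 0L) {
    stop("pipeline_config: 'polymorphic_distance_bp' must be >= 0", call. = FALSE)
  }
  cfg$polymorphic_distance_bp <- as.integer(polymorphic_distance_bp)
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("pipeline_config: 'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("teinsight pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, x[[nm]]))
  invisible(x)
}

# Accepted TE family vocabulary: the four retrotransposon groups currently
# active in the human genome.
TE_FAMILIES <- c("LINE1", "ALU", "SVA", "HERVK")

#' Normalize chromosome names per the configured style
#' @param chrom Character vector of chromosome names.
#' @param style One of "exact", "strip", "add".
#' @return Character vector.
#' @keywords internal
normalize_chrom <- function(chrom, style = "exact") {
  switch(style,
    exact = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    stop("unknown chromosome style: ", style)
  )
}

#' Infer TE family from a repeat subfamily name
#'
#' Prefix rules: names starting with "L1" are LINE-1; "Alu", "FLAM" or "FRAM"
#' are Alu; everything else is "other".
#' @param subfamily Character vector of RepeatMasker-style subfamily names.
#' @return Character vector over `{"LINE1", "ALU", "other"}`.
#' @export
repeat_family <- function(subfamily) {
  fam <- rep("other", length(subfamily))
  fam[grepl("^L1", subfamily)] <- "LINE1"
  fam[grepl("^(Alu|FLAM|FRAM)", subfamily)] <- "ALU"
  fam
}

# Round half-up to `digits` decimals (printed-percentage convention; base R
# round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
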