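---
title: "Methods: TE-insertion landscapes, methylation, and survival with teinsight"
author: "teinsight authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-insertion landscapes, methylation, and survival with teinsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teinsight)
```

# Scope and model

teinsight implements the post-calling half of a tumor/normal
mobile-element-insertion (MEI) study. The upstream steps — read alignment and
the insertion callers themselves — are out of scope; the package starts from
two callers' per-sample call sets and carries them through six stages:

1. **Consensus.** Two callers' records represent the same insertion when they
   lie on the same chromosome, report the same TE family (LINE-1, Alu, SVA,
   or HERV-K), and are within `consensus_window_bp = 100` bp of each other
   (inclusive). The precise caller's coordinate becomes the final site, since
   the imprecise caller only reports a position plus a confidence interval.
2. **Polymorphic filtering.** Insertions segregating in the general
   population are not informative about the disease; any call with a
   same-family catalog entry within `polymorphic_distance_bp = 20` bp is
   removed. HERV-K is never filtered because population catalogs of
   LINE-1-mediated insertions do not report it.
3. **Germline/somatic classification.** Within each patient, tumor and
   normal calls pair one-to-one within `somatic_window_bp = 100` bp; paired
   calls are germline (reported once, at the tumor coordinate), unmatched
   tumor calls are tumor-specific somatic, unmatched normal calls are
   normal-specific somatic.
4. **Insertional features.** TSD length histograms, per-position base
   composition in ±50 bp flanks, genomic context against representative
   transcripts, gene-length stratification, common-fragile-site overlap,
   cross-patient recurrence, gene-list intersection, and exon proximity.
5. **TE methylation.** 450K-style beta values are transformed to M-values
   (`M = log2(beta / (1 - beta))`), probes are mapped into ±500 bp windows
   around the most-5' ends of Alu and full-length LINE-1 elements, averaged
   per subfamily per sample, then per evolutionary-age category, and compared
   between tumor and control groups with the unpaired two-sample Wilcoxon
   rank-sum test.
6. **Survival association.** Standardized TE-activity features (expression
   and methylation by age category, insertion burden) plus clinical
   covariates enter a Cox proportional-hazards model of event-free survival;
   the cohort is additionally stratified at a burden of 100 insertions and
   compared with Kaplan–Meier curves and the log-rank test.

# Matching semantics

Neither the consensus nor the classification step has a canonical matching
rule in the literature, so the package fixes one and validates it: candidate
pairs are ranked by distance ascending (ties broken by the smaller first-set
position, then the smaller second-set position) and accepted greedily,
consuming each call once. This is deterministic, order-independent, and —
verified against an exhaustive minimum-total-distance bipartite matcher in
the test suite — identical to the optimal matching whenever call sites are
separated by more than the window, which is the regime both real data (calls
hundreds of bp apart) and the simulator (200 bp minimum separation) occupy.
The "within 100 bp" windows are inclusive (`<=`); the boundary is covered by
tests at 100 and 101 bp.

The polymorphic filter is deliberately **not** one-to-one: one catalog entry
absorbs every call within the distance, because the step is filtering against
a reference set, not pairing. The distance-threshold scan
(`scan_filter_distances()`, default grid 0–100 by 5) is emitted for
inspection, but the working threshold is a configuration value: the original
choice of 20 bp was made by eye from diminishing returns, and automating an
elbow criterion would invent a method the analysis never used.

# Coordinate and naming conventions

Intervals are held in the 1-based closed convention of
GenomicRanges/IRanges; VCF (1-based), GFF3 (1-based closed) and BED (0-based
half-open) are converted at the readers/writers, which round-trip exactly.
Chromosome names are matched as exact strings, with an explicit configuration
switch (`chr_style`) to strip or add a `chr` prefix — silent normalization
has caused too many real-world mismatches. TE families are the closed
vocabulary {LINE1, ALU, SVA, HERVK}; subfamily strings are free-form, with
families inferred from RepeatMasker-style prefixes (`L1*` → LINE1,
`Alu*`/`FLAM*`/`FRAM*` → ALU).

# Feature definitions

* **Representative transcript**: the transcript of maximal genomic span per
  gene (ties → lexicographically smallest transcript id). All gene-level
  features (context, gene length, recurrence, exon proximity) use it.
* **Context precedence**: within a gene, CDS > 5'UTR > 3'UTR > intron;
  across overlapped genes the highest-precedence label wins and the
  insertion is flagged as "overlapping" when ≥ 2 distinct genes are hit.
  Exonic positions of transcripts without an annotated CDS fall through to
  intron, since the vocabulary has no non-coding-exon class.
* **Flanking composition** uses the reference strand without orientation
  flipping (insertion strands are not resolved upstream); N bases are
  excluded per position from the denominator, and sites truncated by contig
  edges are excluded and counted.
* **Percentages** are rounded half-up to two decimals, matching the style of
  printed count ledgers; base R's half-even `round()` is not used for
  reported percentages.
* **Recurrence** collapses per-patient multiplicity: a patient counts once
  per gene regardless of how many insertions hit it.

# Methylation choices

* Beta values exactly 0 or 1 are clamped to `[1e-6, 1 - 1e-6]` before the M
  transform, which is undefined at the endpoints.
* "Full-length" LINE-1 defaults to ≥ 5900 bp — an intact element is about
  6 kb and only near-full-length copies retain the internal promoter the TSS
  window is meant to capture. The cutoff is configurable because no single
  published criterion exists.
* A probe is located by its single manifest CpG coordinate, not the 50 bp
  probe extent: manifests provide one coordinate.
* Ambiguity exclusions: probes inside windows of ≥ 2 subfamilies of one
  family are dropped (`multi_subfamily`), as are probes inside both a LINE-1
  and an Alu window (`cross_family`). The multi-subfamily rule is applied to
  both families symmetrically.
* Age aggregation is a two-step unweighted mean — probes → subfamily means →
  category means — so large subfamilies do not dominate a category. Age
  categories follow the standard nomenclature: L1HS/L1PA young, other L1P
  intermediate, L1M old; AluY young, AluS intermediate, other Alu (AluJ,
  FLAM/FRAM) old.
* Probes annotated to several gene regions collapse to one by the priority
  TSS1500 > TSS200 > 5'UTR > first exon > body > 3'UTR.

# Survival choices

Features are standardized as `(x - mean(x)) / sd(x)` with the `n - 1`
denominator; constant columns are dropped with a warning. Dummy columns for
categorical clinical covariates (reference = most frequent level) are left
unscaled so their coefficients remain level contrasts. Ties use Efron's
method (the default of the survival package this analysis builds on);
collinear covariates that the fitter drops are reported as such rather than
failing the run, while genuinely separated fits (coefficients beyond ±15)
abort with diagnostics. A burden of exactly 100 goes to the low group: the
stratification was defined as "more than 100" vs "less than 100", leaving
the boundary undefined, and the low side is the conservative assignment.
Spearman correlations use exact permutation p-values for small untied
samples (n ≤ 9) and the t-approximation with n − 2 df otherwise.

# The synthetic cohort

`generate_cohort()` emits everything the pipeline consumes — toy genome
(FASTA), gene models (GFF3), repeat annotation, fragile-site intervals,
polymorphic catalog, per-sample two-caller call sets, methylation matrices,
expression and clinical tables — plus a truth ledger sufficient to recompute
every downstream summary. Defaults encode the study conditions:

* 39 patients (the cohort size of the motivating study), paired tumor/normal.
* Per-patient germline counts are negative-binomial (mean 80, dispersion 5) —
  cohorts show strong burden heterogeneity, and the dispersion is exposed
  because no published per-patient distribution exists — with Poisson means
  of 5 tumor-specific and 1 normal-specific somatic insertions, and 60
  cohort-level polymorphic sites carried with probability 0.6.
* Family mix 0.33/0.63/0.035/0.005 (LINE1/ALU/SVA/HERVK), the
  patient-specific composition of the motivating cohort.
* TSD lengths are a discretized normal on 0–30 bp with mode 15 and sd 1.5;
  flanks within ±10 bp of planted sites get +0.15 excess A+T probability
  over the 50% GC background.
* Genic targeting with probability 0.5, gene chosen proportional to
  representative-transcript length (exponent 1), planting the
  long-gene bias.
* The secondary caller jitters positions uniformly on ±30 bp and reports a
  CI of that half-width; per-caller FN rates default to 0.05 and FP rates to
  0.02. Polymorphic sites enter the catalog with independent ±5 bp jitter so
  the 20 bp filter is exercised nontrivially.
* Methylation M-values are per-probe Gaussian with planted tumor-minus-
  control shifts: −0.5 at young LINE-1 TSS probes, −0.25 at Alu TSS probes,
  +0.2 elsewhere (TE hypomethylation against a hypermethylated background).
* Event times are exponential with hazard `h0 · exp(β · z(burden))`,
  `h0 = 0.001`/day and `β = −0.7` (high burden protective, the direction the
  motivating analysis reported), with independent exponential censoring
  calibrated to ≈ 20%.

Planted sites keep a 200 bp minimum separation within a patient and from
polymorphic sites, so that in the noiseless limit (no FN/FP, jitter within
windows) the pipeline recovers every planted label exactly — the
truth-recovery tests rely on this. A single RNG stream with a fixed
generation order makes the bundle byte-identical for a given
(parameters, seed).

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: read-level evidence (no FASTQ/BAM), realistic
repeat landscapes and segmental duplication, caller biases that correlate
between callers or with sequence context, probe cross-hybridization, and
correlated expression/methylation structure (the expression table is
independent noise). With the default caller noise, FN-induced
misclassification inflates the somatic classes relative to the planted
rates — a germline insertion missed in one tissue's consensus set
masquerades as somatic. The motivating study suppressed this with manual
IGV review of every candidate, a step that is explicitly out of scope here,
so the noisy-cohort somatic counts should be read as caller-limited upper
bounds while the noiseless cohort demonstrates algorithmic correctness.

# Problem sizes and runtime

The test suite runs on cohorts of 3–20 patients over a 3 Mb two-chromosome
toy genome (about 1,500–2,000 planted insertions, 360 TE TSS probes), 200
random 25-call consensus instances against the exhaustive matcher, 100
random 30×30 filter instances against the brute-force scan, 100-seed power
and type-I simulations for the methylation and survival tests, and n = 200
cohorts for Cox parameter recovery; the whole suite completes in about a
minute on one core. These sizes were chosen so every distributional claim is
backed by a 3-standard-deviation Monte-Carlo band while remaining quick to
iterate on.

# Known limitations

* Greedy matching is only proven optimal in the well-separated regime; at
  densities where many calls share a window it can differ from the
  minimum-distance matching (the tests cover both regimes, asserting
  invariants rather than optimality in the dense case).
* Genomic context uses representative transcripts only; isoform-specific
  UTR/CDS differences are invisible.
* The Cox stage fits whatever feature matrix it is given; with small cohorts
  and many covariates the fit can be degenerate, which the package reports
  as an error rather than silently regularizing.
* Expression quantification is out of scope: expression features are
  accepted as a precomputed per-patient table.
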