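# teinsight

Post-calling analysis of transposable-element (TE) insertions in paired
tumor/normal cohorts. Somatic and germline mobile-element insertions (MEIs)
are increasingly recognized as both a source of genomic instability in
cancer and a potential prognostic signal; this package is for genomicists
who already have per-sample MEI call sets from two callers (a precise caller
reporting exact sites and target-site duplications, and an imprecise caller
reporting sites with confidence intervals) and want a tested, reproducible
route from those calls to a cohort-level characterization and a survival
association.

## What it computes

For calls from callers *A* (precise) and *B* (imprecise) on one sample, a
**consensus insertion** is a one-to-one pairing with

    same chromosome,  same TE family,  |pos_A - pos_B| <= W   (W = 100 bp)

with the precise caller's coordinate as the final site. Consensus calls
within distance *d* = 20 bp of a same-family entry of a population catalog
are discarded as **polymorphic** (HERV-K is exempt; catalogs of
LINE-1-mediated insertions do not report it), and a scan of *d* from 0 to
100 bp is emitted alongside. Within each patient, tumor and normal calls
pair one-to-one within 100 bp: paired calls are **germline**, unmatched
tumor calls **tumor-specific somatic**, unmatched normal calls
**normal-specific somatic**.

Downstream, the package characterizes the insertion set (TSD length
histogram, ±50 bp flanking base composition, genomic context against
representative transcripts, gene-length stratification, common-fragile-site
overlap, ≥3-patient recurrence, gene-list intersection, exon proximity),
maps 450K-style methylation probes into ±500 bp windows around the most-5'
ends of Alu and full-length LINE-1 (with M = log2(β/(1−β)), subfamily and
evolutionary-age aggregation, and Wilcoxon tumor/control comparisons), and
fits the survival association: standardized TE-activity features in a Cox
proportional-hazards model of event-free survival, plus Kaplan–Meier
curves and a log-rank test for patients above vs below a burden of 100
insertions.

A first-class synthetic-cohort generator (`generate_cohort()`) plants
ground truth for every one of these signals — germline/somatic/polymorphic
status, TSD mode 15 bp, AT-rich flanks, long-gene targeting, young-LINE-1
TSS hypomethylation, a protective burden effect on survival — so the whole
pipeline is testable end to end without access-controlled patient data.

## Worked example

```r
library(teinsight)

params <- sim_params()                        # 39 patients, defaults
bundle <- generate_cohort(params, seed = 42, out_dir = "demo_bundle")
res    <- run_pipeline("demo_bundle", pipeline_config(),
                       out_dir = "demo_report")
```

The run logs one line per stage:

```
consensus: 8799 consensus insertions across 78 samples
specificity: 6293 of 8799 consensus insertions are patient-specific at d = 20
classification: 2743 germline / 479 tumor-somatic / 328 normal-somatic
features: TSD mode 15; 205 recurrently affected genes
methylation: 355 probes assigned, 0 excluded
association: Cox LRT = 36.64 on 17 df; log-rank p = 0.01
```

and the result object carries every table the report directory receives:

```r
print(res$summary)
#> classification_summary: 3550 insertions across 39 patients
#>   germline: 2743  tumor_somatic: 479  normal_somatic: 328

res$methylation$group_tests[, c("category", "mean_tumor", "mean_control", "p_value")]
#>             category mean_tumor mean_control  p_value
#> 1   ALU_intermediate       1.68         1.93 0.000174
#> ...
#> 6        LINE1_young       1.34         1.95 0.000174

ct <- res$association$cox$table
ct[ct$feature == "insertion_burden", ]
#>             feature coef    hr    se     z        p
#> 13 insertion_burden -1.4 0.246 0.388 -3.62 0.000295
```

Reading the output: the TSD mode of 15 bp and the AT-enriched flanks confirm
LINE-1-machinery insertions; the young-LINE-1 methylation category is about
0.6 M-units lower in tumors than controls (the planted hypomethylation);
and the insertion-burden hazard ratio below 1 with log-rank p = 0.01 says
high-burden patients had longer event-free survival — the planted protective
effect. Under the default caller noise the somatic classes are inflated
relative to the planted rates (a germline call missed in one tissue
masquerades as somatic); the noiseless generator setting recovers every
planted label exactly, which is what the truth-recovery tests assert.

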