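test_that("TSD histogram counts lengths and finds the mode", {
  calls <- make_calls("chr1", c(10L, 20L, 30L), "ALU",
                      tsd = c("AAGAAAGTAAAGGA", NA, "ACGTA"))
  h <- tsd_length_histogram(calls)
  expect_identical(h$histogram$length, c(5L, 14L))
  expect_identical(h$histogram$count, c(1L, 1L))
  expect_identical(h$mode, 5L)  # tie -> smallest length
  expect_identical(h$n_with_tsd, 2L)
  expect_identical(h$n_without_tsd, 1L)

  none <- tsd_length_histogram(make_calls("chr1", 1L, "ALU"))
  expect_identical(nrow(none$histogram), 0L)
  expect_true(is.na(none$mode))
})

test_that("flanking composition is a normalized per-position profile", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste(rep("A", 200), collapse = ""),
    chrR = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")))
  calls <- make_calls("chrA", 100L, "ALU")
  fc <- flanking_composition(genome, calls, 50L)
  expect_identical(fc$position, seq(-50L, 50L))
  expect_true(all(fc$A == 1))
  expect_true(all(abs(fc$A + fc$C + fc$G + fc$T - 1) < 1e-12))

  set.seed(3)
  calls2 <- make_calls("chrR", sample(60:340, 10), "ALU")
  fc2 <- flanking_composition(genome, calls2, 50L)
  expect_true(all(abs(fc2$A + fc2$C + fc2$G + fc2$T - 1) < 1e-12))

  # edge truncation excludes the site and counts it
  fc3 <- flanking_composition(genome, make_calls("chrA", c(10L, 100L), "ALU"),
                              50L)
  expect_identical(attr(fc3, "n_excluded"), 1L)
  expect_identical(unique(fc3$n_sites), 1L)

  expect_error(flanking_composition(genome, make_calls("chrZ", 5L, "ALU")),
               "chrZ")
})

context_genes <- function() {
  make_gene_set(list(
    list(id = "g1", name = "GENE1", chrom = "chr1", strand = "+",
         transcripts = list(list(
           id = "g1.t1",
           exons = rbind(c(1000, 1199), c(2000, 2199), c(3000, 3199)),
           cds = rbind(c(1100, 1199), c(2000, 2199), c(3000, 3099))))),
    list(id = "g2", name = "GENE2", chrom = "chr1", strand = "-",
         transcripts = list(list(
           id = "g2.t1",
           exons = rbind(c(3150, 3349), c(4000, 4199)),
           cds = rbind(c(3250, 3349), c(4000, 4099))))),
    list(id = "g3", name = "GENE3", chrom = "chr2", strand = "+",
         transcripts = list(list(id = "g3.t1",
                                 exons = rbind(c(500, 2499)))))
  ))
}

test_that("genomic context labels follow the precedence rules", {
  gs <- context_genes()
  calls <- make_calls(
    c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    c(1500L,   1050L,  2100L,  3120L,  9000L,  3180L,  1000L),
    "ALU")
  ctx <- assign_genomic_context(calls, gs)
  expect_identical(ctx$label[1], "intron")      # between exon 1 and 2 of g1
  expect_identical(ctx$label[2], "UTR5")        # exonic, upstream of g1 CDS
  expect_identical(ctx$label[3], "CDS")
  expect_identical(ctx$label[4], "UTR3")        # exonic after CDS end on '+'
  expect_identical(ctx$label[5], "intergenic")
  expect_identical(ctx$gene_ids[5], NA_character_)
  # overlap of g1 (UTR3 region) and g2 spans
  expect_true(ctx$overlapping_flag[6])
  expect_identical(ctx$gene_ids[6], "g1,g2")
  # non-coding transcript: inside span -> intron
  expect_identical(ctx$label[7], "intron")
  expect_false(any(ctx$overlapping_flag[c(1:5, 7)]))
})

test_that("context summary percentages are half-up to two decimals", {
  labels <- data.frame(
    label = c(rep("intron", 3), rep("intergenic", 2), "CDS"),
    te_family = c("ALU", "ALU", "LINE1", "SVA", "ALU", "LINE1"),
    overlapping_flag = FALSE)
  cs <- context_summary(labels, by_family = TRUE)
  expect_identical(sum(cs$count), 6L)
  expect_identical(cs$pct[cs$label == "intron"], 50.00)
  expect_identical(cs$pct[cs$label == "intergenic"], 33.33)
  expect_lt(abs(sum(cs$pct) - 100), 0.05)
  expect_identical(cs$ALU[cs$label == "intron"], 2L)

  one <- context_summary(data.frame(label = "intron",
                                    overlapping_flag = FALSE))
  expect_identical(one$pct[one$label == "intron"], 100.00)
})

test_that("gene-length strata split inserted vs non-inserted genes", {
  gs <- context_genes()
  ctx <- assign_genomic_context(make_calls("chr1", 1500L, "ALU"), gs)
  st <- gene_length_strata(gs, ctx)
  expect_identical(st$n_inserted, 1L)
  expect_identical(st$n_genes, 3L)
  expect_equal(st$median_inserted, 2200)
  expect_identical(st$pct_inserted, 33.33)

  # all genes inserted -> empty non-inserted stratum
  ctx_all <- assign_genomic_context(
    make_calls(c("chr1", "chr1", "chr2"), c(1500L, 4100L, 1000L), "ALU"), gs)
  st_all <- gene_length_strata(gs, ctx_all)
  expect_identical(length(st_all$noninserted_lengths), 0L)
  expect_true(is.na(st_all$median_noninserted))
})

test_that("CFS overlap counts insertions and hit intervals", {
  cfs <- data.frame(chrom = "chr1", start = c(1L, 1001L, 2001L),
                    end = c(500L, 1500L, 2500L),
                    name = c("f1", "f2", "f3"))
  calls <- make_calls("chr1", c(100L, 120L, 1200L, 5000L), "ALU")
  s <- cfs_overlap_summary(calls, cfs)
  expect_identical(s$n_in_cfs, 3L)
  expect_identical(s$frac_in_cfs, 75.00)
  expect_identical(s$n_cfs_hit, 2L)
  expect_identical(s$frac_cfs_hit, 66.67)

  empty <- cfs_overlap_summary(calls, cfs[0, ])
  expect_identical(empty$n_in_cfs, 0L)
  expect_true(is.na(empty$frac_in_cfs))
})

test_that("recurrence collapses per-patient multiplicity", {
  gs <- context_genes()
  rows <- rbind(
    make_calls("chr1", rep(1500L, 5L), "ALU", patient_id = "P1"),  # 5 in g1
    make_calls("chr1", 1510L, "ALU", patient_id = "P2"),
    make_calls("chr1", 1520L, "ALU", patient_id = "P3"),
    make_calls("chr1", 4100L, "ALU", patient_id = "P1"),           # g2: 2 pats
    make_calls("chr1", 4100L, "ALU", patient_id = "P2"))
  rows$patient_class <- "germline"
  rep3 <- recurrent_gene_report(rows, gs, 3L)
  expect_identical(rep3$gene_id, "g1")
  expect_identical(rep3$n_patients, 3L)
  rep1 <- recurrent_gene_report(rows, gs, 1L)
  expect_identical(rep1$n_patients[rep1$gene_id == "g2"], 2L)
  expect_identical(rep1$n_insertions[rep1$gene_id == "g1"], 7L)
})

test_that("gene-list intersection matches symbols case-insensitively", {
  affected <- data.frame(gene_id = c("g1", "g2"), name = c("Gene1", "GENE2"),
                         n_patients = c(3L, 2L), stringsAsFactors = FALSE)
  expect_identical(nrow(gene_list_intersection(affected, character(0))), 0L)
  hit <- gene_list_intersection(affected, c("gene2", "OTHER"))
  expect_identical(hit$gene_id, "g2")
  expect_identical(hit$list_symbol, "gene2")
})

test_that("exon proximity uses an inclusive distance to the nearest boundary", {
  gs <- make_gene_set(list(
    list(id = "g1", chrom = "chr1", strand = "+",
         transcripts = list(list(id = "g1.t1",
                                 exons = rbind(c(1000, 1199), c(2000, 2199)))))
  ))
  # exon 1 ends at 1199: distances 1, 100, 101 into the intron
  calls <- make_calls("chr1", c(1200L, 1299L, 1300L, 1301L), "ALU")
  ctx <- assign_genomic_context(calls, gs)
  expect_identical(unique(ctx$label), "intron")
  near <- exon_proximity(ctx, gs, 100L)
  expect_identical(sort(near$exon_distance), c(1L, 100L))
  expect_false(1301L %in% near$pos)
  # midpoint distance measured to the nearest of the two boundaries
  mid <- exon_proximity(assign_genomic_context(
    make_calls("chr1", 1600L, "ALU"), gs), gs, 500L)
  expect_identical(mid$exon_distance, 400L)
})
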