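test_that("pipeline_config validates its fields", {
  cfg <- pipeline_config()
  expect_s3_class(cfg, "pipeline_config")
  expect_identical(cfg$consensus_window_bp, 100L)
  expect_identical(cfg$polymorphic_distance_bp, 20L)
  expect_identical(cfg$tss_flank_bp, 500L)
  expect_error(pipeline_config(consensus_window_bp = 0), "strictly positive")
  expect_error(pipeline_config(flank_bp = -5), "strictly positive")
  expect_error(pipeline_config(alpha = 1), "alpha")
  expect_error(pipeline_config(alpha = 0), "alpha")
})

test_that("MEI call records map to TE calls with validation", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tN\t<INS:ME:ALU>\t.\tPASS\tMEITYPE=ALU",
    paste0("chr16\t500\tins1\tN\t<INS:ME:ALU>\t.\tPASS\t",
           "MEITYPE=ALU;SUBFAMILY=AluYb8;TSD=AAGAAAGTAAAGGA"),
    "chr2\t900\t.\tN\t<INS:ME:LINE1>\t.\tPASS\tMEITYPE=LINE1;CILO=870;CIHI=930"
  ), path)
  calls <- read_mei_calls(path, "primary_caller", "P01", "tumor")
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$chrom[1], "chr1")
  expect_identical(calls$pos[1], 100L)
  expect_identical(calls$te_family[1], "ALU")
  expect_identical(nchar(calls$tsd_sequence[2]), 14L)
  expect_identical(calls$subfamily[2], "AluYb8")
  expect_identical(calls$ci_lo[3], 870L)
  expect_identical(calls$ci_hi[3], 930L)
  expect_identical(unique(calls$sample_id), "P01.tumor")
})

test_that("MEI reader rejects bad records with line numbers", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tN\t<INS>\t.\tPASS\tMEITYPE=FOO"
  ), path)
  expect_error(read_mei_calls(path, "primary_caller", "P01", "tumor"),
               "unknown TE family 'FOO' at line 2.*LINE1, ALU, SVA, HERVK")

  writeLines(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tN\t<INS>\t.\tPASS\tMEITYPE=ALU",
    "chr1\tnotanumber\t.\tN\t<INS>\t.\tPASS\tMEITYPE=ALU"
  ), path)
  expect_error(read_mei_calls(path, "primary_caller", "P01", "tumor"),
               "line 3")

  writeLines(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tN\t<INS>\t.\tPASS\tMEITYPE=ALU;CILO=150;CIHI=200"
  ), path)
  expect_error(read_mei_calls(path, "primary_caller", "P01", "tumor"),
               "CILO <= POS <= CIHI")
})

test_that("MEI writer and reader round-trip", {
  calls <- make_calls("chr1", c(100L, 5000L), c("ALU", "LINE1"),
                      subfamily = c("AluYa5", "L1HS"),
                      tsd = c("ACGT", NA))
  calls$ci_lo <- c(NA_integer_, 4970L)
  calls$ci_hi <- c(NA_integer_, 5030L)
  path <- tempfile(fileext = ".vcf")
  write_mei_vcf(calls, path)
  back <- read_mei_calls(path, "primary_caller", "P001", "tumor")
  for (col in c("chrom", "pos", "te_family", "subfamily", "tsd_sequence",
                "ci_lo", "ci_hi", "call_id")) {
    expect_identical(back[[col]], calls[[col]], info = col)
  }
})

test_that("gene models pick the representative transcript by span", {
  gs <- make_gene_set(list(
    list(id = "g1", name = "GENE1", chrom = "chr1", strand = "+",
         transcripts = list(
           list(id = "g1.t1", exons = rbind(c(1000, 1500), c(10500, 11000))),
           list(id = "g1.t2", exons = rbind(c(1000, 1500), c(25500, 26000)))
         ))
  ))
  expect_identical(gs$genes$tx_id, "g1.t2")
  expect_identical(gs$genes$tx_length, 25001L)
})

test_that("representative-transcript ties go to the smaller transcript id", {
  gs <- make_gene_set(list(
    list(id = "g1", chrom = "chr1", strand = "+",
         transcripts = list(
           list(id = "g1.tB", exons = rbind(c(100, 2099))),
           list(id = "g1.tA", exons = rbind(c(500, 2499)))
         ))
  ))
  expect_identical(gs$genes$tx_id, "g1.tA")
})

test_that("gene model coordinates stay 1-based closed", {
  gs <- make_gene_set(list(
    list(id = "g1", chrom = "chr1", strand = "+",
         transcripts = list(list(id = "g1.t1",
                                 exons = rbind(c(101, 200), c(301, 400)))))
  ))
  expect_identical(gs$exons$start, c(101L, 301L))
  expect_identical(gs$exons$end, c(200L, 400L))
  expect_identical(gs$exons$end - gs$exons$start + 1L, c(100L, 100L))
})

test_that("orphan exons are rejected", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\texon\t100\t400\t.\t+\t.\tID=e1;Parent=g1.tMISSING"
  ), path)
  expect_error(read_gene_models(path), "orphan exon")
})

test_that("repeat tables infer families and lengths", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tsubfamily",
               "chr4\t1000\t7200\t+\tL1HS",
               "chr1\t5000\t5300\t-\tAluYb8",
               "chr2\t100\t400\t+\tMER41"), path)
  rs <- read_repeats(path)
  expect_identical(rs$family, c("LINE1", "ALU", "other"))
  expect_identical(rs$length[1], 6200L)
  writeLines(c("chrom\tstart\tend\tstrand\tsubfamily",
               "chr1\t500\t400\t+\tL1HS"), path)
  expect_error(read_repeats(path), "start >= end")
})

test_that("repeat round-trip is exact", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tsubfamily",
               "chr1\t999\t7199\t+\tL1PA2",
               "chr2\t0\t312\t-\tFLAM_C"), path)
  rs <- read_repeats(path)
  path2 <- tempfile(fileext = ".tsv")
  write_repeats(rs, path2)
  expect_identical(read_repeats(path2), rs)
  expect_identical(readLines(path), readLines(path2))
})

test_that("BED intervals convert involutively", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tcfs1", "chr2\t500\t900\tcfs2"), path)
  iv <- read_intervals(path)
  expect_identical(iv$start, c(1L, 501L))
  expect_identical(iv$end, c(10L, 900L))
  expect_identical(iv$end - iv$start + 1L, c(10L, 400L))
  path2 <- tempfile(fileext = ".bed")
  write_intervals(iv, path2)
  expect_identical(readLines(path2), readLines(path))

  writeLines(character(0), path)
  expect_identical(nrow(read_intervals(path)), 0L)
  writeLines("chr1\t-5\t10", path)
  expect_error(read_intervals(path), "negative")
  writeLines("chr1\tx\t10", path)
  expect_error(read_intervals(path), "non-integer")
})

test_that("beta/manifest reader aligns and validates keys", {
  beta_csv <- tempfile(fileext = ".csv")
  man_csv <- tempfile(fileext = ".csv")
  writeLines(c("probe_id,S1,S2,S3",
               "cg01,0.5,0.8,0.2",
               "cg02,0.1,0.9,0.4"), beta_csv)
  writeLines(c("probe_id,chrom,pos,region_annotations",
               "cg01,chr1,100,Body",
               "cg02,chr1,900,TSS1500;Body"), man_csv)
  bm <- read_beta_and_manifest(beta_csv, man_csv)
  expect_identical(dim(bm$beta), c(2L, 3L))
  expect_identical(bm$beta["cg01", "S2"], 0.8)

  writeLines(c("probe_id,S1", "cg01,0.5", "cg01,0.6"), beta_csv)
  expect_error(read_beta_and_manifest(beta_csv, man_csv), "duplicated")
  writeLines(c("probe_id,S1", "cg01,0.5", "cg09,0.6"), beta_csv)
  expect_error(read_beta_and_manifest(beta_csv, man_csv), "cg09")
})

test_that("beta clamping keeps the open unit interval", {
  expect_identical(clamp_beta(c(0, 0.5, 1)), c(1e-6, 0.5, 1 - 1e-6))
  expect_error(clamp_beta(1.2), "0, 1")
})

test_that("clinical reader validates survival fields", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,efs_time,event,age_dx,disease_status_dx,primary_site",
               "P1,1200,1,14,non_metastatic,leg",
               "P2,300,0,20,metastatic,arm"), path)
  cl <- read_clinical(path)
  expect_identical(cl$event, c(1L, 0L))
  writeLines(c("patient_id,efs_time,event,age_dx,disease_status_dx,primary_site",
               "P1,-3,1,14,non_metastatic,leg"), path)
  expect_error(read_clinical(path), "efs_time")
})

test_that("report writer is deterministic", {
  tabs <- list(b_table = data.frame(x = 1:3), a_table = data.frame(y = "z"))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_report(tabs, d1)
  p2 <- write_report(tabs[c(2, 1)], d2)
  expect_identical(basename(p1), c("a_table.tsv", "b_table.tsv"))
  expect_identical(readLines(file.path(d1, "b_table.tsv")),
                   readLines(file.path(d2, "b_table.tsv")))
})
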