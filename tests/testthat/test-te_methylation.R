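test_that("the M transform matches its analytic values and symmetry", {
  expect_identical(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.05, 0.95, 0.05)
  expect_equal(beta_to_m(1 - b), -beta_to_m(b))
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_equal(m_to_beta(beta_to_m(b)), b)
  expect_error(beta_to_m(1.5), "0, 1")
  expect_error(beta_to_m(-0.1), "0, 1")
})

test_that("full-length LINE-1 selection is a length and family filter", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tsubfamily",
               "chr1\t0\t6000\t+\tL1HS",       # length 6000
               "chr1\t10000\t15899\t+\tL1PA2", # length 5899
               "chr2\t0\t6000\t+\tAluYb8"), path)
  rs <- read_repeats(path)
  fl <- select_full_length_line1(rs, 5900L)
  expect_identical(fl$subfamily, "L1HS")
})

test_that("TSS windows are strand-aware around the most-5' end", {
  rs <- data.frame(chrom = "chr1", start = c(10001L, 10001L, 101L),
                   end = c(16000L, 16000L, 6100L),
                   strand = c("+", "-", "+"),
                   subfamily = "L1HS", family = "LINE1",
                   length = c(6000L, 6000L, 6000L))
  class(rs) <- c("repeat_set", "data.frame")
  w <- te_tss_windows(rs, 500L, c(chr1 = 20000L))
  expect_identical(w$start[1], 9501L)
  expect_identical(w$end[1], 10500L)
  expect_identical(w$start[2], 15501L)
  expect_identical(w$end[2], 16500L)
  # clamped at the contig start and flagged
  expect_identical(w$start[3], 1L)
  expect_identical(w$end[3], 600L)
  expect_true(w$truncated[3])
  expect_false(any(w$truncated[1:2]))
})

make_windows <- function(chrom, start, end, subfamily, family) {
  data.frame(element_id = paste0("e", seq_along(start)), chrom = chrom,
             start = as.integer(start), end = as.integer(end), strand = "+",
             subfamily = subfamily, family = family, truncated = FALSE,
             stringsAsFactors = FALSE)
}

test_that("probe mapping applies the ambiguity exclusion rules", {
  alu <- make_windows("chr1", c(1000L, 1800L, 5000L, 7000L),
                      c(1999L, 2799L, 5999L, 7999L),
                      c("AluYb8", "AluSx", "AluYb8", "AluYb8"), "ALU")
  l1 <- make_windows("chr1", 7500L, 8499L, "L1HS", "LINE1")
  manifest <- data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
    chrom = "chr1",
    pos = c(1200L,   # only the first AluYb8 window
            1900L,   # AluYb8 + AluSx -> multi_subfamily
            7700L,   # AluYb8 + L1HS -> cross_family
            100L,    # nothing
            5500L),  # single AluYb8 window
    stringsAsFactors = FALSE)
  a <- map_probes_to_windows(manifest, alu, l1)
  expect_identical(a$status, c("assigned", "excluded", "excluded",
                               "unassigned", "assigned"))
  expect_identical(a$reason[2], "multi_subfamily")
  expect_identical(a$reason[3], "cross_family")
  expect_identical(a$subfamily[c(1, 5)], c("AluYb8", "AluYb8"))
  # statuses partition the probe set
  expect_identical(sum(table(a$status)), nrow(manifest))

  # two windows of the same subfamily still give a unique assignment
  alu2 <- make_windows("chr1", c(1000L, 1500L), c(1999L, 2499L),
                       "AluYb8", "ALU")
  a2 <- map_probes_to_windows(
    data.frame(probe_id = "cg1", chrom = "chr1", pos = 1700L), alu2, l1[0, ])
  expect_identical(a2$status, "assigned")
  expect_identical(a2$subfamily, "AluYb8")
})

test_that("subfamily means average assigned probes per sample", {
  assign <- data.frame(probe_id = c("p1", "p2", "p3"),
                       status = c("assigned", "assigned", "excluded"),
                       family = c("ALU", "ALU", "ALU"),
                       subfamily = c("AluYb8", "AluYb8", "AluSx"),
                       reason = NA, stringsAsFactors = FALSE)
  m <- rbind(p1 = c(s1 = -2, s2 = 1.5), p2 = c(2, 1.5), p3 = c(9, 9))
  sm <- subfamily_sample_means(assign, m)
  expect_identical(rownames(sm), "AluYb8")
  expect_equal(sm["AluYb8", "s1"], 0)
  expect_equal(sm["AluYb8", "s2"], 1.5)
  expect_error(subfamily_sample_means(assign, m[1:1, , drop = FALSE]),
               "missing")
})

test_that("planted subfamily shifts are recovered within normal-theory error", {
  set.seed(11)
  n_probes <- 50L; delta <- 0.6; sdv <- 0.5
  n_t <- 12L; n_c <- 12L
  assign <- data.frame(probe_id = sprintf("p%02d", 1:n_probes),
                       status = "assigned", family = "LINE1",
                       subfamily = "L1HS", reason = NA)
  mu <- rnorm(n_probes, 2, 0.4)
  m <- cbind(
    matrix(rnorm(n_probes * n_t, mu - delta, sdv), n_probes, n_t),
    matrix(rnorm(n_probes * n_c, mu, sdv), n_probes, n_c))
  rownames(m) <- assign$probe_id
  colnames(m) <- c(paste0("T", 1:n_t), paste0("C", 1:n_c))
  sm <- subfamily_sample_means(assign, m)
  est <- mean(sm[1, 1:n_t]) - mean(sm[1, n_t + 1:n_c])
  se <- sdv / sqrt(n_probes) * sqrt(1 / n_t + 1 / n_c)
  expect_lt(abs(est + delta), 3 * se)
})

test_that("age categories follow the subfamily nomenclature", {
  expect_identical(age_category(c("L1HS", "L1PA2", "L1P1", "L1MA4"), "LINE1"),
                   c("young", "young", "intermediate", "old"))
  expect_identical(age_category(c("AluYa5", "AluSx", "AluJb", "FLAM_C"), "ALU"),
                   c("young", "intermediate", "old", "old"))
  expect_error(age_category("HAL1X", "LINE1"), "HAL1X")
  expect_error(age_category("L1HS", "SVA"), "LINE1 or ALU")
})

test_that("age aggregation is an unweighted mean over subfamily means", {
  sm <- rbind(L1HS = c(a = 1, b = 3), L1PA2 = c(3, 5), L1MA4 = c(0, 0))
  attr(sm, "family") <- c("LINE1", "LINE1", "LINE1")
  am <- age_category_means(sm)
  expect_equal(am["LINE1_young", "a"], 2)
  expect_equal(am["LINE1_young", "b"], 4)
  expect_equal(am["LINE1_old", "a"], 0)
  # invariant to subfamily ordering
  sm2 <- sm[c(3, 1, 2), ]
  attr(sm2, "family") <- c("LINE1", "LINE1", "LINE1")
  expect_equal(age_category_means(sm2)[rownames(am), ], am[, ])
})

test_that("region annotations collapse by the stated priority", {
  expect_identical(region_priority_label(c("Body", "TSS1500")), "TSS1500")
  expect_identical(region_priority_label("3UTR"), "3UTR")
  expect_identical(region_priority_label(c("TSS200", "5UTR", "Body")), "TSS200")
  expect_identical(region_priority_label("TSS200;5UTR;Body"), "TSS200")
  expect_error(region_priority_label(character(0)), "empty")
  expect_error(region_priority_label("Promoter"), "Promoter")
})

test_that("the rank-sum comparison matches exact small-sample p-values", {
  w <- group_compare_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)  # most extreme of C(6,3) = 20 rankings
  expect_equal(group_compare_wilcoxon(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  a <- c(1.2, 3.4, 2.2, 5.5); b <- c(2.0, 0.4, 4.4)
  expect_equal(group_compare_wilcoxon(a, b)$p_value,
               group_compare_wilcoxon(b, a)$p_value)
  expect_error(group_compare_wilcoxon(numeric(0), 1), "non-empty")
})

test_that("region methylation summary groups samples and regions", {
  manifest <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                         pos = 1:3,
                         region_annotations = c("Body", "TSS1500;Body", "3UTR"))
  m <- rbind(p1 = c(t1 = 1, t2 = 3, c1 = 0),
             p2 = c(2, 2, 1), p3 = c(5, 5, 5))
  s <- region_methylation_summary(manifest, m,
                                  list(tumor = c("t1", "t2"), control = "c1"))
  expect_equal(s$mean_m_tumor[s$region == "Body"], 2)
  expect_equal(s$mean_m_tumor[s$region == "TSS1500"], 2)
  expect_equal(s$mean_m_control[s$region == "3UTR"], 5)
  expect_identical(s$n_probes[s$region == "TSS200"], 0L)
})
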