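write_test_vcf <- function(rows, samples) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

test_that("genotype tallies per population handle missing and phased calls", {
  samples <- c("s1", "s2", "s3", "s4", "s5", "s6")
  rows <- c(
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "0|1", "1/1", "./.", "1|1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/0", "0/1", "0/1", "1/1"), collapse = "\t")
  )
  vcf <- write_test_vcf(rows, samples)
  panel <- tibble::tibble(sample = samples,
                          population = rep(c("P1", "P2"), each = 3))
  cnt <- genotype_counts(vcf, panel)
  expect_equal(nrow(cnt), 4L)
  r <- function(id, pop) cnt[cnt$snp_id == id & cnt$population == pop, ]
  expect_equal(unlist(r("rs1", "P1")[, 3:6], use.names = FALSE), c(1L, 2L, 0L, 0L))
  expect_equal(unlist(r("rs1", "P2")[, 3:6], use.names = FALSE), c(0L, 0L, 2L, 1L))
  expect_equal(unlist(r("rs2", "P2")[, 3:6], use.names = FALSE), c(0L, 2L, 1L, 0L))
  # population totals partition the cohort
  tot <- cnt$n_hom_ref + cnt$n_het + cnt$n_hom_alt + cnt$n_missing
  expect_true(all(tot == 3L))
})

test_that("multiallelic records and unknown samples are errors", {
  samples <- c("s1", "s2")
  rows <- paste(c("1", "100", "rsM", "A", "G,T", ".", "PASS", ".", "GT",
                  "0/1", "0/2"), collapse = "\t")
  vcf <- write_test_vcf(rows, samples)
  panel <- tibble::tibble(sample = samples, population = "P1")
  expect_error(genotype_counts(vcf, panel), "multiallelic.*rsM")
  rows2 <- paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                   "0/1", "0/0"), collapse = "\t")
  vcf2 <- write_test_vcf(rows2, samples)
  expect_error(genotype_counts(vcf2, panel[1, ]), "absent from panel")
})

test_that("chi-square HWE statistic matches hand-computed values", {
  expect_equal(hwe_chi2(50, 0, 50)$chi2_stat, 100)
  res <- hwe_chi2(25, 50, 25)
  expect_equal(res$chi2_stat, 0)
  expect_equal(res$p_chi2, 1)
  # independent formula evaluation for an arbitrary configuration
  o <- c(30, 40, 30)
  n <- sum(o); p <- (2 * o[1] + o[2]) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((o - e)^2 / e)
  got <- hwe_chi2(30, 40, 30)
  expect_equal(got$chi2_stat, chi, tolerance = 1e-12)
  expect_equal(got$p_chi2, pchisq(chi, 1, lower.tail = FALSE), tolerance = 1e-12)
  # monomorphic convention
  mono <- hwe_chi2(10, 0, 0)
  expect_equal(mono$p_chi2, 1)
})

test_that("exact HWE test equals direct enumeration (spot sweep)", {
  expect_equal(hwe_exact(10, 0, 0), 1)
  # all-heterozygote extreme: enumeration over even het counts 0..100
  expect_equal(hwe_exact(0, 100, 0), oracle_hwe_exact(0, 100, 0), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact(naa, nab, nbb), oracle_hwe_exact(naa, nab, nbb),
                 tolerance = 1e-12, info = paste(naa, nab, nbb))
  }
})

test_that("exact and chi-square p-values agree asymptotically", {
  # the two two-sided conventions converge slowly; at n = 20000 with all
  # genotype categories well filled they agree to ~0.02
  set.seed(7)
  for (i in 1:15) {
    n <- 20000
    q <- runif(1, 0.25, 0.5)
    g <- gen_genotypes(n, q, f = 0)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    if (min(cnt) < 20) next
    p_e <- hwe_exact(cnt[1], cnt[2], cnt[3])
    p_c <- hwe_chi2(cnt[1], cnt[2], cnt[3])$p_chi2
    expect_lt(abs(p_e - p_c), 0.02)
  }
})

test_that("heterozygote-excess D has the documented sign semantics", {
  # observed 60 het vs expected 50: D = +5
  # counts (20, 60, 20): p = 0.5, expected het = 50
  expect_equal(het_excess_d(20, 60, 20), 5)
  expect_equal(het_excess_d(50, 0, 50), -25)
  # D = 0 exactly at HWE frequencies
  expect_equal(het_excess_d(25, 50, 25), 0)
  expect_equal(het_excess_d(81, 18, 1), 0)  # p = 0.9
  # positive D iff heterozygotes above expectation
  expect_gt(het_excess_d(30, 55, 15), 0)
})

test_that("the low-count skip rule gates both tests", {
  expect_false(apply_skip_rule(5, 5, 5))
  expect_true(apply_skip_rule(4, 100, 100))
  expect_false(apply_skip_rule(0, 0, 0, min_count = 0))
  counts <- tibble::tibble(snp_id = c("a", "b"), population = "P1",
                           n_hom_ref = c(4L, 25L), n_het = c(100L, 50L),
                           n_hom_alt = c(100L, 25L), n_missing = 0L)
  res <- hwe_test(counts)
  expect_true(res$skipped[1])
  expect_true(is.na(res$p_exact[1]) && is.na(res$p_chi2[1]))
  expect_false(res$skipped[2])
  expect_equal(res$p_chi2[2], 1)
  # D is still reported for skipped rows
  expect_false(is.na(res$d_het_excess[1]))
  # chi2-only gating leaves the exact test on
  res2 <- hwe_test(counts, skip_applies = "chi2")
  expect_false(is.na(res2$p_exact[1]))
})

test_that("deviation summaries count populations and negative-D fractions", {
  hwe <- tibble::tibble(
    snp_id = rep(c("s1", "s2", "s3"), each = 3),
    population = rep(c("P1", "P2", "P3"), 3),
    p_exact = c(0.01, 0.04, 0.5, 0.9, 0.2, 0.7, NA, 0.8, 0.6),
    d_het_excess = c(-3, 2, 0, 1, -1, 0, 0, 1, -2),
    skipped = c(rep(FALSE, 6), TRUE, FALSE, FALSE)
  )
  summ <- deviation_summary(hwe, alpha = 0.05)
  s1 <- summ[summ$snp_id == "s1", ]
  expect_equal(s1$n_populations_tested, 3L)
  expect_equal(s1$n_populations_deviating, 2L)
  expect_true(s1$deviates_in_multiple)
  expect_equal(s1$frac_deviating_d_negative, 0.5)
  expect_false(summ$deviates[summ$snp_id == "s2"])
  expect_equal(summ$n_populations_tested[summ$snp_id == "s3"], 2L)
  ov <- deviation_overview(hwe, alpha = 0.05)
  expect_equal(ov$n_snps_deviating, 1L)
  expect_equal(ov$pct_deviating_pairs_d_negative, 50)
})

test_that("planted inbreeding is detected as heterozygote deficit", {
  set.seed(123)
  n_dev <- 40
  rej <- logical(n_dev); dneg <- logical(n_dev)
  for (i in seq_len(n_dev)) {
    g <- gen_genotypes(500, 0.3, f = 0.3)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    p <- hwe_exact(cnt[1], cnt[2], cnt[3])
    rej[i] <- p < 0.05
    dneg[i] <- het_excess_d(cnt[1], cnt[2], cnt[3]) < 0
  }
  expect_gte(mean(rej), 0.9)
  expect_true(all(dneg[rej]))
})
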