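fake_variants <- function(tab) {
  # tab: 2x2 matrix rows contacting/non_contacting, cols common/rare
  tibble::tibble(
    variant_id = sprintf("v%d", seq_len(sum(tab))),
    position_class = rep(rep(c("contacting", "non_contacting"), each = 2),
                         times = as.vector(t(tab))),
    is_common = rep(rep(c(TRUE, FALSE), 2), times = as.vector(t(tab)))
  )
}

test_that("a balanced table gives odds ratio 1 and p = 1", {
  res <- common_by_class_test(fake_variants(matrix(c(10, 10, 10, 10), 2)))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_fisher, 1)
  expect_equal(unname(res$table["contacting", "common"]), 10)
  g <- glance(res)
  expect_equal(g$odds_ratio, 1)
  t <- tidy(res)
  expect_equal(sum(t$n), 40)
})

test_that("Fisher exact p equals fixed-margin enumeration", {
  tab <- matrix(c(1, 9, 9, 1), 2, byrow = TRUE)
  res <- common_by_class_test(fake_variants(tab))
  expect_equal(res$p_fisher, oracle_fisher(tab), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- common_by_class_test(fake_variants(tab))
    expect_equal(res$p_fisher, oracle_fisher(tab), tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
})

test_that("degenerate tables are flagged with p = 1", {
  res <- common_by_class_test(fake_variants(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)))
  expect_true(res$degenerate)
  expect_equal(res$p_fisher, 1)
})

test_that("deviation-rate comparison joins the per-SNP summary by class", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:40),
    position_class = rep(c("contacting", "non_contacting"), each = 20)
  )
  dev <- tibble::tibble(snp_id = v$variant_id,
                        deviates = rep(c(TRUE, FALSE, TRUE, FALSE),
                                       times = c(5, 15, 5, 15)))
  res <- deviation_rate_test(v, dev)
  expect_equal(unname(res$table[, "deviating"]), c(5, 5))
  expect_equal(res$p_fisher, 1)
  # planted deviation only among contacting variants
  dev2 <- dev
  dev2$deviates <- c(rep(TRUE, 12), rep(FALSE, 8), rep(FALSE, 20))
  res2 <- deviation_rate_test(v, dev2)
  expect_lt(res2$p_fisher, 0.05)
  # zero deviants anywhere -> degenerate
  dev3 <- dev
  dev3$deviates <- FALSE
  expect_true(deviation_rate_test(v, dev3)$degenerate)
})

test_that("MAF stratification floors very rare variants into one bin", {
  v <- tibble::tibble(variant_id = c("a", "b", "c"),
                      maf = c(0.0005, 0.2, 0.001),
                      position_class = "contacting")
  s <- maf_stratified_summary(v)
  expect_equal(s$maf_bin[1], "<=0.001")
  expect_equal(s$maf_floored[1], 0.001)
  expect_equal(s$maf_bin[2], "0.2")
  expect_equal(s$maf_floored[2], 0.2)
  expect_equal(s$maf_bin[3], "<=0.001")
  # empty join produces an empty table
  expect_equal(nrow(maf_stratified_summary(v[0, ])), 0L)
  # joined flags and KL columns appear
  fl <- flag_deleterious(tibble::tibble(
    variant_id = c("a", "b", "c"), sift = c(0.01, 0.5, NA),
    polyphen2_hdiv = NA_real_, mutation_taster = NA_real_, fathmm = NA_real_))
  kl <- tibble::tibble(pair_id = c("a", "b"), summed = c(3.1, 0.2),
                       is_dramatic = c(TRUE, FALSE))
  s2 <- maf_stratified_summary(v, flags = fl, kl = kl)
  expect_equal(s2$n_methods_deleterious, c(1L, 0L, 0L))
  expect_equal(s2$summed_kl, c(3.1, 0.2, NA))
})

test_that("plot builders return ggplot objects", {
  res <- common_by_class_test(fake_variants(matrix(c(4, 10, 9, 5), 2, byrow = TRUE)))
  expect_s3_class(autoplot(res), "ggplot")
  hwe <- tibble::tibble(snp_id = "s", population = c("P1", "P2"),
                        p_exact = c(0.02, 0.7), d_het_excess = c(-2, 1),
                        skipped = FALSE)
  expect_s3_class(plot_hwe_deviation(hwe), "ggplot")
  strat <- tibble::tibble(variant_id = "a", maf = 0.1, maf_floored = 0.1,
                          maf_bin = "0.1", position_class = "contacting",
                          n_methods_deleterious = 2L, summed_kl = 1.2,
                          is_dramatic = FALSE)
  expect_s3_class(plot_maf_summary(strat), "ggplot")
})

test_that("pipeline outputs are deterministic and consistent with truth", {
  config <- list(seed = 41, n_proteins = 24, n_planted_arrays = 10,
                 n_variants = 60, n_individuals = 40,
                 populations = c("POPA", "POPB"), n_pfm_pairs = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- run_pipeline(c(config, list(out_dir = d1)))
  res2 <- run_pipeline(c(config, list(out_dir = d2)))
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  # class counts equal planted truth
  truth <- res1$sim$variants$truth
  got <- table(res1$variants$position_class)
  want <- table(truth$class)
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  # retained = planted missense at tracked positions
  expect_equal(nrow(res1$retained),
               sum(truth$effect == "missense" & truth$class != "unknown"))
  # margins conserved: annotated = retained + itemized drops
  expect_equal(nrow(res1$variants), nrow(res1$retained) + sum(res1$dropped$n))
})
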