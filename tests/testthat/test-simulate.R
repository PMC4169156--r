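test_that("sim_config validates its inputs", {
  expect_error(sim_config(fingers_per_array = 2), ">= 3")
  expect_error(sim_config(maf_spectrum = c(0.1, 0.6)), "0, 0.5")
  expect_error(sim_config(n_proteins = 5, n_planted_arrays = 10), "more planted")
  expect_error(sim_config(deleterious_fraction = 1.2), "0, 1")
})

test_that("gen_proteome plants the requested arrays and is deterministic", {
  cfg <- sim_config(seed = 3, n_proteins = 12, n_planted_arrays = 5,
                    fingers_per_array = 3)
  a <- gen_proteome(cfg)
  b <- gen_proteome(cfg)
  expect_identical(a$seqs, b$seqs)
  expect_equal(nrow(a$truth$arrays), 5L)
  expect_true(all(a$truth$arrays$n_fingers == 3L))
  expect_equal(nrow(a$truth$fingers), 15L)
  # nothing planted
  cfg0 <- sim_config(seed = 3, n_proteins = 4, n_planted_arrays = 0)
  p0 <- gen_proteome(cfg0)
  expect_equal(nrow(p0$truth$arrays), 0L)
  expect_equal(length(p0$seqs), 4L)
})

test_that("decoys preserve composition but (virtually) never form arrays", {
  cfg <- sim_config(seed = 5, n_proteins = 10, n_planted_arrays = 5)
  p <- gen_proteome(cfg)
  decoys <- p$seqs[grepl("^DECOY", names(p$seqs))]
  planted <- p$seqs[grepl("^ZNFP", names(p$seqs))]
  comp <- function(s) sort(table(strsplit(s, "")[[1]]))
  expect_true(all(vapply(decoys, function(d) {
    any(vapply(planted, function(q) identical(comp(d), comp(q)), logical(1)))
  }, logical(1))))
})

test_that("genotype generator matches its probability model", {
  # f = 1: heterozygotes impossible
  g1 <- gen_genotypes(500, maf = 0.4, f = 1, seed = 11)
  expect_equal(sum(g1 == 1L), 0L)
  # f = 0, maf = 0.5: het fraction near 0.5
  g2 <- gen_genotypes(20000, maf = 0.5, f = 0, seed = 12)
  expect_lt(abs(mean(g2 == 1L) - 0.5), 3 * sqrt(0.25 / 20000))
  # f = 0.2, maf = 0.3: het fraction within 3 SE of 2*0.3*0.7*0.8 = 0.336
  g3 <- gen_genotypes(10000, maf = 0.3, f = 0.2, seed = 13)
  p_het <- 2 * 0.3 * 0.7 * 0.8
  expect_lt(abs(mean(g3 == 1L) - p_het), 3 * sqrt(p_het * (1 - p_het) / 10000))
  # invalid inputs
  expect_error(gen_genotypes(10, maf = 0.6), "maf")
  expect_error(gen_genotypes(10, maf = 0.1, f = -0.5), "negative genotype")
})

test_that("variant table plants exact class counts and position-4 unknowns", {
  cfg <- sim_config(seed = 9, n_proteins = 10, n_planted_arrays = 8,
                    fingers_per_array = 4, n_variants = 40)
  prot <- gen_proteome(cfg)
  vt <- gen_variant_table(cfg, prot$truth, n_contacting = 10,
                          n_non_contacting = 10, n_unknown = 4,
                          n_silent = 3, n_other = 3)
  expect_equal(nrow(vt$variants), 30L)
  expect_equal(sum(vt$truth$class == "contacting" & vt$truth$effect == "missense"), 10L)
  expect_equal(sum(vt$truth$class == "non_contacting" & vt$truth$effect == "missense"), 10L)
  expect_equal(sum(vt$truth$class == "unknown"), 4L)
  expect_equal(sum(vt$truth$effect == "silent"), 3L)
  expect_equal(sum(vt$truth$effect == "other"), 3L)
  # planted position-4 rows are class unknown and do not land on tracked positions
  unk <- vt$truth[vt$truth$label == "4", ]
  expect_equal(nrow(unk), 4L)
  expect_true(all(unk$class == "unknown"))
  hm <- prot$truth$helix
  expect_equal(nrow(dplyr::inner_join(
    unk, hm, by = c(protein_id = "protein_id", residue_pos = "pos"))), 0L)
})

test_that("empty truth yields an empty variant table", {
  cfg <- sim_config(seed = 2, n_proteins = 3, n_planted_arrays = 0, n_variants = 0)
  p <- gen_proteome(cfg)
  vt <- gen_variant_table(cfg, p$truth, n_contacting = 0, n_non_contacting = 0,
                          n_unknown = 0, n_silent = 0, n_other = 0)
  expect_equal(nrow(vt$variants), 0L)
})

test_that("PFM pairs normalize, collapse at zero divergence, and respond to it", {
  pair0 <- gen_pfm_pair(0, seed = 21)
  expect_identical(pair0$ref, pair0$snp)
  expect_equal(unname(colSums(pair0$ref)), rep(1, 3), tolerance = 1e-9)
  cfg <- sim_config(seed = 31, n_pfm_pairs = 30)
  mean_kl <- vapply(c(0, 0.3, 0.9), function(d) {
    man <- gen_pfm_pairs(cfg, divergence = d)
    mean(vapply(seq_len(nrow(man)), function(i) {
      summed_kl(man$ref[[i]], man$snp[[i]])$summed
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean_kl[1], 0, tolerance = 1e-9)
  expect_true(all(diff(mean_kl) > 0))
})

test_that("score tables plant recoverable per-method deleterious sets", {
  cfg <- sim_config(seed = 17, n_variants = 400)
  ids <- sprintf("v%03d", 1:400)
  # extremes
  none <- gen_scores(cfg, ids, deleterious_fraction = 0)
  expect_equal(sum(flag_deleterious(none$scores)$n_methods_deleterious), 0L)
  all4 <- gen_scores(cfg, ids, deleterious_fraction = 1)
  expect_true(all(flag_deleterious(all4$scores)$n_methods_deleterious == 4L))
  # planted 25% for SIFT only, recovered within binomial error
  sift_only <- gen_scores(cfg, ids, deleterious_fraction = c(sift = 0.25))
  fl <- flag_deleterious(sift_only$scores)
  expect_equal(sum(fl$polyphen2_hdiv_del) + sum(fl$mutation_taster_del) +
                 sum(fl$fathmm_del), 0L)
  expect_lt(abs(mean(fl$sift_del) - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
  # flags recover the planted truth exactly
  mixed <- gen_scores(cfg, ids, deleterious_fraction = 0.3)
  flm <- flag_deleterious(mixed$scores)
  for (m in c("sift", "polyphen2_hdiv", "mutation_taster", "fathmm")) {
    expect_identical(flm[[paste0(m, "_del")]], mixed$truth[[paste0(m, "_del")]])
  }
})

test_that("simulated cohort files are byte-identical across runs", {
  cfg <- sim_config(seed = 23, n_proteins = 10, n_planted_arrays = 4,
                    n_variants = 20, n_individuals = 20,
                    populations = c("POPA", "POPB"), n_pfm_pairs = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
})
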