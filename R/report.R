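# Headline comparisons (common-variant depletion at contacting
# positions, HWE deviation rates by class), MAF-stratified summaries,
# and the end-to-end pipeline.

.assoc_test <- function(tab, comparison) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    p_fisher <- 1
    p_chi2 <- 1
    or <- NA_real_
  } else {
    p_fisher <- fisher.test(tab)$p.value
    p_chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  structure(list(table = tab, odds_ratio = or,
                 odds_ratio_infinite = is.finite(or) == FALSE && !degenerate,
                 p_fisher = p_fisher, p_chi2 = p_chi2,
                 degenerate = degenerate, comparison = comparison),
            class = "zfv_assoc")
}

#' Test depletion of common variants at DNA-contacting positions
#'
#' Builds the 2x2 table of position class (contacting / non-contacting)
#' against frequency class (common / rare) over retained missense
#' variants and tests association with a two-sided Fisher exact test
#' (primary) and a Pearson chi-square without continuity correction.
#' The odds ratio is (contacting-common x non-contacting-rare) /
#' (contacting-rare x non-contacting-common), so depletion of common
#' variants at contacting positions gives OR < 1.
#'
#' @param variants annotated variant tibble with `position_class` and
#'   `is_common` (see [annotate_variants()]; typically after
#'   [filter_retained()]).
#' @return a `zfv_assoc` object (see [tidy()]/[glance()] methods).
#' @export
common_by_class_test <- function(variants) {
  v <- variants %>% filter(.data$position_class %in% c("contacting", "non_contacting"))
  tab <- matrix(c(
    sum(v$position_class == "contacting" & v$is_common),
    sum(v$position_class == "contacting" & !v$is_common),
    sum(v$position_class == "non_contacting" & v$is_common),
    sum(v$position_class == "non_contacting" & !v$is_common)
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(class = c("contacting", "non_contacting"),
                  frequency = c("common", "rare")))
  .assoc_test(tab, "common vs rare by position class")
}

#' Compare HWE deviation rates between position classes
#'
#' Joins the per-SNP deviation summary to the annotated variants and
#' tests whether the proportion of SNPs deviating from HWE differs
#' between DNA-contacting and non-contacting positions (2x2 Fisher
#' exact + chi-square, like [common_by_class_test()]).
#'
#' @param variants annotated variant tibble (`variant_id`,
#'   `position_class`).
#' @param deviation per-SNP summary from [deviation_summary()].
#' @return a `zfv_assoc` object.
#' @export
deviation_rate_test <- function(variants, deviation) {
  v <- variants %>%
    filter(.data$position_class %in% c("contacting", "non_contacting")) %>%
    left_join(deviation %>% select("snp_id", "deviates"),
              by = c(variant_id = "snp_id")) %>%
    filter(!is.na(.data$deviates))
  tab <- matrix(c(
    sum(v$position_class == "contacting" & v$deviates),
    sum(v$position_class == "contacting" & !v$deviates),
    sum(v$position_class == "non_contacting" & v$deviates),
    sum(v$position_class == "non_contacting" & !v$deviates)
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(class = c("contacting", "non_contacting"),
                  deviation = c("deviating", "in_hwe")))
  .assoc_test(tab, "HWE deviation by position class")
}

#' @export
print.zfv_assoc <- function(x, ...) {
  cat("2x2 association:", x$comparison, "\n")
  print(x$table)
  if (x$degenerate) {
    cat("degenerate table (empty margin); p = 1 by convention\n")
  } else {
    cat(sprintf("odds ratio = %.4g; Fisher exact p = %.4g; chi-square p = %.4g\n",
                x$odds_ratio, x$p_fisher, x$p_chi2))
  }
  invisible(x)
}

#' @rdname common_by_class_test
#' @param x a `zfv_assoc` object.
#' @param ... unused.
#' @export
tidy.zfv_assoc <- function(x, ...) {
  as_tibble(as.data.frame.table(x$table, responseName = "n"))
}

#' @rdname common_by_class_test
#' @export
glance.zfv_assoc <- function(x, ...) {
  tibble(comparison = x$comparison, odds_ratio = x$odds_ratio,
         p_fisher = x$p_fisher, p_chi2 = x$p_chi2,
         degenerate = x$degenerate)
}

#' MAF-stratified summary of predictions and specificity shifts
#'
#' Joins deleteriousness flags and summed KL distances onto annotated
#' variants and floors very rare frequencies into a single bin
#' (frequencies below `floor` cannot be estimated reliably and are
#' clustered as `<= floor`).
#'
#' @param variants annotated variant tibble.
#' @param flags optional tibble from [flag_deleterious()].
#' @param kl optional tibble from [kl_pairs()] (`pair_id` matched to
#'   `variant_id`).
#' @param floor MAF floor for the clustered bin, default 0.001.
#' @return tibble: `variant_id`, `maf`, `maf_floored`, `maf_bin`,
#'   `position_class`, and when available `n_methods_deleterious`,
#'   `summed_kl`, `is_dramatic`.
#' @export
maf_stratified_summary <- function(variants, flags = NULL, kl = NULL,
                                   floor = 0.001) {
  out <- variants %>%
    select("variant_id", "maf", "position_class") %>%
    mutate(
      maf_floored = pmax(.data$maf, floor),
      maf_bin = if_else(.data$maf <= floor, paste0("<=", format(floor)),
                        vapply(.data$maf, format, character(1),
                               digits = 4, scientific = FALSE, trim = TRUE))
    )
  if (!is.null(flags)) {
    unmatched <- setdiff(out$variant_id, flags$variant_id)
    if (length(unmatched)) {
      inform(sprintf("%d variants without prediction scores", length(unmatched)))
    }
    out <- out %>%
      left_join(flags %>% select("variant_id", "n_methods_deleterious"),
                by = "variant_id")
  }
  if (!is.null(kl)) {
    out <- out %>%
      left_join(kl %>% select(variant_id = "pair_id", summed_kl = "summed",
                              "is_dramatic"),
                by = "variant_id")
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes scan -> variant mapping -> HWE -> KL -> report on either a
#' simulated cohort (when `config$seed` is set and no input paths are
#' given) or user-supplied files, writing every output table as TSV plus
#' a YAML run log (seed, parameters, input digests). Outputs are a pure
#' function of the configuration: identical configs give byte-identical
#' files. A missing PFM manifest skips the specificity stage with a
#' warning; other stage failures abort with stage-named errors.
#'
#' @param config a named list (or path of a YAML file) with any of:
#'   `seed`, `out_dir`, simulation parameters (passed to [sim_config()]),
#'   input paths (`fasta`, `variants`, `vcf`, `panel`, `scores`,
#'   `pfm_manifest`), and thresholds `alpha` (0.05), `min_count` (5),
#'   `common_threshold` (0.01), `kl_threshold` (2.5), `pseudocount`
#'   (1e-6).
#' @return invisibly, a list of all result tables and fitted tests.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(alpha = 0.05, min_count = 5L, common_threshold = 0.01,
                   kl_threshold = 2.5, pseudocount = 1e-6, seed = 1L)
  config <- modifyList(defaults, config)
  out_dir <- config$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  simulated <- is.null(config$fasta)
  if (simulated) {
    sim_args <- config[intersect(names(config), names(formals(sim_config)))]
    cfg <- do.call(sim_config, sim_args)
    sim <- stage("simulate", simulate_cohort(cfg, out_dir = if (is.null(out_dir)) NULL
                                             else file.path(out_dir, "inputs")))
    seqs <- sim$proteome$seqs
    variants_in <- sim$variants$variants
    gt <- sim$cohort$gt
    panel <- sim$cohort$panel
    scores_in <- sim$scores$scores
    pfm_manifest <- sim$pfms
  } else {
    sim <- NULL
    seqs <- .as_protein_set(config$fasta)
    variants_in <- readr::read_tsv(config$variants, show_col_types = FALSE)
    gt <- config$vcf
    panel <- config$panel
    scores_in <- if (!is.null(config$scores)) {
      readr::read_tsv(config$scores, show_col_types = FALSE)
    }
    pfm_manifest <- if (!is.null(config$pfm_manifest) && file.exists(config$pfm_manifest)) {
      man <- readr::read_tsv(config$pfm_manifest, show_col_types = FALSE)
      # relative PFM paths resolve against the manifest's own directory
      base <- dirname(config$pfm_manifest)
      fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
      man$ref_path <- fix(man$ref_path)
      man$snp_path <- fix(man$snp_path)
      man
    }
  }

  scan <- stage("scan", scan_proteome(seqs))
  annotated <- stage("map", annotate_variants(
    variants_in, scan$helix,
    protein_lengths = setNames(nchar(seqs), names(seqs)),
    common_threshold = config$common_threshold))
  retained <- filter_retained(annotated)

  hwe <- stage("hwe", {
    counts <- genotype_counts(gt, panel)
    hwe_test(counts, min_count = config$min_count)
  })
  dev_sum <- deviation_summary(hwe, alpha = config$alpha)

  kl <- if (!is.null(pfm_manifest)) {
    stage("kl", kl_pairs(pfm_manifest, pseudocount = config$pseudocount,
                         threshold = config$kl_threshold))
  } else {
    warn("no PFM manifest; specificity stage skipped")
    NULL
  }

  flags <- if (!is.null(scores_in)) flag_deleterious(scores_in) else NULL
  common_test <- stage("report", common_by_class_test(retained))
  dev_test <- stage("report", deviation_rate_test(retained, dev_sum))
  strat <- maf_stratified_summary(retained, flags = flags, kl = kl)
  agreement <- if (!is.null(flags)) count_method_agreement(flags) else NULL

  res <- list(
    scan = scan, variants = annotated, retained = retained,
    dropped = attr(retained, "dropped"),
    hwe = hwe, deviation = dev_sum,
    kl = kl, flags = flags, agreement = agreement,
    common_test = common_test, deviation_test = dev_test,
    maf_summary = strat, sim = sim, config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
    w(scan$fingers, "fingers.tsv")
    w(scan$arrays, "arrays.tsv")
    w(annotated %>% select(-dplyr::any_of("finger")), "variants_annotated.tsv")
    w(as_tibble(retained), "variants_retained.tsv")
    w(hwe, "hwe.tsv")
    w(dev_sum, "hwe_summary.tsv")
    if (!is.null(kl)) w(kl, "kl.tsv")
    if (!is.null(flags)) w(flags, "prediction_flags.tsv")
    w(strat, "maf_summary.tsv")
    w(bind_rows(glance(common_test), glance(dev_test)), "association_tests.tsv")
    digests <- if (!is.null(sim) && !is.null(sim$paths)) {
      setNames(as.list(unname(tools::md5sum(unlist(sim$paths)))), names(sim$paths))
    } else NULL
    log <- list(
      seed = config$seed,
      parameters = config[c("alpha", "min_count", "common_threshold",
                            "kl_threshold", "pseudocount")],
      simulated = simulated,
      input_md5 = digests
    )
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  }
  invisible(res)
}
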