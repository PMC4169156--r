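# Per-population genotype counts and Hardy-Weinberg deviation statistics:
# chi-square test, conditional exact test, heterozygote-excess D, and the
# low-count skip rule.

#' Tally genotype counts per SNP and population
#'
#' Reads biallelic SNP genotypes (GT field) and tallies hom-ref /
#' het / hom-alt / missing per (SNP, population), following the
#' one-VCF-per-cohort layout in which populations live only in a
#' separate sample panel.
#'
#' @param vcf path to a VCF file, a `vcfR` object, a genotype matrix
#'   (SNPs x samples) of GT strings such as `"0/0"`, `"0|1"`, `"./."`, or
#'   an integer alt-allele dosage matrix (0/1/2, NA = missing).
#' @param panel data frame with columns `sample` and `population`, or the
#'   path of a TSV with those columns. Every sample in the VCF must appear.
#' @return tibble: `snp_id`, `population`, `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing`.
#' @export
genotype_counts <- function(vcf, panel) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- readr::read_tsv(panel, show_col_types = FALSE)
  }
  if (!all(c("sample", "population") %in% names(panel))) {
    abort("panel needs columns 'sample' and 'population'")
  }
  if (is.matrix(vcf) && is.numeric(vcf)) {
    codes <- vcf  # alt-allele dosage matrix (0/1/2, NA missing)
  } else {
    codes <- .gt_codes(.extract_gt(vcf))
  }
  missing_samples <- setdiff(colnames(codes), panel$sample)
  if (length(missing_samples)) {
    abort(paste("samples absent from panel:",
                paste(head(missing_samples, 5L), collapse = ", ")))
  }
  pop <- setNames(panel$population, panel$sample)[colnames(codes)]
  out <- list()
  for (p in unique(pop)) {
    sub <- codes[, pop == p, drop = FALSE]
    out[[p]] <- tibble(
      snp_id = rownames(codes),
      population = p,
      n_hom_ref = as.integer(rowSums(sub == 0L, na.rm = TRUE)),
      n_het = as.integer(rowSums(sub == 1L, na.rm = TRUE)),
      n_hom_alt = as.integer(rowSums(sub == 2L, na.rm = TRUE)),
      n_missing = as.integer(rowSums(is.na(sub)))
    )
  }
  bind_rows(out) %>% arrange(.data$snp_id, .data$population)
}

.extract_gt <- function(vcf) {
  if (is.matrix(vcf)) return(vcf)
  if (is.character(vcf) && length(vcf) == 1L) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  if (!inherits(vcf, "vcfR")) abort("vcf must be a path, vcfR object or GT matrix")
  multi <- !vcfR::is.biallelic(vcf)
  if (any(multi)) {
    rec <- vcfR::getID(vcf)[which(multi)[1]]
    abort(sprintf("multiallelic record not supported: %s", rec))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  no_id <- is.na(ids) | ids == "."
  if (any(no_id)) {
    ids[no_id] <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))[no_id]
  }
  rownames(gt) <- ids
  gt
}

.gt_codes <- function(gt) {
  flat <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  codes[flat %in% "0/0"] <- 0L
  codes[flat %in% c("0/1", "1/0")] <- 1L
  codes[flat %in% "1/1"] <- 2L
  known <- flat %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".", "./", "/.") | is.na(flat)
  if (!all(known)) {
    abort(sprintf("unrecognised genotype string: %s", flat[!known][1]))
  }
  codes
}

#' Conditional exact test of Hardy-Weinberg equilibrium
#'
#' Conditions on the observed allele counts and enumerates every
#' heterozygote count of the same parity; each outcome's probability
#' under the HWE null follows the standard hypergeometric-type formula,
#' computed by the numerically stable ratio recurrence started at the
#' distribution's mode. The two-sided p-value is the total probability of
#' outcomes no more likely than the observed one (ties included).
#'
#' @param n_hom_ref,n_het,n_hom_alt integer vectors of genotype counts.
#' @return numeric vector of exact p-values in (0, 1]. Monomorphic
#'   configurations give 1.
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  mapply(.hwe_exact1, n_hom_ref, n_het, n_hom_alt, USE.NAMES = FALSE)
}

.hwe_exact1 <- function(naa, nab, nbb) {
  stopifnot(naa >= 0, nab >= 0, nbb >= 0)
  n <- naa + nab + nbb
  if (n < 1L) return(NA_real_)
  n_rare <- min(2L * naa + nab, 2L * nbb + nab)
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # unnormalized probabilities by the ratio recurrence, anchored at the mode
  probs <- numeric(length(hets))
  mode_idx <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n - 1)))
  probs[mode_idx] <- 1
  if (mode_idx < length(hets)) {
    for (i in mode_idx:(length(hets) - 1L)) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - hom_r - h
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
    }
  }
  if (mode_idx > 1L) {
    for (i in mode_idx:2L) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - hom_r - h
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(nab, hets)]
  if (is.na(p_obs)) abort("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' Expected counts are n(p-hat^2, 2 p-hat q-hat, q-hat^2) from the sample
#' allele frequency; the statistic sums (O - E)^2 / E over the three
#' genotype classes and is referred to chi-square with one degree of
#' freedom. No continuity correction is applied. Monomorphic
#' configurations give statistic 0 and p = 1 by convention.
#'
#' @inheritParams hwe_exact
#' @return tibble with `chi2_stat` and `p_chi2`.
#' @export
hwe_chi2 <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p_hat <- (2 * n_hom_ref + n_het) / (2 * n)
  q_hat <- 1 - p_hat
  mono <- p_hat == 0 | q_hat == 0
  e <- cbind(n * p_hat^2, 2 * n * p_hat * q_hat, n * q_hat^2)
  o <- cbind(n_hom_ref, n_het, n_hom_alt)
  chi2 <- rowSums((o - e)^2 / ifelse(e > 0, e, NA_real_), na.rm = TRUE)
  chi2[mono] <- 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  tibble(chi2_stat = chi2, p_chi2 = p)
}

#' Heterozygote-excess statistic D
#'
#' D is the observed minus HWE-expected number of heterozygous
#' individuals, divided by two. Positive D means more heterozygotes than
#' expected (heterozygote advantage); negative D means one or both
#' homozygotes are favoured.
#'
#' @inheritParams hwe_exact
#' @return numeric vector of D values (0 for monomorphic SNPs).
#' @export
het_excess_d <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p_hat <- (2 * n_hom_ref + n_het) / (2 * n)
  (n_het - 2 * p_hat * (1 - p_hat) * n) / 2
}

#' Low-count skip rule
#'
#' HWE calculations are not performed when any genotype category holds
#' fewer than `min_count` individuals (default 5). `min_count = 0`
#' disables the rule.
#'
#' @inheritParams hwe_exact
#' @param min_count minimum count per genotype category.
#' @return logical vector, `TRUE` when the SNP/population is skipped.
#' @export
apply_skip_rule <- function(n_hom_ref, n_het, n_hom_alt, min_count = 5L) {
  pmin(n_hom_ref, pmin(n_het, n_hom_alt)) < min_count
}

#' Hardy-Weinberg deviation statistics for a table of genotype counts
#'
#' Runs both HWE tests plus the heterozygote-excess statistic on every
#' (SNP, population) row, applying the low-count skip rule before both
#' tests (configurable to chi-square only). Skipped rows carry NA
#' p-values; D is always computed. Monomorphic rows are flagged, not
#' errors.
#'
#' @param counts tibble from [genotype_counts()] (columns `n_hom_ref`,
#'   `n_het`, `n_hom_alt`; other columns pass through).
#' @param min_count skip threshold, default 5; 0 disables.
#' @param skip_applies which tests the skip rule gates: `"both"`
#'   (default) or `"chi2"`.
#' @return `counts` with `n`, `p_hat`, `q_hat`, `expected_het`,
#'   `chi2_stat`, `p_chi2`, `p_exact`, `d_het_excess`, `monomorphic`,
#'   `skipped` added.
#' @export
hwe_test <- function(counts, min_count = 5L, skip_applies = c("both", "chi2")) {
  skip_applies <- match.arg(skip_applies)
  req <- c("n_hom_ref", "n_het", "n_hom_alt")
  if (!all(req %in% names(counts))) {
    abort("counts needs columns n_hom_ref, n_het, n_hom_alt")
  }
  if (nrow(counts) == 0L) {
    return(counts %>% mutate(n = integer(), p_hat = numeric(), q_hat = numeric(),
                             expected_het = numeric(), chi2_stat = numeric(),
                             p_chi2 = numeric(), p_exact = numeric(),
                             d_het_excess = numeric(), monomorphic = logical(),
                             skipped = logical()))
  }
  n_tot <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  p_hat <- ifelse(n_tot > 0, (2 * counts$n_hom_ref + counts$n_het) / (2 * n_tot), NA_real_)
  skipped <- apply_skip_rule(counts$n_hom_ref, counts$n_het, counts$n_hom_alt, min_count)
  chi <- hwe_chi2(counts$n_hom_ref, counts$n_het, counts$n_hom_alt)
  p_exact <- hwe_exact(counts$n_hom_ref, counts$n_het, counts$n_hom_alt)
  chi$chi2_stat[skipped] <- NA_real_
  chi$p_chi2[skipped] <- NA_real_
  if (skip_applies == "both") p_exact[skipped] <- NA_real_
  counts$n <- n_tot
  counts$p_hat <- p_hat
  counts$q_hat <- 1 - p_hat
  counts$expected_het <- 2 * p_hat * (1 - p_hat) * n_tot
  counts$chi2_stat <- chi$chi2_stat
  counts$p_chi2 <- chi$p_chi2
  counts$p_exact <- p_exact
  counts$d_het_excess <- het_excess_d(counts$n_hom_ref, counts$n_het, counts$n_hom_alt)
  counts$monomorphic <- p_hat %in% c(0, 1)
  counts$skipped <- skipped
  counts
}

#' Per-SNP summary of HWE deviation across populations
#'
#' Counts, for every SNP, how many populations were testable, how many
#' deviate from HWE (exact-test p below `alpha`), whether the SNP
#' deviates in more than one population, and the fraction of its
#' deviating (SNP, population) pairs with negative D. No multiple-testing
#' correction is applied by default (`bonferroni = TRUE` divides alpha by
#' the number of populations tested per SNP).
#'
#' @param hwe tibble from [hwe_test()] with a `snp_id` column.
#' @param alpha per-test significance level, default 0.05.
#' @param bonferroni apply a per-SNP Bonferroni correction (default off).
#' @return per-SNP tibble: `snp_id`, `n_populations_tested`,
#'   `n_populations_deviating`, `deviates`, `deviates_in_multiple`,
#'   `frac_deviating_d_negative` (NA when no population deviates).
#' @export
deviation_summary <- function(hwe, alpha = 0.05, bonferroni = FALSE) {
  if (!"snp_id" %in% names(hwe)) abort("hwe needs a snp_id column")
  hwe %>%
    group_by(.data$snp_id) %>%
    summarise(
      n_populations_tested = sum(!.data$skipped & !is.na(.data$p_exact)),
      n_populations_deviating = {
        a <- if (bonferroni) alpha / max(1L, sum(!is.na(.data$p_exact))) else alpha
        sum(.data$p_exact < a, na.rm = TRUE)
      },
      frac_deviating_d_negative = {
        a <- if (bonferroni) alpha / max(1L, sum(!is.na(.data$p_exact))) else alpha
        dev <- !is.na(.data$p_exact) & .data$p_exact < a
        if (any(dev)) mean(.data$d_het_excess[dev] < 0) else NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(
      deviates = .data$n_populations_deviating >= 1L,
      deviates_in_multiple = .data$n_populations_deviating > 1L
    )
}

#' Cohort-level overview of HWE deviation
#'
#' @param hwe tibble from [hwe_test()].
#' @param alpha significance level for the exact test.
#' @return one-row tibble: SNP totals, deviation percentages, and the
#'   percentage of deviating (SNP, population) pairs with negative D.
#' @export
deviation_overview <- function(hwe, alpha = 0.05) {
  summ <- deviation_summary(hwe, alpha = alpha)
  dev_pairs <- hwe %>% filter(!is.na(.data$p_exact), .data$p_exact < alpha)
  tibble(
    n_snps = nrow(summ),
    n_snps_tested = sum(summ$n_populations_tested > 0L),
    n_snps_deviating = sum(summ$deviates),
    pct_snps_deviating = 100 * mean(summ$deviates[summ$n_populations_tested > 0L]),
    n_deviating_multiple = sum(summ$deviates_in_multiple),
    pct_deviating_pairs_d_negative =
      if (nrow(dev_pairs)) 100 * mean(dev_pairs$d_het_excess < 0) else NA_real_
  )
}
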