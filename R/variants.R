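# Variant-to-finger mapping, coding-effect and frequency classification,
# and deleteriousness prediction flags.

#' Classify the coding effect of a codon substitution
#'
#' Translates both codons with the standard genetic code. Identical amino
#' acids give `silent`, two different non-stop amino acids give
#' `missense`, and gain or loss of a stop codon gives `other`.
#'
#' @param ref_codon,alt_codon character vectors of DNA triplets (A/C/G/T).
#' @return character vector over `{"missense", "silent", "other"}`.
#' @examples
#' classify_effect("GAA", "GAG")  # silent
#' classify_effect("CGC", "CAC")  # missense
#' classify_effect("TAC", "TAA")  # other (stop gain)
#' @export
classify_effect <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  bad <- nchar(ref_codon) != 3L | nchar(alt_codon) != 3L |
    grepl("[^ACGT]", ref_codon) | grepl("[^ACGT]", alt_codon)
  if (any(bad)) abort("codons must be DNA triplets over A/C/G/T")
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  dplyr::case_when(
    aa_ref == aa_alt ~ "silent",
    aa_ref == "*" | aa_alt == "*" ~ "other",
    TRUE ~ "missense"
  )
}

#' Classify a minor allele frequency as common or rare
#'
#' A variant is common when its MAF reaches the threshold (default 1%).
#'
#' @param maf numeric vector of minor allele frequencies in \[0, 0.5\].
#' @param threshold common/rare cutoff, default 0.01.
#' @return logical vector, `TRUE` when common.
#' @export
classify_frequency <- function(maf, threshold = 0.01) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 0.5)) {
    abort("maf must lie in [0, 0.5]")
  }
  maf >= threshold
}

#' Map variants onto zinc finger helix positions and classify them
#'
#' Joins protein-level substitutions to the helix position map of the
#' scanned fingers. A variant landing on a tracked position gets that
#' position label and class (contacting for -1/2/3/6, non-contacting for
#' C2/-2/1/5); any other residue gets label `"none"` and class
#' `"unknown"`. Variants are de-duplicated by
#' (protein_id, residue_pos, alt_aa); should a residue be tracked by two
#' overlapping fingers, the earlier finger wins with a warning.
#'
#' @param variants tibble with columns `variant_id`, `protein_id`,
#'   `residue_pos`, `ref_aa`, `alt_aa`, `maf`, and optionally `effect`
#'   (derived from `ref_aa`/`alt_aa` when absent: equal amino acids give
#'   silent, a `*` gives other, otherwise missense).
#' @param helix helix map tibble from [helix_position_map()].
#' @param protein_lengths optional named integer vector; when given,
#'   variants with `residue_pos` beyond their protein's length are an error.
#' @param common_threshold MAF threshold for `is_common` (default 0.01).
#' @return the variant tibble with `position_label`, `position_class`,
#'   `finger` and `is_common` columns added.
#' @export
annotate_variants <- function(variants, helix, protein_lengths = NULL,
                              common_threshold = 0.01) {
  req <- c("variant_id", "protein_id", "residue_pos", "ref_aa", "alt_aa", "maf")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    abort(paste("variants is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(protein_lengths)) {
    plen <- protein_lengths[variants$protein_id]
    out_of_range <- !is.na(plen) & variants$residue_pos > plen
    if (any(out_of_range)) {
      abort(sprintf("variant %s: residue position beyond protein length",
                    variants$variant_id[which(out_of_range)[1]]))
    }
  }
  variants <- variants %>%
    distinct(.data$protein_id, .data$residue_pos, .data$alt_aa, .keep_all = TRUE)
  if (!"effect" %in% names(variants)) {
    variants <- variants %>%
      mutate(effect = dplyr::case_when(
        .data$ref_aa == .data$alt_aa ~ "silent",
        .data$ref_aa == "*" | .data$alt_aa == "*" ~ "other",
        TRUE ~ "missense"
      ))
  }
  hits <- helix %>%
    select("protein_id", residue_pos = "pos", position_label = "label",
           finger = "finger")
  dup <- hits %>% count(.data$protein_id, .data$residue_pos) %>% filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    warn("residue tracked by more than one finger; assigning the earlier finger")
    hits <- hits %>%
      group_by(.data$protein_id, .data$residue_pos) %>%
      dplyr::slice_min(.data$finger, n = 1L, with_ties = FALSE) %>%
      ungroup()
  }
  variants %>%
    left_join(hits, by = c("protein_id", "residue_pos")) %>%
    mutate(
      position_label = dplyr::coalesce(.data$position_label, "none"),
      position_class = position_class(.data$position_label),
      is_common = classify_frequency(.data$maf, common_threshold)
    )
}

#' Retain missense variants at tracked helix positions
#'
#' Applies the study's two retention rules: the variant must be missense
#' (frameshift/stop/silent changes are dropped), and it must sit at a
#' tracked DNA-contacting or non-contacting helix position. Counts dropped
#' by each rule are attached as the `"dropped"` attribute.
#'
#' @param variants annotated variant tibble from [annotate_variants()].
#' @return the retained subset, with attribute `dropped` (a tibble of
#'   rule/n pairs).
#' @export
filter_retained <- function(variants) {
  non_missense <- variants$effect != "missense"
  untracked <- !variants$position_class %in% c("contacting", "non_contacting")
  keep <- !non_missense & !untracked
  out <- variants[keep, , drop = FALSE]
  attr(out, "dropped") <- tibble(
    rule = c("non_missense", "untracked_position"),
    n = c(sum(non_missense), sum(!non_missense & untracked))
  )
  out
}

#' Flag variants predicted deleterious by each method
#'
#' Applies the four per-method thresholds, all strict inequalities:
#' SIFT < 0.05, PolyPhen2-HDIV > 0.95, MutationTaster > 0.90,
#' FATHMM < -1.5. A missing score never flags its method.
#'
#' @param scores tibble with `variant_id` and numeric columns `sift`,
#'   `polyphen2_hdiv`, `mutation_taster`, `fathmm` (NA allowed).
#' @param thresholds named list overriding the default cutoffs.
#' @return `scores` with logical columns `sift_del`, `polyphen2_hdiv_del`,
#'   `mutation_taster_del`, `fathmm_del`, plus `n_methods_deleterious`
#'   and a `flags` string (methods joined by `+`, `""` when none).
#' @export
flag_deleterious <- function(scores,
                             thresholds = list(sift = 0.05, polyphen2_hdiv = 0.95,
                                               mutation_taster = 0.90, fathmm = -1.5)) {
  missing_cols <- setdiff(.score_methods, names(scores))
  if (length(missing_cols)) {
    abort(paste("scores is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  out <- scores %>%
    mutate(
      sift_del = !is.na(.data$sift) & .data$sift < thresholds$sift,
      polyphen2_hdiv_del = !is.na(.data$polyphen2_hdiv) &
        .data$polyphen2_hdiv > thresholds$polyphen2_hdiv,
      mutation_taster_del = !is.na(.data$mutation_taster) &
        .data$mutation_taster > thresholds$mutation_taster,
      fathmm_del = !is.na(.data$fathmm) & .data$fathmm < thresholds$fathmm
    )
  del <- as.matrix(out[paste0(.score_methods, "_del")])
  out$n_methods_deleterious <- as.integer(rowSums(del))
  out$flags <- apply(del, 1L, function(z) paste(.score_methods[z], collapse = "+"))
  out
}

#' Count agreement between deleteriousness prediction methods
#'
#' Partitions variants flagged by at least one method into the 15
#' non-empty method subsets (the cells of a four-set Venn diagram) and
#' tallies variants by the number of agreeing methods.
#'
#' @param flags tibble from [flag_deleterious()].
#' @return list with `by_subset` (15 rows: `methods`, `n_methods`,
#'   `n_variants`; cells sum to the number of variants flagged by >= 1
#'   method) and `by_n` (counts for 0--4 agreeing methods).
#' @export
count_method_agreement <- function(flags) {
  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(.score_methods, k, paste, collapse = "+", simplify = FALSE)
  }))
  by_subset <- tibble(methods = subsets,
                      n_methods = stringr::str_count(subsets, stringr::fixed("+")) + 1L) %>%
    left_join(flags %>% filter(.data$flags != "") %>% count(.data$flags),
              by = c(methods = "flags")) %>%
    mutate(n_variants = dplyr::coalesce(.data$n, 0L)) %>%
    select(-"n") %>%
    arrange(.data$n_methods, .data$methods)
  by_n <- tibble(n_methods = 0:4) %>%
    left_join(flags %>% count(.data$n_methods_deleterious),
              by = c(n_methods = "n_methods_deleterious")) %>%
    mutate(n_variants = dplyr::coalesce(.data$n, 0L)) %>%
    select(-"n")
  list(by_subset = by_subset, by_n = by_n)
}
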