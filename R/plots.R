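# Diagnostic plots for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_hline geom_vline
#'   labs scale_x_log10 position_dodge theme_minimal
NULL

#' Plot a 2x2 association result
#'
#' Bar chart of the contingency table behind a [common_by_class_test()]
#' or [deviation_rate_test()] result.
#'
#' @param object a `zfv_assoc` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.zfv_assoc <- function(object, ...) {
  d <- tidy(object)
  names(d)[2] <- "category"
  ggplot(d, aes(x = .data$class, y = .data$n, fill = .data$category)) +
    geom_col(position = position_dodge()) +
    labs(title = object$comparison,
         subtitle = sprintf("Fisher exact p = %.3g", object$p_fisher),
         x = NULL, y = "variants") +
    theme_minimal()
}

#' Plot HWE deviation per (SNP, population)
#'
#' Heterozygote-excess D against the exact-test p-value; deviating pairs
#' (p below `alpha`) sit left of the vertical line, and negative D
#' (homozygote excess) below the horizontal one.
#'
#' @param hwe tibble from [hwe_test()].
#' @param alpha significance level drawn as a reference line.
#' @return a ggplot.
#' @export
plot_hwe_deviation <- function(hwe, alpha = 0.05) {
  d <- hwe %>% filter(!.data$skipped, !is.na(.data$p_exact))
  ggplot(d, aes(x = .data$p_exact, y = .data$d_het_excess,
                colour = .data$population)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = alpha, linetype = 2) +
    geom_hline(yintercept = 0, linetype = 3) +
    scale_x_log10() +
    labs(x = "exact HWE p-value", y = "heterozygote excess D") +
    theme_minimal()
}

#' Plot predictions and specificity shifts against MAF
#'
#' The MAF-stratified view of deleteriousness agreement (point size =
#' number of agreeing methods) and, when present, summed KL distance.
#'
#' @param strat tibble from [maf_stratified_summary()].
#' @param kl_threshold reference line for dramatic specificity shifts.
#' @return a ggplot.
#' @export
plot_maf_summary <- function(strat, kl_threshold = 2.5) {
  if ("summed_kl" %in% names(strat) && any(!is.na(strat$summed_kl))) {
    ggplot(strat %>% filter(!is.na(.data$summed_kl)),
           aes(x = .data$maf_floored, y = .data$summed_kl,
               colour = .data$position_class)) +
      geom_point(alpha = 0.7) +
      geom_hline(yintercept = kl_threshold, linetype = 2) +
      scale_x_log10() +
      labs(x = "minor allele frequency (floored)", y = "summed KL distance") +
      theme_minimal()
  } else {
    ggplot(strat, aes(x = .data$maf_floored,
                      y = .data$n_methods_deleterious,
                      colour = .data$position_class)) +
      geom_point(alpha = 0.7) +
      scale_x_log10() +
      labs(x = "minor allele frequency (floored)",
           y = "methods predicting deleterious") +
      theme_minimal()
  }
}
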