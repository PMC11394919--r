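#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Volcano plot of differential-expression results
#'
#' @param de_results [nb_wald_test()] output.
#' @param lfc,alpha Gates drawn as reference lines (defaults match
#'   [nb_wald_test()]).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de_results, lfc = 0.2, alpha = 0.05) {
  ggplot2::ggplot(de_results,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(.data$p_adj),
                               colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-trait enrichment
#'
#' @param trait_tbl [trait_enrichment()] output.
#' @param top Number of traits shown (by direct rSNP count), default 20.
#' @return A ggplot object.
#' @export
plot_trait_enrichment <- function(trait_tbl, top = 20) {
  df <- trait_tbl |> dplyr::slice_head(n = top) |>
    mutate(trait = factor(.data$trait, levels = rev(.data$trait)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$trait)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_rsnp_direct,
                                     colour = .data$significant)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  size = "direct rSNPs", colour = "p.adj < 0.1") +
    ggplot2::theme_minimal()
}

#' ROC curve for one gene
#'
#' Plots the empirical ROC curve (true-positive vs false-positive rate
#' over score thresholds) with the AUC in the subtitle.
#'
#' @param values,labels,positive As in [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(values, labels, positive = NULL) {
  if (!is.logical(labels)) labels <- labels == positive
  res <- roc_auc(values, labels)
  ord <- order(values, decreasing = TRUE)
  tpr <- c(0, cumsum(labels[ord]) / sum(labels))
  fpr <- c(0, cumsum(!labels[ord]) / sum(!labels))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  subtitle = sprintf("AUC = %.3f", res$auc)) +
    ggplot2::theme_minimal()
}
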