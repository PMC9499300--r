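#' Plot the QC filtering funnel
#'
#' @param report A stage report from [qc_report()].
#' @return A ggplot object.
#' @export
plot_filter_funnel <- function(report) {
  df <- dplyr::mutate(report, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_pass)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_pass), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants retained",
                  title = "Variant filtering funnel") +
    ggplot2::theme_minimal()
}

#' Plot the mutation-type spectrum
#'
#' @param spectrum A tibble from [mutation_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- dplyr::mutate(spectrum,
                      consequence = stats::reorder(.data$consequence, -.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consequence, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "variants", title = "Mutation-type spectrum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Forest plot of enrichment odds ratios
#'
#' @param enrichment A tibble from [run_enrichment()]; only significant
#'   variants are drawn by default.
#' @param significant_only Restrict to significant variants (default TRUE).
#' @return A ggplot object.
#' @export
plot_enrichment_or <- function(enrichment, significant_only = TRUE) {
  df <- if (significant_only) {
    dplyr::filter(enrichment, .data$significant)
  } else {
    enrichment
  }
  df <- dplyr::mutate(df, label = paste(.data$gene, .data$variant))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$or, y = stats::reorder(.data$label, .data$or)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL,
                  title = "Case vs reference enrichment") +
    ggplot2::theme_minimal()
}

#' ROC curves for the full and control metastasis models
#'
#' @param eval A [cross_cohort_evaluate()] result.
#' @return A ggplot object.
#' @export
plot_roc <- function(eval) {
  df <- dplyr::bind_rows(
    dplyr::mutate(eval$full$roc_test,
                  model = sprintf("full (AUC %.3f)", eval$full$auc_test)),
    dplyr::mutate(eval$control$roc_test,
                  model = sprintf("control (AUC %.3f)", eval$control$auc_test))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Held-out metastasis prediction") +
    ggplot2::theme_minimal()
}
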