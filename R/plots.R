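#' Volcano plot of a moderated differential-expression result
#'
#' @param object an `lnr_de` object.
#' @param alpha Bonferroni significance level highlighted.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lnr_de
#' @export
autoplot.lnr_de <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- !is.na(df$p_bonferroni) & df$p_bonferroni < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$logFC, -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (non-responder vs responder)",
                  y = expression(-log[10](p)),
                  colour = sprintf("Bonferroni < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' GSEA running-sum plot
#'
#' @param object an `lnr_gsea` object.
#' @param ... unused.
#' @return a ggplot of the running enrichment score.
#' @method autoplot lnr_gsea
#' @export
autoplot.lnr_gsea <- function(object, ...) {
  running <- attr(object, "running")
  df <- tibble::tibble(rank = seq_along(running), running = running)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "rank in ordered gene list",
                  y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}

#' Per-cluster module-score distributions
#'
#' @param scores an `lnr_module_score` tibble.
#' @param clusters cluster label per cell.
#' @return a ggplot of score distributions by cluster.
#' @export
plot_module_scores <- function(scores, clusters) {
  df <- tibble::tibble(score = scores$score,
                       cluster = as.character(clusters))
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$score)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "module score") +
    ggplot2::theme_minimal()
}

#' Estimated cell-type fractions per sample
#'
#' @param fractions an `lnr_fractions` tibble.
#' @return a stacked-bar ggplot of fractions.
#' @export
plot_fractions <- function(fractions) {
  types <- attr(fractions, "cell_types") %||%
    setdiff(names(fractions), c("sample_id", "residual_norm"))
  df <- tidyr::pivot_longer(fractions, dplyr::all_of(types),
                            names_to = "cell_type", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$fraction,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Nested-CV model ranking plot
#'
#' @param object an `lnr_cv` object.
#' @param ... unused.
#' @return a ggplot of per-fold and mean MCC per model.
#' @method autoplot lnr_cv
#' @export
autoplot.lnr_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$model, .data$mcc,
                                                  FUN = mean),
                                   .data$mcc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick",
                          size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "outer-fold MCC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
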