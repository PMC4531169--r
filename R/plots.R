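#' Volcano-style plot of module differential expression
#'
#' Log2 fold change against -log10 adjusted p, faceted by cancer condition,
#' with the calling thresholds drawn as reference lines.
#'
#' @param de_table output of [module_de()].
#' @param alpha,lfc_min thresholds to draw.
#' @return A ggplot object.
#' @export
plot_module_de <- function(de_table, alpha = 0.01, lfc_min = 2) {
  ggplot2::ggplot(de_table,
                  ggplot2::aes(x = .data$lfc, y = -log10(.data$fdr),
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (cancer - normal)",
                  y = expression(-log[10] ~ "FDR"),
                  colour = "call",
                  title = "Module differential expression vs normal tissue")
}

#' Dot plot of module subtype-specificity AUC
#'
#' @param spec_table output of [specificity_auc()].
#' @param auc_hi,auc_lo extremeness thresholds to draw.
#' @return A ggplot object.
#' @export
plot_module_specificity <- function(spec_table, auc_hi = 0.9, auc_lo = 0.1) {
  d <- dplyr::arrange(spec_table, .data$auc)
  d$module <- factor(d$module, levels = d$module)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auc, y = .data$module,
                                  colour = .data$extreme)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = c(auc_lo, 0.5, auc_hi),
                        linetype = c("dashed", "dotted", "dashed")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#8e44ad",
                                            `FALSE` = "grey60")) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "ROC AUC (positive class: subtype A)", y = NULL,
                  colour = "extreme",
                  title = "Module subtype specificity")
}

#' Bar plot of top discriminating genes
#'
#' Mirrors the usual presentation of a discriminating-gene screen: the top
#' upregulated (positive score) and downregulated (negative score) genes,
#' bar height the signed score, labelled by module.
#'
#' @param scores output of [score_genes()].
#' @param top_n genes to show per direction.
#' @return A ggplot object.
#' @export
plot_gene_scores <- function(scores, top_n = 10) {
  ranked <- scores[!is.na(scores$rank), , drop = FALSE]
  up <- utils::head(ranked[ranked$score > 0, ], top_n)
  down <- utils::head(ranked[ranked$score < 0, ], top_n)
  d <- dplyr::bind_rows(up, down) |>
    dplyr::arrange(.data$score)
  d$gene <- factor(d$gene, levels = d$gene)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$score,
                                  fill = .data$score > 0)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$module,
                                    y = .data$score / 2), size = 2.5) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2980b9"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "discriminating score",
                  title = "Top subtype-discriminating genes")
}

#' Autoplot a pipeline result
#'
#' @param object a `discordnet_result`.
#' @param type which panel: gene scores (default), module specificity, or
#'   module DE.
#' @param ... passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.discordnet_result <- function(object,
                                       type = c("scores", "specificity", "de"),
                                       ...) {
  type <- match.arg(type)
  switch(type,
         scores = plot_gene_scores(object$scores, ...),
         specificity = plot_module_specificity(object$specificity,
                                               auc_hi = object$config$auc_hi,
                                               auc_lo = object$config$auc_lo),
         de = plot_module_de(object$de, alpha = object$config$alpha,
                             lfc_min = object$config$lfc_min))
}

#' @export
ggplot2::autoplot
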