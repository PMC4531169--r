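#' Pipeline configuration
#'
#' Collects every tunable threshold with the method's standard values as
#' defaults: 1% coexpression quantiles, backbone score threshold 500
#' (strict), module-DE FDR 0.01 with |log2 fold change| > 2, AUC extremeness
#' 0.9/0.1, enrichment threshold 0.01, ANOVA FDR 0.05.
#'
#' @param top_frac,bottom_frac coexpression selection quantile fractions.
#' @param min_score backbone association score threshold (strictly greater
#'   retained).
#' @param algorithm,min_module_size,seed partitioning controls (see
#'   [partition_modules()]).
#' @param alpha,lfc_min module differential-expression thresholds.
#' @param auc_hi,auc_lo module specificity extremeness thresholds.
#' @param enrich_alpha,relatedness_min enrichment controls.
#' @param anova_alpha validation ANOVA FDR threshold.
#' @param normal,cancer_a,cancer_b condition names; `cancer_a` is the
#'   positive (AUC) class.
#' @param block_size optional correlation block size (see [pairwise_pcc()]).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(top_frac = 0.01, bottom_frac = 0.01,
                            min_score = 500, algorithm = "fast_greedy",
                            min_module_size = 3L, seed = 1L,
                            alpha = 0.01, lfc_min = 2,
                            auc_hi = 0.9, auc_lo = 0.1,
                            enrich_alpha = 0.01, relatedness_min = 0.3,
                            anova_alpha = 0.05,
                            normal = "normal", cancer_a = "cancerA",
                            cancer_b = "cancerB", block_size = NULL) {
  structure(list(top_frac = top_frac, bottom_frac = bottom_frac,
                 min_score = min_score, algorithm = algorithm,
                 min_module_size = as.integer(min_module_size),
                 seed = as.integer(seed), alpha = alpha, lfc_min = lfc_min,
                 auc_hi = auc_hi, auc_lo = auc_lo,
                 enrich_alpha = enrich_alpha,
                 relatedness_min = relatedness_min,
                 anova_alpha = anova_alpha, normal = normal,
                 cancer_a = cancer_a, cancer_b = cancer_b,
                 block_size = block_size),
            class = "pipeline_config")
}

#' Run the full discrimination pipeline
#'
#' Executes the complete analysis on three-condition expression data and a
#' scored backbone: per-condition all-pairs PCC and signed-pair selection,
#' network assembly, modularity partitioning, module median expression,
#' differential expression against normal with cross-subtype categories,
#' subtype-specificity AUC over the DE modules, and gene scoring in the
#' extreme-AUC modules. Gene-set enrichment (with redundancy reduction) runs
#' when `gene_sets` is supplied. When `out_dir` is given, all result tables
#' and a provenance log (inputs, parameters, versions) are written there.
#'
#' @param expression named list of wide expression tibbles; names must
#'   include the three configured conditions. Genes are restricted to those
#'   present in every condition (dropped counts are logged).
#' @param backbone scored edge tibble.
#' @param config a [pipeline_config()].
#' @param gene_sets optional long gene-set tibble for enrichment.
#' @param out_dir optional output directory.
#' @return A `discordnet_result` list: `pair_sets`, `network`,
#'   `network_summary`, `partition`, `module_expression`, `de`, `categories`,
#'   `specificity`, `scores`, `module_stats`, `enrichment` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(expression, backbone, config = pipeline_config(),
                         gene_sets = NULL, out_dir = NULL) {
  conds <- c(config$normal, config$cancer_a, config$cancer_b)
  if (!all(conds %in% names(expression))) {
    stop_input(sprintf("expression must be a named list covering: %s",
                       paste(conds, collapse = ", ")))
  }
  expression <- expression[conds]

  # common gene universe across the three conditions
  gene_lists <- lapply(expression, function(e) e$gene)
  common <- Reduce(intersect, gene_lists)
  dropped <- sum(vapply(gene_lists, function(g) length(setdiff(g, common)),
                        integer(1)))
  if (dropped > 0) {
    inform(sprintf("dropped %d gene entries absent from at least one condition",
                   dropped))
  }
  expression <- lapply(expression, function(e) e[match(common, e$gene), ])

  pair_sets <- purrr::imap(expression, function(ex, cond) {
    select_signed_pairs(pairwise_pcc(ex, block_size = config$block_size),
                        top_frac = config$top_frac,
                        bottom_frac = config$bottom_frac,
                        condition = cond)
  })
  net <- build_network(pair_sets, backbone, min_score = config$min_score)
  partition <- partition_modules(net, algorithm = config$algorithm,
                                 min_size = config$min_module_size,
                                 seed = config$seed)
  mod_expr <- module_expression_all(expression, partition)
  de <- module_de(mod_expr, normal = config$normal, alpha = config$alpha,
                  lfc_min = config$lfc_min)
  categories <- categorize_modules(de, cancer_a = config$cancer_a,
                                   cancer_b = config$cancer_b)
  de_modules <- categories$module[categories$category != "ns"]
  spec_tbl <- specificity_auc(mod_expr, positive = config$cancer_a,
                              negative = config$cancer_b,
                              auc_hi = config$auc_hi, auc_lo = config$auc_lo,
                              modules = de_modules)
  scores <- score_genes(net, partition, spec_tbl, auc_hi = config$auc_hi,
                        auc_lo = config$auc_lo,
                        cancer_a = config$cancer_a,
                        cancer_b = config$cancer_b)
  module_stats <- assemble_module_stats(partition, de, categories, spec_tbl,
                                        config)
  enr <- NULL
  if (!is.null(gene_sets) && length(de_modules) > 0) {
    enr <- enrich_modules(partition, gene_sets, alpha = config$enrich_alpha,
                          modules = de_modules)
    enr <- cluster_and_filter(enr, gene_sets,
                              relatedness_min = config$relatedness_min)
  }
  result <- structure(
    list(pair_sets = pair_sets, network = net,
         network_summary = network_summary(net), partition = partition,
         module_expression = mod_expr, de = de, categories = categories,
         specificity = spec_tbl, scores = scores,
         module_stats = module_stats, enrichment = enr, config = config),
    class = "discordnet_result")
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

assemble_module_stats <- function(partition, de, categories, spec_tbl, config) {
  part <- as_tibble(partition)
  sizes <- part |>
    group_by(.data$module) |>
    summarise(n_genes = n(), analyzed = .data$analyzed[1], .groups = "drop")
  wide <- de |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("t", "p", "fdr", "lfc", "call"))
  # normalise the two cancer-condition suffixes to _a / _b
  names(wide) <- sub(paste0("_", config$cancer_a, "$"), "_a", names(wide))
  names(wide) <- sub(paste0("_", config$cancer_b, "$"), "_b", names(wide))
  sizes |>
    left_join(wide, by = "module") |>
    left_join(categories[c("module", "category")], by = "module") |>
    left_join(spec_tbl[c("module", "auc", "extreme")], by = "module") |>
    arrange(.data$module)
}

#' Write all pipeline result tables and a provenance log
#'
#' @param result a `discordnet_result`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) readr::write_tsv(as_tibble(x),
                                            file.path(out_dir, name),
                                            progress = FALSE)
  signed <- purrr::imap_dfr(result$pair_sets, function(ps, cond) {
    out <- as_tibble(ps)
    if (!"condition" %in% names(out)) out$condition <- cond
    out
  })
  tsv(signed, "signed_pairs.tsv")
  tsv(result$network, "network.tsv")
  tsv(result$partition, "modules.tsv")
  tsv(result$module_stats, "module_stats.tsv")
  tsv(result$scores, "gene_scores.tsv")
  if (!is.null(result$enrichment)) tsv(result$enrichment, "enrichment.tsv")

  cfg <- result$config
  lines <- c(
    "discordnet provenance log",
    sprintf("package_version: %s", as.character(utils::packageVersion("discordnet"))),
    sprintf("conditions: normal=%s cancer_a=%s cancer_b=%s",
            cfg$normal, cfg$cancer_a, cfg$cancer_b),
    sprintf("n_genes_analyzed: %d",
            length(unique(c(result$network$gene1, result$network$gene2)))),
    sprintf("n_edges: %d", nrow(result$network)),
    sprintf("modularity: %.6f", attr(result$partition, "modularity")),
    "parameters:",
    vapply(setdiff(names(cfg), "block_size"), function(k) {
      sprintf("  %s: %s", k, paste(format(cfg[[k]]), collapse = " "))
    }, character(1)),
    sprintf("  block_size: %s",
            if (is.null(cfg$block_size)) "whole-matrix" else format(cfg$block_size)))
  writeLines(lines, file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.discordnet_result <- function(x, ...) {
  s <- x$network_summary
  cat("<discordnet_result>\n")
  cat(sprintf("  network: %d genes, %d edges\n", s$n_nodes, s$n_edges))
  cat(sprintf("  partition: %d modules (Q = %.3f), %d analyzed\n",
              length(unique(x$partition$module)),
              attr(x$partition, "modularity"),
              length(unique(x$partition$module[x$partition$analyzed]))))
  cat(sprintf("  DE modules: %d; extreme-AUC modules: %d; scored genes: %d\n",
              sum(x$categories$category != "ns"),
              sum(x$specificity$extreme),
              sum(!is.na(x$scores$rank))))
  invisible(x)
}
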