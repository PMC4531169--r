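#' Coexpression sign difference per edge
#'
#' Encodes, for every network edge, how the pair's coexpression status
#' differs between the two cancer subtypes: the absolute difference of the
#' two signs. Discordant pairs (positively coexpressed in one subtype,
#' negatively in the other, `+1` vs `-1` in either order) score 2; pairs
#' coexpressed in one subtype but unselected in the other score 1; pairs
#' with the same status in both score 0. Normal-condition signs are carried
#' on the network but play no role here.
#'
#' @param net a `cancer_network`.
#' @param cancer_a,cancer_b names of the two cancer conditions.
#' @return The edge tibble with an added integer `diff` column in `{0,1,2}`.
#' @export
edge_sign_diff <- function(net, cancer_a = "cancerA", cancer_b = "cancerB") {
  ca <- paste0("sign_", cancer_a)
  cb <- paste0("sign_", cancer_b)
  if (!all(c(ca, cb) %in% names(net))) {
    stop_input(sprintf("network lacks sign columns for '%s' and '%s'", cancer_a, cancer_b))
  }
  out <- as_tibble(net)
  out$diff <- abs(out[[ca]] - out[[cb]])
  out
}

#' Average coexpression sign difference per gene
#'
#' For each gene, averages the edge sign difference over its module-internal
#' edges (edges whose other endpoint lies in the same module). Genes with no
#' module-internal edge get `mean_diff = 0` and `n_edges = 0`; they carry no
#' differential-coexpression evidence and are excluded from ranking
#' downstream.
#'
#' @param net a `cancer_network`.
#' @param partition a `module_partition`.
#' @param cancer_a,cancer_b names of the two cancer conditions.
#' @param genes optional genes to report (default: all partitioned genes
#'   present in the network); asking for a gene outside the network is an
#'   error.
#' @return Tibble `gene`, `module`, `n_edges`, `mean_diff`.
#' @export
gene_mean_diff <- function(net, partition, cancer_a = "cancerA",
                           cancer_b = "cancerB", genes = NULL) {
  part <- as_tibble(partition)
  nodes <- network_nodes(net)
  if (!is.null(genes)) {
    outside <- setdiff(genes, nodes)
    if (length(outside) > 0) {
      stop_input(sprintf("gene(s) not in network: %s",
                         paste(utils::head(outside, 5), collapse = ", ")))
    }
    part <- part[part$gene %in% genes, , drop = FALSE]
  } else {
    part <- part[part$gene %in% nodes, , drop = FALSE]
  }
  edges <- edge_sign_diff(net, cancer_a, cancer_b)
  mod_of <- setNames(as_tibble(partition)$module, as_tibble(partition)$gene)
  internal <- edges[!is.na(mod_of[edges$gene1]) & !is.na(mod_of[edges$gene2]) &
                      mod_of[edges$gene1] == mod_of[edges$gene2], , drop = FALSE]
  incident <- bind_rows(
    tibble(gene = internal$gene1, diff = internal$diff),
    tibble(gene = internal$gene2, diff = internal$diff))
  stats_tbl <- incident |>
    group_by(.data$gene) |>
    summarise(n_edges = n(), mean_diff = mean(.data$diff), .groups = "drop")
  part |>
    select("gene", "module") |>
    left_join(stats_tbl, by = "gene") |>
    mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L),
           mean_diff = dplyr::coalesce(.data$mean_diff, 0)) |>
    arrange(.data$gene)
}

#' Score genes by module specificity and coexpression change
#'
#' Ranks candidate subtype-discriminating genes. Only genes in modules with
#' extreme subtype-specificity AUC (`auc > auc_hi` or `auc < auc_lo`) are
#' scored. A gene's score is the module's signed specificity times the
#' gene's mean coexpression sign difference:
#' `score = (auc - 0.5) * mean_diff`, in `[-1, 1]`. Positive scores mark
#' genes from modules upregulated in the positive subtype (`cancer_a`),
#' negative scores the converse; the magnitude combines how
#' subtype-specific the module is with how strongly the gene's coexpression
#' pattern differs between the subtypes. Genes with no module-internal edge
#' are kept in the table with score 0 but excluded from the ranking.
#'
#' @param net a `cancer_network`.
#' @param partition a `module_partition`.
#' @param specificity output of [specificity_auc()] (typically over the DE
#'   modules).
#' @param auc_hi,auc_lo extremeness thresholds for module screening.
#' @param modules optional further module filter (e.g. DE modules only).
#' @param cancer_a,cancer_b names of the two cancer conditions.
#' @return Tibble `gene`, `module`, `auc`, `n_edges`, `mean_diff`, `score`,
#'   `rank` (by decreasing `|score|`, ties broken by gene id; `NA` for
#'   unrankable genes), sorted by rank. Empty, with a warning, when no
#'   module is extreme.
#' @export
score_genes <- function(net, partition, specificity, auc_hi = 0.9,
                        auc_lo = 0.1, modules = NULL,
                        cancer_a = "cancerA", cancer_b = "cancerB") {
  screened <- specificity |>
    filter(.data$auc > auc_hi | .data$auc < auc_lo)
  if (!is.null(modules)) screened <- screened[screened$module %in% modules, ]
  if (nrow(screened) == 0) {
    warn("no module passes the extreme-AUC screen; empty score table")
    return(tibble(gene = character(), module = character(), auc = numeric(),
                  n_edges = integer(), mean_diff = numeric(),
                  score = numeric(), rank = integer()))
  }
  part <- as_tibble(partition)
  member <- part[part$module %in% screened$module & part$analyzed, , drop = FALSE]
  md <- gene_mean_diff(net, partition, cancer_a, cancer_b)
  out <- member |>
    select("gene", "module") |>
    left_join(md, by = c("gene", "module")) |>
    mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L),
           mean_diff = dplyr::coalesce(.data$mean_diff, 0)) |>
    left_join(screened[c("module", "auc")], by = "module") |>
    mutate(score = (.data$auc - 0.5) * .data$mean_diff) |>
    relocate("auc", .after = "module")
  n_unranked <- sum(out$n_edges == 0)
  if (n_unranked > 0) {
    inform(sprintf("%d gene(s) without module-internal edges excluded from ranking",
                   n_unranked))
  }
  out <- out |>
    arrange(desc(abs(.data$score)), .data$gene) |>
    mutate(rank = if_else(.data$n_edges > 0, row_number(), NA_integer_))
  # ranks must be contiguous over rankable genes
  out$rank[!is.na(out$rank)] <- rank(out$rank[!is.na(out$rank)],
                                     ties.method = "first")
  arrange(out, is.na(.data$rank), .data$rank, .data$gene)
}
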