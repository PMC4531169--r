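#' Fisher's-exact gene-set enrichment for one module
#'
#' One-sided (overrepresentation) Fisher's exact test of a module's genes
#' against a gene set, over a declared gene universe. The 2x2 table is
#' (in-module & in-set, in-module & not-in-set, in-set & not-in-module,
#' neither); the one-sided p equals the hypergeometric upper tail. A module
#' or set that is empty after intersection with the universe yields p = 1
#' and is flagged `degenerate`.
#'
#' @param module_genes character vector of module member genes (must lie in
#'   the universe).
#' @param set_genes character vector of gene-set members (intersected with
#'   the universe).
#' @param universe character vector, the gene universe.
#' @return One-row tibble `k` (overlap), `K` (set size in universe), `n`
#'   (module size), `N` (universe size), `p`, `degenerate`.
#' @export
fisher_enrich <- function(module_genes, set_genes, universe) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (length(setdiff(module_genes, universe)) > 0) {
    stop_input("module genes must be a subset of the universe")
  }
  set_genes <- intersect(unique(set_genes), universe)
  N <- length(universe)
  n <- length(module_genes)
  K <- length(set_genes)
  k <- length(intersect(module_genes, set_genes))
  if (n == 0 || K == 0) {
    return(tibble(k = k, K = K, n = n, N = N, p = 1, degenerate = TRUE))
  }
  tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble(k = k, K = K, n = n, N = N, p = p, degenerate = FALSE)
}

#' Enrichment of every module against a gene-set collection
#'
#' Runs [fisher_enrich()] for each analyzed module of a partition against
#' each gene set. The default universe is the set of network genes carried by
#' the partition. Significance is judged on the raw p-value at `alpha`;
#' BH-adjusted p-values (across sets, within each module) are reported as an
#' extra column.
#'
#' @param partition a `module_partition` (or tibble `gene`, `module`).
#' @param gene_sets long tibble `set`, `description`, `gene`.
#' @param universe gene universe; defaults to the partitioned genes.
#' @param alpha raw-p significance threshold.
#' @param modules optional module subset (e.g. DE modules).
#' @return Tibble `module`, `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `significant`.
#' @export
enrich_modules <- function(partition, gene_sets, universe = NULL,
                           alpha = 0.01, modules = NULL) {
  part <- as_tibble(partition)
  if ("analyzed" %in% names(part)) part <- part[part$analyzed, , drop = FALSE]
  if (!is.null(modules)) part <- part[part$module %in% modules, , drop = FALSE]
  universe <- universe %||% unique(part$gene)
  part <- part[part$gene %in% universe, , drop = FALSE]
  sets <- split(gene_sets$gene, gene_sets$set)
  out <- purrr::map_dfr(unique(part$module), function(mod) {
    mg <- part$gene[part$module == mod]
    purrr::imap_dfr(sets, function(sg, sname) {
      res <- fisher_enrich(mg, sg, universe)
      dplyr::bind_cols(tibble(module = mod, set = sname), res)
    })
  })
  out |>
    group_by(.data$module) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$p < alpha) |>
    select(-"degenerate") |>
    relocate("p_adj", .after = "p")
}

#' Relatedness of two gene sets
#'
#' The number of overlapping genes divided by the number of genes in the
#' union (the Jaccard index).
#'
#' @param set1,set2 character vectors; both must be nonempty.
#' @return Value in `[0, 1]`.
#' @export
set_relatedness <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  if (length(set1) == 0 || length(set2) == 0) {
    stop_input("set_relatedness requires two nonempty sets")
  }
  length(intersect(set1, set2)) / length(union(set1, set2))
}

#' Redundancy reduction of enrichment results
#'
#' Highly overlapping gene sets produce redundant enrichment hits. This
#' cluster-and-filter step builds a gene-set relatedness graph (edges where
#' the Jaccard relatedness is at least `relatedness_min`), partitions it with
#' the same greedy modularity algorithm used for the gene network, and within
#' each gene-set community marks the most significantly enriched (minimum-p)
#' significant result as the representative — per module, so each module
#' keeps one representative per community. Ties on p are broken by
#' lexicographic set name. The reduced list never grows and always keeps the
#' most significant result.
#'
#' @param results output of [enrich_modules()].
#' @param gene_sets the gene-set collection the results were computed from.
#' @param relatedness_min Jaccard threshold for gene-set graph edges.
#' @return `results` with added columns `set_community` and
#'   `representative`.
#' @export
cluster_and_filter <- function(results, gene_sets, relatedness_min = 0.3) {
  sets <- split(gene_sets$gene, gene_sets$set)
  set_names <- sort(names(sets))
  n_sets <- length(set_names)
  pairs <- if (n_sets >= 2) utils::combn(set_names, 2) else matrix(character(), 2, 0)
  rel <- purrr::map_dbl(seq_len(ncol(pairs)), function(i) {
    set_relatedness(sets[[pairs[1, i]]], sets[[pairs[2, i]]])
  })
  keep <- rel >= relatedness_min
  g <- igraph::graph_from_data_frame(
    tibble(from = pairs[1, keep], to = pairs[2, keep]),
    directed = FALSE, vertices = set_names)
  comm <- igraph::membership(igraph::cluster_fast_greedy(igraph::simplify(g)))
  community <- setNames(sprintf("gs%03d", as.integer(comm)), names(comm))

  out <- results |>
    mutate(set_community = unname(community[.data$set])) |>
    group_by(.data$module, .data$set_community) |>
    arrange(.data$p, .data$set, .by_group = TRUE) |>
    mutate(representative = .data$significant &
             row_number() == 1 & any(.data$significant)) |>
    ungroup() |>
    arrange(.data$module, .data$set)
  # a non-significant minimum cannot represent; promote nothing in that case
  out$representative[!out$significant] <- FALSE
  out
}
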