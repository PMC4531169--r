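#' Partition the network into gene modules
#'
#' Partitions the binary network into modules by modularity optimisation.
#' The default algorithm is agglomerative greedy modularity merging
#' (`igraph::cluster_fast_greedy`), which is deterministic once the vertex
#' order is fixed; vertices are sorted lexicographically so repeated runs are
#' identical. `"louvain"` is available as an alternative and is seeded for
#' reproducibility. Modules smaller than `min_size` are retained in the table
#' but flagged `analyzed = FALSE`: one- or two-gene modules cannot support
#' median-expression or within-module coexpression statistics.
#'
#' @param net a `cancer_network` from [build_network()].
#' @param algorithm `"fast_greedy"` (default) or `"louvain"`.
#' @param min_size smallest module size admitted to downstream analysis.
#' @param seed integer seed (used by the stochastic algorithms).
#' @return A `module_partition`: tibble `gene`, `module` (`"m<k>"`, numbered
#'   by decreasing size), `module_size`, `analyzed`, with attributes
#'   `modularity` (Newman-Girvan Q of the partition) and `algorithm`.
#' @export
partition_modules <- function(net, algorithm = c("fast_greedy", "louvain"),
                              min_size = 3L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (nrow(net) == 0) stop_input("cannot partition an empty network")
  nodes <- network_nodes(net)
  g <- igraph::graph_from_data_frame(
    as_tibble(net)[c("gene1", "gene2")], directed = FALSE, vertices = nodes)
  g <- igraph::simplify(g)
  comm <- switch(algorithm,
    fast_greedy = igraph::cluster_fast_greedy(g),
    louvain = withr::with_seed(derive_seed(seed, "louvain"),
                               igraph::cluster_louvain(g)))
  memb <- igraph::membership(comm)

  assignment <- tibble(gene = names(memb), raw = as.integer(memb))
  # relabel by decreasing size, ties by smallest member gene id
  sizes <- assignment |>
    group_by(.data$raw) |>
    summarise(module_size = n(), first_gene = min(.data$gene), .groups = "drop") |>
    arrange(desc(.data$module_size), .data$first_gene) |>
    mutate(module = sprintf("m%03d", row_number()))
  out <- assignment |>
    left_join(sizes, by = "raw") |>
    select("gene", "module", "module_size") |>
    mutate(analyzed = .data$module_size >= min_size) |>
    arrange(.data$module, .data$gene)

  q <- modularity_q(net, setNames(out$module, out$gene))
  structure(out,
            modularity = q,
            algorithm = algorithm,
            min_size = as.integer(min_size),
            class = c("module_partition", class(out)))
}

#' Newman-Girvan modularity of a partition
#'
#' Computes `Q = sum_c (e_c / m - (d_c / 2m)^2)` over modules `c`, where
#' `e_c` is the number of intra-module edges, `d_c` the total degree of the
#' module's nodes, and `m` the number of edges — on the binary (unweighted)
#' graph. Invariant under relabelling of module ids.
#'
#' @param net a `cancer_network` (or any tibble with `gene1`/`gene2`).
#' @param assignment named vector or two-column data frame (`gene`,
#'   `module`) covering every network node.
#' @return Modularity Q, a number in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, assignment) {
  if (is.data.frame(assignment)) {
    assignment <- setNames(assignment$module, assignment$gene)
  }
  nodes <- network_nodes(net)
  missing_nodes <- setdiff(nodes, names(assignment))
  if (length(missing_nodes) > 0) {
    stop_input(sprintf("assignment missing %d network node(s), e.g. %s",
                       length(missing_nodes), missing_nodes[1]))
  }
  m <- nrow(net)
  if (m == 0) return(0)
  mod1 <- assignment[net$gene1]
  mod2 <- assignment[net$gene2]
  e_c <- table(factor(mod1[mod1 == mod2], levels = unique(assignment)))
  deg <- table(factor(assignment[c(net$gene1, net$gene2)],
                      levels = unique(assignment)))
  sum(as.numeric(e_c) / m - (as.numeric(deg) / (2 * m))^2)
}

#' Write a module assignment table
#' @param partition a `module_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(as_tibble(partition), path, progress = FALSE)
  invisible(path)
}
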