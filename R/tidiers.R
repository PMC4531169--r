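#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cancer network
#'
#' @param x a `cancer_network`.
#' @param ... unused.
#' @return The edge tibble (one row per edge with per-condition signs).
#' @export
tidy.cancer_network <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidy.cancer_network
#' @export
glance.cancer_network <- function(x, ...) network_summary(x)

#' Tidy a module partition
#'
#' @param x a `module_partition`.
#' @param ... unused.
#' @return `tidy()`: the gene-to-module assignment tibble. `glance()`: a
#'   one-row tibble with module counts and modularity Q.
#' @export
tidy.module_partition <- function(x, ...) {
  tibble::as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidy.module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tbl <- tibble::as_tibble(unclass_keep_tbl(x))
  tibble(n_modules = length(unique(tbl$module)),
         n_analyzed_modules = length(unique(tbl$module[tbl$analyzed])),
         n_genes = nrow(tbl),
         modularity = attr(x, "modularity"),
         algorithm = attr(x, "algorithm"))
}

#' Tidy a pipeline result
#'
#' @param x a `discordnet_result`.
#' @param ... unused.
#' @return `tidy()`: the gene score table. `glance()`: one-row summary of
#'   the run (network size, modularity, DE/extreme module and scored gene
#'   counts).
#' @export
tidy.discordnet_result <- function(x, ...) x$scores

#' @rdname tidy.discordnet_result
#' @export
glance.discordnet_result <- function(x, ...) {
  tibble(n_nodes = x$network_summary$n_nodes,
         n_edges = x$network_summary$n_edges,
         n_modules = length(unique(x$partition$module)),
         modularity = attr(x$partition, "modularity"),
         n_de_modules = sum(x$categories$category != "ns"),
         n_extreme_modules = sum(x$specificity$extreme),
         n_scored_genes = sum(!is.na(x$scores$rank)))
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("cancer_network", "module_partition"))
  x
}
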