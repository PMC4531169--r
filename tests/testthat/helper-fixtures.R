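# Construct a cancer_network through the public API from a manual edge
# specification: a tibble with gene1, gene2, score, sign_normal,
# sign_cancerA, sign_cancerB (sign columns optional, default 0).
make_net <- function(edges, min_score = 500) {
  for (col in c("sign_normal", "sign_cancerA", "sign_cancerB")) {
    if (is.null(edges[[col]])) edges[[col]] <- 0L
  }
  pair_sets <- lapply(c(normal = "sign_normal", cancerA = "sign_cancerA",
                        cancerB = "sign_cancerB"), function(col) {
    sel <- edges[edges[[col]] != 0, c("gene1", "gene2"), drop = FALSE]
    sel$pcc <- 0.9 * edges[[col]][edges[[col]] != 0]
    sel$sign <- as.integer(edges[[col]][edges[[col]] != 0])
    sel
  })
  suppressWarnings(
    build_network(pair_sets, edges[c("gene1", "gene2", "score")],
                  min_score = min_score))
}

# Edge list of one or more disjoint cliques, signed +1 in cancerA.
clique_edges <- function(sizes, score = 900L) {
  offset <- 0L
  out <- list()
  for (s in sizes) {
    genes <- sprintf("n%02d", offset + seq_len(s))
    cmb <- combn(genes, 2)
    out[[length(out) + 1]] <- tibble::tibble(
      gene1 = cmb[1, ], gene2 = cmb[2, ], score = score, sign_cancerA = 1L)
    offset <- offset + s
  }
  dplyr::bind_rows(out)
}

# Small planted study reused by pipeline-level tests.
small_study <- function(seed = 11) {
  spec <- planted_spec(
    n_genes = 150, n_modules = 3, module_size = 12,
    samples_per_condition = c(normal = 30, cancerA = 30, cancerB = 30),
    within_module_corr = 0.9, de_shift = 3, flip_fraction = 0.5, seed = seed)
  simulate_study(spec, n_background = 100, n_decoys = 5)
}
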