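#' Build the disease-specific coexpression network
#'
#' Combines the per-condition signed coexpression pairs and intersects them
#' with the scored functional-association backbone: an edge is retained when
#' it is selected (top or bottom PCC quantile) in at least one condition and
#' its backbone association score is strictly greater than `min_score`. The
#' result is a binary network whose edges carry the per-condition signs
#' (`+1`, `-1`, or `0` when unselected in that condition) and the backbone
#' score.
#'
#' @param pair_sets named list of [select_signed_pairs()] outputs, one per
#'   condition; the names become the sign-column suffixes.
#' @param backbone scored edge tibble (`gene1`, `gene2`, `score`), e.g. from
#'   [read_backbone()] or [simulate_backbone()].
#' @param min_score backbone retention threshold (strict inequality).
#' @return A `cancer_network`: tibble `gene1`, `gene2`, `score`,
#'   `sign_<condition>`..., in canonical pair order, with attribute
#'   `conditions`. An empty intersection yields an empty network with a
#'   warning.
#' @export
build_network <- function(pair_sets, backbone, min_score = 500) {
  if (length(pair_sets) == 0 || is.null(names(pair_sets)) ||
      any(!nzchar(names(pair_sets)))) {
    stop_input("pair_sets must be a non-empty named list of signed pair sets")
  }
  if (all(vapply(pair_sets, nrow, integer(1)) == 0)) {
    stop_input("all pair sets are empty")
  }
  conditions <- names(pair_sets)

  bb <- canonicalise_pairs(backbone) |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    filter(.data$score > min_score)

  signed <- purrr::imap(pair_sets, function(ps, cond) {
    ps <- canonicalise_pairs(as_tibble(ps))
    if (anyDuplicated(ps[c("gene1", "gene2")])) {
      stop_input(sprintf("conflicting duplicate pairs in the %s signed set", cond))
    }
    out <- ps[c("gene1", "gene2", "sign")]
    names(out)[3] <- paste0("sign_", cond)
    out
  })
  merged <- purrr::reduce(signed, full_join, by = c("gene1", "gene2"))
  edges <- inner_join(bb, merged, by = c("gene1", "gene2"))
  sign_cols <- paste0("sign_", conditions)
  edges <- edges |>
    mutate(across(dplyr::all_of(sign_cols), ~ dplyr::coalesce(.x, 0L))) |>
    arrange(.data$gene1, .data$gene2)
  if (nrow(edges) == 0) {
    warn("signed pairs and backbone do not intersect: network is empty")
  }
  new_cancer_network(edges, conditions)
}

new_cancer_network <- function(edges, conditions) {
  structure(as_tibble(edges),
            conditions = conditions,
            class = c("cancer_network", class(as_tibble(edges))))
}

#' Nodes of a network
#' @param net a `cancer_network`.
#' @return Sorted character vector of gene ids touched by at least one edge.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$gene1, net$gene2)))
}

#' Summary counts for a network
#'
#' Node and edge counts, per-condition signed-edge counts, and a degree
#' distribution summary, recomputed directly from the edge list.
#'
#' @param net a `cancer_network`.
#' @return One-row tibble.
#' @export
network_summary <- function(net) {
  conditions <- attr(net, "conditions") %||%
    sub("^sign_", "", grep("^sign_", names(net), value = TRUE))
  nodes <- network_nodes(net)
  deg <- if (nrow(net) > 0) table(c(net$gene1, net$gene2)) else integer(0)
  out <- tibble(n_nodes = length(nodes), n_edges = nrow(net))
  for (cond in conditions) {
    s <- net[[paste0("sign_", cond)]]
    out[[paste0("n_pos_", cond)]] <- sum(s == 1L)
    out[[paste0("n_neg_", cond)]] <- sum(s == -1L)
  }
  out$mean_degree <- if (length(deg)) mean(deg) else 0
  out$median_degree <- if (length(deg)) median(as.numeric(deg)) else 0
  out$max_degree <- if (length(deg)) max(deg) else 0L
  out
}

#' Write a network edge table
#' @param net a `cancer_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(as_tibble(net), path, progress = FALSE)
  invisible(path)
}
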