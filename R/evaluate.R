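#' Agreement between a computed partition and the planted truth
#'
#' Adjusted Rand index between the computed module assignment and the
#' planted module membership. By default only planted genes (truth label not
#' `"background"`) are compared: background genes that drift into the
#' network through chance signed backbone edges carry no planted module
#' structure, so including them would measure noise-edge incidence rather
#' than module recovery.
#'
#' @param partition a `module_partition`.
#' @param truth output of [planted_truth()].
#' @param planted_only compare planted genes only.
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
partition_recovery_ari <- function(partition, truth, planted_only = TRUE) {
  part <- as_tibble(partition)
  memb <- truth$membership
  if (planted_only) memb <- memb[memb$module != "background", , drop = FALSE]
  common <- intersect(part$gene, memb$gene)
  if (length(common) < 2) stop_input("fewer than 2 genes in common between partition and truth")
  mclust::adjustedRandIndex(
    part$module[match(common, part$gene)],
    memb$module[match(common, memb$gene)])
}

#' Recovery of planted differentially expressed modules
#'
#' Matches each planted DE module to the analyzed computed module with the
#' highest Jaccard overlap of gene membership and asks whether that module
#' was called differentially expressed in the planted condition with the
#' planted direction.
#'
#' @param de_table output of [module_de()].
#' @param partition the `module_partition` the DE table was computed on.
#' @param truth output of [planted_truth()].
#' @return Tibble with one row per planted DE module: `module`, `condition`,
#'   `direction`, `matched_module`, `jaccard`, `call`, `recovered`; the
#'   overall recovery rate is the attribute `recovery_rate`.
#' @export
de_module_recovery <- function(de_table, partition, truth) {
  part <- as_tibble(partition)
  part <- part[part$analyzed, , drop = FALSE]
  computed <- split(part$gene, part$module)
  planted <- split(truth$membership$gene, truth$membership$module)
  if (nrow(truth$de_modules) == 0) stop_input("truth contains no planted DE module")

  rows <- purrr::pmap_dfr(truth$de_modules, function(module, condition, direction) {
    pg <- planted[[module]]
    jac <- vapply(computed, function(cg) {
      length(intersect(pg, cg)) / length(union(pg, cg))
    }, numeric(1))
    if (length(jac) == 0) {
      return(tibble(module = module, condition = condition,
                    direction = direction, matched_module = NA_character_,
                    jaccard = 0, call = NA_character_, recovered = FALSE))
    }
    best <- names(which.max(jac))
    hit <- de_table[de_table$module == best & de_table$condition == condition, ]
    call <- if (nrow(hit) == 1) hit$call else NA_character_
    want <- if (direction > 0) "up" else "down"
    tibble(module = module, condition = condition, direction = direction,
           matched_module = best, jaccard = max(jac), call = call,
           recovered = identical(call, want))
  })
  structure(rows, recovery_rate = mean(rows$recovered))
}

#' Recall of planted discriminating genes in the score ranking
#'
#' Fraction of the planted sign-discordant genes that appear within the top
#' `k` positions of the gene score ranking (default: twice the number of
#' planted genes).
#'
#' @param scores output of [score_genes()].
#' @param truth output of [planted_truth()].
#' @param k ranking depth.
#' @return Recall in `[0, 1]`.
#' @export
discriminating_recall <- function(scores, truth,
                                  k = 2 * length(truth$discriminating_genes)) {
  planted <- truth$discriminating_genes
  if (length(planted) == 0) stop_input("truth contains no planted discriminating gene")
  top <- scores$gene[!is.na(scores$rank) & scores$rank <= k]
  mean(planted %in% top)
}
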