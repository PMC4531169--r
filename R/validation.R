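#' Significance of the overlap between two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between two gene sets drawn from a common universe:
#' `P[X >= overlap]` with `X ~ Hypergeometric(N, |set1|, |set2|)`. Used to
#' ask whether predictions from two dataset choices agree more than chance.
#'
#' @param set1,set2 character vectors of gene ids.
#' @param universe_size size of the common gene universe; must be at least
#'   the size of each set.
#' @return One-row tibble `n1`, `n2`, `overlap`, `universe`, `p`.
#' @export
overlap_significance <- function(set1, set2, universe_size) {
  set1 <- unique(set1); set2 <- unique(set2)
  n1 <- length(set1); n2 <- length(set2)
  if (universe_size < max(n1, n2)) {
    stop_input("universe_size smaller than one of the sets")
  }
  ov <- length(intersect(set1, set2))
  p <- phyper(ov - 1, n1, universe_size - n1, n2, lower.tail = FALSE)
  tibble(n1 = n1, n2 = n2, overlap = ov, universe = universe_size, p = p)
}

#' Per-gene one-way ANOVA across sample groups
#'
#' Tests, for each gene, whether expression differs across the levels of a
#' grouping variable (stage or subtype). Groups with fewer than `min_group`
#' samples are merged into an `"other"` stratum (logged); the classical
#' equal-variance one-way ANOVA F-test is used, p-values are BH-adjusted
#' across the tested genes, and genes with zero variance across all samples
#' get p = 1 by convention.
#'
#' @param expression wide expression tibble.
#' @param annotations tibble `sample`, `stage`, `subtype`.
#' @param grouping `"stage"` or `"subtype"`.
#' @param genes optional subset of genes to test (default: all).
#' @param alpha FDR significance threshold.
#' @param min_group smallest group size kept as its own stratum.
#' @return Tibble `gene`, `f`, `p`, `fdr`, `significant`.
#' @export
anova_by_group <- function(expression, annotations, grouping = c("stage", "subtype"),
                           genes = NULL, alpha = 0.05, min_group = 2L) {
  grouping <- match.arg(grouping)
  m <- expr_matrix(expression)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(m))
    if (length(missing_genes) > 0) {
      stop_input(sprintf("gene(s) not in expression data: %s",
                         paste(utils::head(missing_genes, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  samples <- intersect(colnames(m), annotations$sample)
  if (length(samples) == 0) stop_input("no annotated sample matches the expression data")
  m <- m[, samples, drop = FALSE]
  grp <- annotations[[grouping]][match(samples, annotations$sample)]

  small <- names(which(table(grp) < min_group))
  if (length(small) > 0) {
    inform(sprintf("merged %d small %s group(s) into 'other'", length(small), grouping))
    grp[grp %in% small] <- "other"
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2) stop_input("fewer than 2 groups after merging; nothing to test")

  res <- purrr::map_dfr(rownames(m), function(gene) {
    v <- m[gene, ]
    if (var(v) == 0) return(tibble(gene = gene, f = 0, p = 1))
    a <- anova(lm(v ~ grp))
    tibble(gene = gene, f = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  res |>
    mutate(fdr = p.adjust(.data$p, method = "BH"),
           significant = .data$fdr < alpha)
}

#' Compare a predicted gene set against random draws
#'
#' Asks whether the qualifying genes (e.g. genes separating NSCLC stages)
#' are overrepresented among the predicted genes relative to random same-size
#' gene draws from the universe. Reports the empirical p (fraction of
#' `n_draws` random sets whose overlap with the qualifying set reaches the
#' observed overlap) alongside the exact hypergeometric upper-tail p.
#'
#' @param predicted,qualifying character vectors, subsets of `universe`.
#' @param universe character vector of candidate genes.
#' @param n_draws number of random draws; fewer than 100 triggers a warning.
#' @param seed integer seed for the draws.
#' @return One-row tibble `observed`, `expected`, `empirical_p`, `hyper_p`,
#'   `n_draws`.
#' @export
proportion_vs_random <- function(predicted, qualifying, universe,
                                 n_draws = 1000L, seed = 1L) {
  universe <- unique(universe)
  predicted <- unique(predicted); qualifying <- unique(qualifying)
  if (length(setdiff(predicted, universe)) > 0 ||
      length(setdiff(qualifying, universe)) > 0) {
    stop_input("predicted and qualifying genes must lie in the universe")
  }
  if (n_draws < 100) warn("fewer than 100 random draws: empirical p is unstable")
  observed <- length(intersect(predicted, qualifying))
  k <- length(predicted)
  hits <- withr::with_seed(derive_seed(seed, "proportion_vs_random"), {
    vapply(seq_len(n_draws), function(i) {
      length(intersect(sample(universe, k), qualifying))
    }, numeric(1))
  })
  hyper <- phyper(observed - 1, length(qualifying),
                  length(universe) - length(qualifying), k, lower.tail = FALSE)
  tibble(observed = observed,
         expected = k * length(qualifying) / length(universe),
         empirical_p = mean(hits >= observed),
         hyper_p = hyper,
         n_draws = as.integer(n_draws))
}
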