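#' All-pairs Pearson correlation within one condition
#'
#' Computes the Pearson correlation coefficient (PCC) of every unordered gene
#' pair across the samples of one condition. Genes with zero variance are
#' removed first (their PCC is undefined) with a warning. Computation can be
#' chunked into row blocks so memory stays bounded for large gene universes;
#' results are identical to the whole-matrix computation.
#'
#' @param expression wide expression tibble (`gene` + sample columns).
#' @param block_size optional number of genes per block; `NULL` computes the
#'   full correlation matrix at once.
#' @return Tibble `gene1`, `gene2`, `pcc` with one row per unordered pair, in
#'   canonical pair order.
#' @export
pairwise_pcc <- function(expression, block_size = NULL) {
  m <- expr_matrix(expression)
  if (ncol(m) < 3) stop_input("at least 3 samples are required to compute correlations")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("removed %d zero-variance gene(s) before correlation", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  g <- nrow(m)
  if (g < 2) stop_input("need at least 2 genes with nonzero variance")
  genes <- rownames(m)

  if (is.null(block_size) || block_size >= g) {
    cc <- cor(t(m))
    idx <- which(upper.tri(cc), arr.ind = TRUE)
    out <- tibble(gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
                  pcc = cc[idx])
  } else {
    blocks <- split(seq_len(g), ceiling(seq_len(g) / block_size))
    out <- purrr::map_dfr(blocks, function(rows) {
      cc <- cor(t(m[rows, , drop = FALSE]), t(m))
      idx <- which(outer(rows, seq_len(g), `<`), arr.ind = TRUE)
      tibble(gene1 = genes[rows[idx[, 1]]], gene2 = genes[idx[, 2]],
             pcc = cc[idx])
    })
  }
  arrange(canonicalise_pairs(out), .data$gene1, .data$gene2)
}

#' Select signed coexpression pairs by correlation quantile
#'
#' Tags the top `top_frac` of the realised PCC distribution as positively
#' coexpressed (`sign = +1`) and the bottom `bottom_frac` as negatively
#' coexpressed (`sign = -1`); all other pairs are unselected. Cutoffs are the
#' `1 - top_frac` and `bottom_frac` quantiles of the PCC values over all
#' evaluated pairs, and pairs tied at a cutoff are all included, so selection
#' does not depend on enumeration order. A degenerate distribution where the
#' two cutoffs coincide (all PCCs equal) yields an empty selection with a
#' warning.
#'
#' @param pcc_pairs output of [pairwise_pcc()].
#' @param top_frac,bottom_frac selection fractions, each in (0, 0.5).
#' @param condition optional condition label added as a column.
#' @return Tibble `gene1`, `gene2`, `pcc`, `sign` (and `condition` when
#'   given), with attributes `cutoff_low` and `cutoff_high`.
#' @export
select_signed_pairs <- function(pcc_pairs, top_frac = 0.01,
                                bottom_frac = 0.01, condition = NULL) {
  if (top_frac <= 0 || top_frac >= 0.5 || bottom_frac <= 0 || bottom_frac >= 0.5) {
    stop_config("top_frac and bottom_frac must lie in (0, 0.5)")
  }
  n <- nrow(pcc_pairs)
  if (n < 1 / top_frac) {
    stop_input(sprintf("too few pairs (%d) for a %.3g selection fraction", n, top_frac))
  }
  hi <- quantile(pcc_pairs$pcc, 1 - top_frac, names = FALSE)
  lo <- quantile(pcc_pairs$pcc, bottom_frac, names = FALSE)
  if (hi <= lo) {
    warn("degenerate PCC distribution: high and low cutoffs coincide; returning empty selection")
    out <- pcc_pairs[0, ]
    out$sign <- integer(0)
  } else {
    out <- pcc_pairs |>
      mutate(sign = case_when(.data$pcc >= hi ~ 1L,
                              .data$pcc <= lo ~ -1L,
                              TRUE ~ 0L)) |>
      filter(.data$sign != 0L)
  }
  if (!is.null(condition)) out$condition <- condition
  attr(out, "cutoff_low") <- lo
  attr(out, "cutoff_high") <- hi
  out
}
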