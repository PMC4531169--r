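# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops and closed forms only.

# Two-pass Pearson correlation for a single gene pair.
oracle_pcc <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# ROC AUC by explicit pair counting, ties worth 0.5.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Hypergeometric upper tail P[X >= k] by direct summation.
# N genes, K in the set, n drawn.
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Newman-Girvan modularity by looping over modules.
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  q <- 0
  for (mod in unique(membership)) {
    genes <- names(membership)[membership == mod]
    e_c <- sum(edges$gene1 %in% genes & edges$gene2 %in% genes)
    d_c <- sum(edges$gene1 %in% genes) + sum(edges$gene2 %in% genes)
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Gene discriminating scores by direct evaluation of the definition:
# for each gene, enumerate its module-internal edges, average |sA - sB|,
# multiply by (auc - 0.5) of its module.
oracle_gene_scores <- function(edges, membership, auc_by_module) {
  genes <- names(membership)
  out <- numeric(length(genes))
  names(out) <- genes
  for (g in genes) {
    mod <- membership[[g]]
    diffs <- c()
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      other <- if (e$gene1 == g) e$gene2 else if (e$gene2 == g) e$gene1 else NA
      if (is.na(other)) next
      if (!identical(membership[[other]], mod)) next
      diffs <- c(diffs, abs(e$sign_cancerA - e$sign_cancerB))
    }
    md <- if (length(diffs)) mean(diffs) else 0
    out[g] <- (auc_by_module[[mod]] - 0.5) * md
  }
  out
}
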