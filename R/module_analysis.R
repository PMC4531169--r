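#' Per-sample median module expression
#'
#' Represents a module in a sample by the median expression of its member
#' genes in that sample (even member counts use the mean of the two central
#' values, the usual sample-median convention). Members absent from the
#' dataset are ignored (logged when partial); modules with no member present
#' are skipped with a warning. Only modules flagged `analyzed` in the
#' partition are summarised unless `analyzed_only = FALSE`.
#'
#' @param expression wide expression tibble for one condition.
#' @param partition a `module_partition`.
#' @param condition condition label recorded in the output.
#' @param analyzed_only restrict to modules of admissible size.
#' @return Long tibble `module`, `condition`, `sample`, `value`.
#' @export
module_expression <- function(expression, partition, condition,
                              analyzed_only = TRUE) {
  m <- expr_matrix(expression)
  part <- as_tibble(partition)
  if (analyzed_only) part <- part[part$analyzed, , drop = FALSE]
  mods <- unique(part$module)
  missing_members <- sum(!(part$gene %in% rownames(m)))
  if (missing_members > 0) {
    inform(sprintf("%d module member(s) absent from the %s expression data",
                   missing_members, condition))
  }
  out <- purrr::map_dfr(mods, function(mod) {
    members <- intersect(part$gene[part$module == mod], rownames(m))
    if (length(members) == 0) {
      warn(sprintf("module %s has no member in the %s expression data; skipped",
                   mod, condition))
      return(tibble(module = character(), condition = character(),
                    sample = character(), value = numeric()))
    }
    vals <- apply(m[members, , drop = FALSE], 2, median)
    tibble(module = mod, condition = condition,
           sample = names(vals), value = unname(vals))
  })
  out
}

#' Module expression across several conditions
#' @param expression_list named list of wide expression tibbles.
#' @param partition a `module_partition`.
#' @param analyzed_only restrict to modules of admissible size.
#' @return Long tibble as in [module_expression()], stacked over conditions.
#' @export
module_expression_all <- function(expression_list, partition,
                                  analyzed_only = TRUE) {
  purrr::imap_dfr(expression_list, function(ex, cond) {
    module_expression(ex, partition, cond, analyzed_only = analyzed_only)
  })
}

# Welch t-test with the degenerate-input convention: both groups constant
# with equal means -> p = 1 (no evidence), constant with different means ->
# p = 0.
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_input("t-test requires at least 2 samples per group")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    d <- mean(x) - mean(y)
    if (isTRUE(all.equal(d, 0))) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(d) * Inf, p.value = 0))
  }
  tt <- t.test(x, y)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Module differential expression against normal tissue
#'
#' For each module and each cancer condition, compares the module's
#' per-sample expression values against the normal samples with a Welch
#' two-sample t-test. The log fold change is the mean difference
#' (cancer minus normal) on the log2 input scale. P-values are
#' Benjamini-Hochberg adjusted across all modules within each cancer
#' condition, and a module is called `up` (`down`) when the adjusted p-value
#' is below `alpha` and the fold change exceeds `lfc_min` (falls below
#' `-lfc_min`); otherwise `ns`.
#'
#' @param module_expr long module-expression tibble from
#'   [module_expression_all()] covering the normal and cancer conditions.
#' @param normal name of the normal condition.
#' @param alpha FDR significance threshold.
#' @param lfc_min minimum absolute log2 fold change.
#' @return Tibble `module`, `condition`, `t`, `p`, `fdr`, `lfc`, `call`.
#' @export
module_de <- function(module_expr, normal = "normal", alpha = 0.01,
                      lfc_min = 2) {
  conds <- unique(module_expr$condition)
  if (!normal %in% conds) stop_input(sprintf("no '%s' condition in module expression", normal))
  cancers <- setdiff(conds, normal)
  if (length(cancers) == 0) stop_input("no cancer condition to test")
  norm_tbl <- module_expr[module_expr$condition == normal, ]

  res <- purrr::map_dfr(cancers, function(cc) {
    cc_tbl <- module_expr[module_expr$condition == cc, ]
    mods <- intersect(unique(cc_tbl$module), unique(norm_tbl$module))
    purrr::map_dfr(mods, function(mod) {
      x <- cc_tbl$value[cc_tbl$module == mod]
      y <- norm_tbl$value[norm_tbl$module == mod]
      tt <- welch_t(x, y)
      tibble(module = mod, condition = cc, t = tt$statistic, p = tt$p.value,
             lfc = mean(x) - mean(y))
    })
  })
  res |>
    group_by(.data$condition) |>
    mutate(fdr = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(call = case_when(
      .data$fdr < alpha & .data$lfc > lfc_min ~ "up",
      .data$fdr < alpha & .data$lfc < -lfc_min ~ "down",
      TRUE ~ "ns")) |>
    relocate("fdr", .after = "p")
}

#' Cross-subtype DE category per module
#'
#' Combines the per-condition DE calls into one exhaustive category per
#' module. `mixed` covers modules regulated in opposite directions in the
#' two subtypes, a combination the usual up/down labelling leaves implicit.
#'
#' @param de_table output of [module_de()] for exactly two cancer conditions.
#' @param cancer_a,cancer_b names of the two cancer conditions (A is the
#'   positive class throughout the package).
#' @return Tibble `module`, `call_a`, `call_b`, `category` with category in
#'   `A_only_up`, `A_only_down`, `B_only_up`, `B_only_down`, `both_up`,
#'   `both_down`, `mixed`, `ns`.
#' @export
categorize_modules <- function(de_table, cancer_a = "cancerA",
                               cancer_b = "cancerB") {
  wide <- de_table |>
    select("module", "condition", "call") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "call")
  for (cc in c(cancer_a, cancer_b)) {
    if (!cc %in% names(wide)) stop_input(sprintf("no DE calls for condition '%s'", cc))
  }
  wide |>
    rename(call_a = dplyr::all_of(cancer_a), call_b = dplyr::all_of(cancer_b)) |>
    mutate(category = case_when(
      .data$call_a == "up" & .data$call_b == "up" ~ "both_up",
      .data$call_a == "down" & .data$call_b == "down" ~ "both_down",
      .data$call_a == "up" & .data$call_b == "down" ~ "mixed",
      .data$call_a == "down" & .data$call_b == "up" ~ "mixed",
      .data$call_a == "up" ~ "A_only_up",
      .data$call_a == "down" ~ "A_only_down",
      .data$call_b == "up" ~ "B_only_up",
      .data$call_b == "down" ~ "B_only_down",
      TRUE ~ "ns"))
}

#' Rank-based ROC AUC (Mann-Whitney statistic)
#'
#' AUC for classifying the positive-class values `x` against the
#' negative-class values `y`, computed as the Mann-Whitney U statistic
#' normalised by `length(x) * length(y)`; tied value pairs count 0.5. Equals
#' the probability that a random positive sample exceeds a random negative
#' one; two identical constant groups give exactly 0.5.
#'
#' @param x positive-class values.
#' @param y negative-class values.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop_input("AUC requires at least one value per class")
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' Module subtype-specificity by ROC AUC
#'
#' For each module, uses its per-sample expression values to classify the
#' `positive` cancer condition against the `negative` one and reports the
#' ROC AUC. AUC near 1 means the module is upregulated in the positive
#' subtype, near 0 downregulated, and 0.5 is random. Modules with
#' `auc > auc_hi` or `auc < auc_lo` are flagged `extreme` — these have
#' distinct expression patterns between the subtypes and feed gene scoring.
#'
#' @param module_expr long module-expression tibble covering both cancer
#'   conditions.
#' @param positive,negative condition names; the positive class fixes the
#'   AUC orientation.
#' @param auc_hi,auc_lo extremeness thresholds.
#' @param modules optional module subset (e.g. the DE modules).
#' @return Tibble `module`, `auc`, `specificity` (`|auc - 0.5|`),
#'   `direction`, `extreme`.
#' @export
specificity_auc <- function(module_expr, positive = "cancerA",
                            negative = "cancerB", auc_hi = 0.9,
                            auc_lo = 0.1, modules = NULL) {
  pos <- module_expr[module_expr$condition == positive, ]
  neg <- module_expr[module_expr$condition == negative, ]
  mods <- intersect(unique(pos$module), unique(neg$module))
  if (!is.null(modules)) mods <- intersect(mods, modules)
  empty <- tibble(module = character(), auc = numeric(),
                  specificity = numeric(), direction = character(),
                  extreme = logical())
  if (length(mods) == 0) return(empty)
  purrr::map_dfr(mods, function(mod) {
    a <- auc_mann_whitney(pos$value[pos$module == mod],
                          neg$value[neg$module == mod])
    tibble(module = mod, auc = a, specificity = abs(a - 0.5),
           direction = if (a > 0.5) paste0("up_in_", positive)
                       else paste0("up_in_", negative),
           extreme = a > auc_hi | a < auc_lo)
  })
}
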