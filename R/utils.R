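#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join full_join bind_rows distinct across n rename
#'   row_number desc if_else case_when pull relocate
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor median quantile t.test p.adjust fisher.test phyper
#'   lm anova rnorm sd var setNames
#' @importFrom utils head
NULL

# Canonical unordered pair representation: gene1 is the lexicographically
# smaller id. All edge tables in the package use this convention.
canonicalise_pairs <- function(df) {
  g1 <- pmin(df$gene1, df$gene2)
  g2 <- pmax(df$gene1, df$gene2)
  df$gene1 <- g1
  df$gene2 <- g2
  df
}

# Deterministic sub-stream seeds: one global integer seed, per-purpose keys.
# Kept below 2^31 - 1 so the result is always a valid R integer.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646L + 1)
}

stop_format <- function(msg, line = NULL, call = rlang::caller_env()) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  abort(msg, class = "discordnet_format_error", call = call)
}

stop_input <- function(msg, call = rlang::caller_env()) {
  abort(msg, class = "discordnet_input_error", call = call)
}

stop_config <- function(msg, call = rlang::caller_env()) {
  abort(msg, class = "discordnet_config_error", call = call)
}

# Wide expression tibble (gene + one column per sample) -> numeric matrix.
expr_matrix <- function(expression) {
  if (!is.data.frame(expression) || !"gene" %in% names(expression)) {
    stop_input("expression must be a data frame with a `gene` column")
  }
  genes <- as.character(expression$gene)
  if (anyDuplicated(genes)) stop_input("duplicate gene ids in expression data")
  m <- as.matrix(expression[setdiff(names(expression), "gene")])
  if (!is.numeric(m)) stop_input("expression values must be numeric")
  if (anyNA(m)) stop_input("expression data contains missing values")
  rownames(m) <- genes
  m
}

matrix_to_expr <- function(m) {
  out <- as_tibble(m, rownames = "gene")
  out
}
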