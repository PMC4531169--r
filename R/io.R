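#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids. Genes
#' with any missing or non-numeric value are dropped with a warning;
#' duplicated gene ids are collapsed by their mean, also with a warning.
#' Values are assumed to be normalised, log2-scale expression.
#'
#' @param path file path.
#' @param condition optional condition label recorded as the `condition`
#'   attribute of the result.
#' @return Wide tibble: `gene` plus one numeric column per sample.
#' @export
read_expression <- function(path, condition = NULL) {
  if (!file.exists(path)) stop_input(sprintf("expression file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !nzchar(lines[1])) {
    stop_format(sprintf("empty expression file: %s", path), line = 1)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop_format(sprintf("malformed expression header in %s: need a gene column plus at least one sample", path), line = 1)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  names(raw)[1] <- "gene"
  samples <- setdiff(names(raw), "gene")
  if (anyDuplicated(samples)) stop_format(sprintf("duplicate sample ids in %s", path), line = 1)

  vals <- suppressWarnings(
    vapply(raw[samples], function(x) as.numeric(x), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  bad <- rowSums(is.na(vals)) > 0
  if (any(bad)) {
    warn(sprintf("dropped %d gene(s) with missing or non-numeric values in %s",
                 sum(bad), path))
  }
  genes <- raw$gene[!bad]
  vals <- vals[!bad, , drop = FALSE]
  if (anyDuplicated(genes)) {
    n_dup <- length(genes) - length(unique(genes))
    warn(sprintf("collapsed %d duplicated gene id(s) by mean in %s", n_dup, path))
    vals <- rowsum(vals, group = genes, reorder = FALSE)
    counts <- as.vector(table(factor(genes, levels = rownames(vals))))
    vals <- vals / counts
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  out <- matrix_to_expr(vals)
  if (!is.null(condition)) attr(out, "condition") <- condition
  out
}

#' Write an expression matrix
#'
#' @param expression wide expression tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Read a scored functional-association edge list
#'
#' Parses a 3-column whitespace-delimited edge list (`gene1 gene2 score`,
#' STRING detailed-links dialect; an optional header line is detected and
#' skipped). Scores must be integers in 0-1000. Self-edges are dropped,
#' duplicate unordered pairs keep the maximum score, and only pairs with
#' score strictly greater than `min_score` are retained.
#'
#' @param path file path.
#' @param min_score retention threshold; strictly-greater comparison.
#' @return Tibble `gene1`, `gene2`, `score` in canonical pair order.
#' @export
read_backbone <- function(path, min_score = 500) {
  if (!file.exists(path)) stop_input(sprintf("backbone file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format(sprintf("empty backbone file: %s", path), line = 1)
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) start <- 2L  # header
  if (start > length(fields)) stop_format(sprintf("backbone file %s has a header but no edges", path), line = 2)
  parsed <- purrr::map2_dfr(fields[start:length(fields)],
                            seq.int(start, length(fields)), function(f, ln) {
    if (length(f) != 3) {
      stop_format(sprintf("backbone line does not have 3 fields in %s", path), line = ln)
    }
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || s != round(s)) {
      stop_format(sprintf("non-integer backbone score '%s' in %s", f[3], path), line = ln)
    }
    tibble(gene1 = f[1], gene2 = f[2], score = as.integer(s))
  })
  parsed <- canonicalise_pairs(parsed)
  parsed <- parsed[parsed$gene1 != parsed$gene2, , drop = FALSE]
  parsed <- parsed |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(score = max(.data$score), .groups = "drop")
  parsed |>
    filter(.data$score > min_score) |>
    arrange(.data$gene1, .data$gene2)
}

#' Write a scored edge list
#' @param backbone tibble `gene1`, `gene2`, `score`.
#' @param path output file path.
#' @param header write the STRING-style header line.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(backbone, path, header = TRUE) {
  lines <- sprintf("%s %s %d", backbone$gene1, backbone$gene2, backbone$score)
  if (header) lines <- c("protein1 protein2 combined_score", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then one or more tab-separated member
#' gene ids. Repeated members within a set are stored once.
#'
#' @param path file path.
#' @return Long tibble `set`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format(sprintf("empty GMT file: %s", path), line = 1)
  out <- purrr::map2_dfr(lines, seq_along(lines), function(l, ln) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3 || length(members) == 0) {
      stop_format(sprintf("GMT line needs a name, description and at least one member in %s", path), line = ln)
    }
    tibble(set = f[1], description = f[2], gene = members)
  })
  set_names <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                      character(1), USE.NAMES = FALSE)
  if (anyDuplicated(set_names)) {
    stop_format(sprintf("duplicate gene-set names in %s", path))
  }
  out
}

#' Write a gene-set collection as GMT
#' @param gene_sets long tibble `set`, `description`, `gene`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  by_set <- split(gene_sets, factor(gene_sets$set, levels = unique(gene_sets$set)))
  lines <- vapply(by_set, function(d) {
    paste(c(d$set[1], d$description[1], d$gene), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a sample annotation table
#'
#' Tab-delimited with columns `sample`, `stage`, `subtype`.
#' @param path file path.
#' @return `read_annotations()`: tibble; `write_annotations()`: `path`,
#'   invisibly.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("annotation file not found: %s", path))
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("sample", "stage", "subtype")
  if (!all(need %in% names(out))) {
    stop_format(sprintf("annotation file %s must have columns sample, stage, subtype", path), line = 1)
  }
  out[need]
}

#' @rdname read_annotations
#' @param annotations tibble with columns `sample`, `stage`, `subtype`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
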