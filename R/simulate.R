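#' Specification of a planted synthetic study
#'
#' Describes a three-condition expression study (normal tissue plus two cancer
#' subtypes, `cancerA` and `cancerB`) with planted gene modules. Genes inside
#' a module share a latent factor so that their pairwise Pearson correlation
#' is `within_module_corr` in expectation; background genes are independent
#' (or weakly coupled through a global factor when `background_corr > 0`).
#' Differential expression is planted as a mean shift of `de_shift` (log2
#' units) in one cancer condition per module, cycling through up-in-A,
#' down-in-A, up-in-B, down-in-B. Coexpression sign discordance between the
#' two cancer subtypes is planted by negating the latent-factor loading of a
#' subset of each module's genes in `cancerB` only, so that their
#' within-module correlations change sign between the subtypes; the subset
#' size is chosen so the fraction of discordant within-module edges is as
#' close as possible to `flip_fraction`.
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted modules.
#' @param module_size genes per planted module; `n_modules * module_size`
#'   must not exceed `n_genes`.
#' @param samples_per_condition named integer vector with entries `normal`,
#'   `cancerA`, `cancerB`.
#' @param within_module_corr expected pairwise correlation inside a planted
#'   module, in `[0, 1]`; must exceed `background_corr`.
#' @param background_corr expected correlation between background genes.
#' @param de_shift planted mean shift (log2 expression units) for
#'   differentially expressed modules. `0` disables DE planting.
#' @param flip_fraction target fraction of within-module edges made
#'   sign-discordant between `cancerA` and `cancerB`, in `[0, 1]`. Requires
#'   `de_shift > 0` (discriminating genes live in DE modules).
#' @param backbone_score_range integer interval within `[0, 1000]` for the
#'   association scores of planted backbone edges.
#' @param seed single integer; every stream of randomness in the generator is
#'   derived deterministically from it.
#'
#' @return An object of class `planted_spec` (a validated list).
#' @export
#' @examples
#' spec <- planted_spec(n_genes = 60, n_modules = 2, module_size = 10,
#'                      samples_per_condition = c(normal = 20, cancerA = 20,
#'                                                cancerB = 20), seed = 1)
#' truth <- planted_truth(spec)
#' table(truth$membership$module)
planted_spec <- function(n_genes = 500L,
                         n_modules = 4L,
                         module_size = 25L,
                         samples_per_condition = c(normal = 50L, cancerA = 50L,
                                                   cancerB = 50L),
                         within_module_corr = 0.9,
                         background_corr = 0,
                         de_shift = 3,
                         flip_fraction = 0.5,
                         backbone_score_range = c(600L, 900L),
                         seed = 1L) {
  cond <- c("normal", "cancerA", "cancerB")
  if (!all(cond %in% names(samples_per_condition))) {
    stop_config("samples_per_condition must name normal, cancerA and cancerB")
  }
  samples_per_condition <- as.integer(samples_per_condition[cond])
  names(samples_per_condition) <- cond
  if (n_modules * module_size > n_genes) {
    stop_config("planted modules overflow the gene universe: n_modules * module_size > n_genes")
  }
  if (within_module_corr <= background_corr) {
    stop_config("within_module_corr must exceed background_corr")
  }
  if (within_module_corr < 0 || within_module_corr > 1 ||
      background_corr < 0 || background_corr > 1) {
    stop_config("correlations must lie in [0, 1]")
  }
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop_config("flip_fraction must lie in [0, 1]")
  }
  if (flip_fraction > 0 && de_shift == 0) {
    stop_config("flip_fraction > 0 requires de_shift > 0: sign-discordant edges are planted inside differentially expressed modules")
  }
  if (length(backbone_score_range) != 2 ||
      backbone_score_range[1] > backbone_score_range[2] ||
      backbone_score_range[1] < 0 || backbone_score_range[2] > 1000) {
    stop_config("backbone_score_range must be an increasing integer interval within [0, 1000]")
  }
  spec <- structure(
    list(n_genes = as.integer(n_genes),
         n_modules = as.integer(n_modules),
         module_size = as.integer(module_size),
         samples_per_condition = samples_per_condition,
         within_module_corr = within_module_corr,
         background_corr = background_corr,
         de_shift = de_shift,
         flip_fraction = flip_fraction,
         backbone_score_range = as.integer(backbone_score_range),
         seed = as.integer(seed)),
    class = "planted_spec")
  spec
}

#' @export
print.planted_spec <- function(x, ...) {
  cat("<planted_spec>\n")
  cat(sprintf("  %d genes, %d modules of %d genes\n",
              x$n_genes, x$n_modules, x$module_size))
  cat(sprintf("  samples: normal=%d cancerA=%d cancerB=%d\n",
              x$samples_per_condition[["normal"]],
              x$samples_per_condition[["cancerA"]],
              x$samples_per_condition[["cancerB"]]))
  cat(sprintf("  within corr %.2f / background %.2f, de_shift %.2f, flip %.2f, seed %d\n",
              x$within_module_corr, x$background_corr, x$de_shift,
              x$flip_fraction, x$seed))
  invisible(x)
}

spec_gene_ids <- function(spec) sprintf("g%04d", seq_len(spec$n_genes))

# Number of genes per module whose loading is negated in cancerB. Chosen so
# the realised fraction of discordant within-module edges k(m-k)/C(m,2) is
# closest to the requested flip_fraction.
flip_count <- function(module_size, flip_fraction) {
  if (flip_fraction == 0) return(0L)
  m <- module_size
  ks <- 0:floor(m / 2)
  realised <- ks * (m - ks) / choose(m, 2)
  ks[which.min(abs(realised - flip_fraction))]
}

#' Ground truth of a planted specification
#'
#' Deterministically derives the planted structure implied by a
#' [planted_spec()]: gene-to-module membership (background genes carry the
#' label `"background"`), which modules are differentially expressed in which
#' cancer condition and direction, and which genes carry sign-discordant
#' coexpression edges (the planted discriminating genes, always a subset of
#' the DE modules' genes).
#'
#' @param spec a [planted_spec()].
#' @return A list with elements `membership` (tibble: gene, module),
#'   `de_modules` (tibble: module, condition, direction), and
#'   `discriminating_genes` (character vector).
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  genes <- spec_gene_ids(spec)
  module <- rep("background", spec$n_genes)
  idx <- seq_len(spec$n_modules * spec$module_size)
  module[idx] <- rep(sprintf("planted_%02d", seq_len(spec$n_modules)),
                     each = spec$module_size)
  membership <- tibble(gene = genes, module = module)

  de_modules <- tibble(module = character(), condition = character(),
                       direction = integer())
  if (spec$de_shift > 0 && spec$n_modules > 0) {
    pattern <- tibble(
      condition = rep(c("cancerA", "cancerA", "cancerB", "cancerB"),
                      length.out = spec$n_modules),
      direction = rep(c(1L, -1L, 1L, -1L), length.out = spec$n_modules))
    de_modules <- dplyr::bind_cols(
      tibble(module = sprintf("planted_%02d", seq_len(spec$n_modules))),
      pattern)
  }

  k <- flip_count(spec$module_size, spec$flip_fraction)
  discriminating <- character(0)
  if (k > 0) {
    # first k genes of each planted module carry the negated loading
    discriminating <- unlist(lapply(seq_len(spec$n_modules), function(i) {
      start <- (i - 1) * spec$module_size
      genes[start + seq_len(k)]
    }))
  }
  list(membership = membership,
       de_modules = de_modules,
       discriminating_genes = discriminating)
}

#' Simulate an expression matrix for one condition
#'
#' Draws a genes-by-samples log2-scale expression matrix under the latent
#' factor model of [planted_spec()]: gene `i` in module `k` has value
#' `baseline_i + s * sqrt(rho) * f_k + sqrt(1 - rho) * eps + shift`, where
#' `f_k` is the module's shared standard-normal factor per sample, `rho` is
#' `within_module_corr`, `s` is `-1` in `cancerB` for planted discriminating
#' genes and `+1` otherwise, and `shift` is `+/- de_shift` for modules planted
#' as differentially expressed in this condition. Per-gene baselines are
#' shared across conditions. Every random stream derives from `spec$seed`, so
#' repeated calls are identical.
#'
#' @param spec a [planted_spec()].
#' @param condition one of `"normal"`, `"cancerA"`, `"cancerB"`.
#' @return A wide tibble: `gene` column plus one numeric column per sample
#'   (sample ids `<condition>_s<k>`).
#' @export
simulate_expression <- function(spec, condition) {
  stopifnot(inherits(spec, "planted_spec"))
  condition <- match.arg(condition, names(spec$samples_per_condition))
  truth <- planted_truth(spec)
  n <- spec$samples_per_condition[[condition]]
  genes <- spec_gene_ids(spec)
  g <- spec$n_genes

  baseline <- withr::with_seed(derive_seed(spec$seed, "baseline"),
                               rnorm(g, mean = 7, sd = 1))

  withr::local_seed(derive_seed(spec$seed, paste0("expr_", condition)))
  rho <- spec$within_module_corr
  bg_rho <- spec$background_corr

  x <- matrix(rnorm(g * n), nrow = g)          # independent noise, sd 1
  noise_scale <- rep(sqrt(1 - bg_rho), g)
  loading <- rep(if (bg_rho > 0) sqrt(bg_rho) else 0, g)
  factor_id <- rep(0L, g)                      # 0 = global background factor

  planted <- truth$membership$module != "background"
  factor_id[planted] <- as.integer(factor(truth$membership$module[planted]))
  loading[planted] <- sqrt(rho)
  noise_scale[planted] <- sqrt(1 - rho)

  sign_vec <- rep(1, g)
  if (condition == "cancerB" && length(truth$discriminating_genes) > 0) {
    sign_vec[genes %in% truth$discriminating_genes] <- -1
  }

  factors <- matrix(rnorm((spec$n_modules + 1) * n), nrow = spec$n_modules + 1)
  shift <- rep(0, g)
  if (nrow(truth$de_modules) > 0) {
    de_here <- truth$de_modules[truth$de_modules$condition == condition, ]
    if (nrow(de_here) > 0) {
      shift_by_module <- setNames(de_here$direction * spec$de_shift,
                                  de_here$module)
      hit <- truth$membership$module %in% names(shift_by_module)
      shift[hit] <- shift_by_module[truth$membership$module[hit]]
    }
  }

  vals <- baseline + shift +
    (sign_vec * loading) * factors[factor_id + 1L, , drop = FALSE] +
    noise_scale * x
  colnames(vals) <- sprintf("%s_s%03d", condition, seq_len(n))
  rownames(vals) <- genes
  matrix_to_expr(vals)
}

#' Simulate a scored functional-association backbone
#'
#' Emulates a STRING-style combined-score edge list. Every within-module gene
#' pair receives a score drawn uniformly from `spec$backbone_score_range`
#' (above the default retention threshold of 500 by construction), and
#' `n_background` random non-planted pairs receive scores drawn from
#' `background_score_range` (spanning the full 0-1000 scale by default, so a
#' retention filter removes roughly half of them). No self-edges; each
#' unordered pair appears exactly once.
#'
#' @param spec a [planted_spec()].
#' @param truth output of [planted_truth()] for the same spec.
#' @param n_background number of random background edges.
#' @param background_score_range integer interval for background-edge scores.
#' @return Tibble with columns `gene1`, `gene2`, `score` (integer 0-1000),
#'   pairs in canonical order.
#' @export
simulate_backbone <- function(spec, truth = planted_truth(spec),
                              n_background = 500L,
                              background_score_range = c(0L, 1000L)) {
  stopifnot(inherits(spec, "planted_spec"))
  withr::local_seed(derive_seed(spec$seed, "backbone"))
  memb <- truth$membership
  planted_mods <- setdiff(unique(memb$module), "background")
  planted_pairs <- purrr::map_dfr(planted_mods, function(m) {
    gs <- sort(memb$gene[memb$module == m])
    if (length(gs) < 2) return(tibble(gene1 = character(), gene2 = character()))
    cmb <- utils::combn(gs, 2)
    tibble(gene1 = cmb[1, ], gene2 = cmb[2, ])
  })
  lo <- spec$backbone_score_range[1]
  hi <- spec$backbone_score_range[2]
  planted_pairs$score <- sample(lo:hi, nrow(planted_pairs), replace = TRUE)

  bg <- tibble(gene1 = character(), gene2 = character(), score = integer())
  if (n_background > 0) {
    genes <- spec_gene_ids(spec)
    max_bg <- choose(length(genes), 2) - nrow(planted_pairs)
    if (n_background > max_bg) {
      stop_config(sprintf("n_background (%d) exceeds the %d available non-planted pairs",
                          n_background, max_bg))
    }
    seen <- paste(planted_pairs$gene1, planted_pairs$gene2)
    acc <- tibble(gene1 = character(), gene2 = character())
    while (nrow(acc) < n_background) {
      need <- n_background - nrow(acc)
      a <- sample(genes, 2L * need + 10L, replace = TRUE)
      b <- sample(genes, 2L * need + 10L, replace = TRUE)
      keep <- a != b
      cand <- tibble(gene1 = pmin(a[keep], b[keep]),
                     gene2 = pmax(a[keep], b[keep]))
      key <- paste(cand$gene1, cand$gene2)
      cand <- cand[!(key %in% seen) &
                     !(key %in% paste(acc$gene1, acc$gene2)) &
                     !duplicated(key), , drop = FALSE]
      acc <- bind_rows(acc, utils::head(cand, need))
    }
    bg <- acc
    bg$score <- sample(background_score_range[1]:background_score_range[2],
                       nrow(bg), replace = TRUE)
  }
  out <- bind_rows(planted_pairs, bg)
  arrange(canonicalise_pairs(out), .data$gene1, .data$gene2)
}

#' Simulate a gene-set collection around the planted truth
#'
#' One gene set per planted module (exact membership) plus `n_decoys` random
#' sets drawn from the full gene universe, for exercising enrichment analysis.
#'
#' @param truth output of [planted_truth()].
#' @param n_decoys number of random decoy sets.
#' @param decoy_size integer range for decoy set sizes.
#' @param seed integer seed.
#' @return Long tibble with columns `set`, `description`, `gene`.
#' @export
simulate_gene_sets <- function(truth, n_decoys = 20L,
                               decoy_size = c(10L, 40L), seed = 1L) {
  withr::local_seed(derive_seed(seed, "gene_sets"))
  memb <- truth$membership
  planted_mods <- setdiff(unique(memb$module), "background")
  planted <- purrr::map_dfr(planted_mods, function(m) {
    tibble(set = paste0("SET_", toupper(m)),
           description = paste("planted module", m),
           gene = sort(memb$gene[memb$module == m]))
  })
  decoys <- tibble(set = character(), description = character(),
                   gene = character())
  if (n_decoys > 0) {
    decoys <- purrr::map_dfr(seq_len(n_decoys), function(i) {
      sz <- sample(decoy_size[1]:decoy_size[2], 1)
      tibble(set = sprintf("SET_DECOY_%02d", i),
             description = "random decoy set",
             gene = sort(sample(memb$gene, sz)))
    })
  }
  bind_rows(planted, decoys)
}

#' Simulate per-sample stage and subtype annotations
#'
#' Assigns each `cancerB` sample a stage (balanced across `n_stages` stages)
#' and a histological subtype label, and plants a stage-dependent mean shift
#' (`(stage - 1) * stage_shift` log2 units) on the given `effect_genes` in the
#' expression matrix, for exercising the ANOVA validation.
#'
#' @param expression wide expression tibble for the `cancerB` condition.
#' @param spec the [planted_spec()] the expression came from.
#' @param n_stages number of stages, at least 2.
#' @param effect_genes genes receiving the stage-dependent shift; must exist
#'   in `expression`.
#' @param stage_shift per-stage mean increment in log2 units.
#' @param subtypes candidate subtype labels, assigned cyclically.
#' @return List with `annotations` (tibble: sample, stage, subtype) and
#'   `expression` (the shifted matrix).
#' @export
simulate_annotations <- function(expression, spec, n_stages = 3L,
                                 effect_genes = character(),
                                 stage_shift = 0,
                                 subtypes = c("adeno", "squamous")) {
  stopifnot(inherits(spec, "planted_spec"))
  if (n_stages < 2) stop_config("n_stages must be at least 2")
  missing_genes <- setdiff(effect_genes, expression$gene)
  if (length(missing_genes) > 0) {
    stop_input(sprintf("effect_genes absent from expression matrix: %s",
                       paste(missing_genes, collapse = ", ")))
  }
  samples <- setdiff(names(expression), "gene")
  withr::local_seed(derive_seed(spec$seed, "annotations"))
  stage <- sample(rep(sprintf("stage%d", seq_len(n_stages)),
                      length.out = length(samples)))
  subtype <- sample(rep(subtypes, length.out = length(samples)))
  ann <- tibble(sample = samples, stage = stage, subtype = subtype)

  if (stage_shift != 0 && length(effect_genes) > 0) {
    m <- expr_matrix(expression)
    stage_idx <- as.integer(sub("stage", "", stage))
    shift_row <- (stage_idx - 1) * stage_shift
    m[effect_genes, ] <- m[effect_genes, , drop = FALSE] +
      matrix(shift_row, nrow = length(effect_genes), ncol = length(samples),
             byrow = TRUE)
    expression <- matrix_to_expr(m)
  }
  list(annotations = ann, expression = expression)
}

#' Simulate a complete study
#'
#' Convenience wrapper generating the three condition matrices, the scored
#' backbone, a gene-set collection and (optionally shifted) sample
#' annotations from one [planted_spec()].
#'
#' @param spec a [planted_spec()].
#' @param n_background random backbone edges (see [simulate_backbone()]).
#' @param n_decoys decoy gene sets (see [simulate_gene_sets()]).
#' @param n_stages,stage_shift,effect_genes passed to
#'   [simulate_annotations()] for the `cancerB` matrix.
#' @return List with `expression` (named list of wide tibbles), `backbone`,
#'   `gene_sets`, `annotations`, `truth`, and the `spec` itself.
#' @export
simulate_study <- function(spec, n_background = 500L, n_decoys = 20L,
                           n_stages = 3L, stage_shift = 0,
                           effect_genes = character()) {
  truth <- planted_truth(spec)
  expression <- lapply(setNames(nm = names(spec$samples_per_condition)),
                       function(cond) simulate_expression(spec, cond))
  ann <- simulate_annotations(expression$cancerB, spec, n_stages = n_stages,
                              effect_genes = effect_genes,
                              stage_shift = stage_shift)
  expression$cancerB <- ann$expression
  list(expression = expression,
       backbone = simulate_backbone(spec, truth, n_background = n_background),
       gene_sets = simulate_gene_sets(truth, n_decoys = n_decoys,
                                      seed = spec$seed),
       annotations = ann$annotations,
       truth = truth,
       spec = spec)
}
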