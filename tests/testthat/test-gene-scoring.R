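test_that("edge sign difference reproduces the 2/1/0 encoding", {
  edges <- tibble::tibble(
    gene1 = c("a", "c", "e", "g", "i"),
    gene2 = c("b", "d", "f", "h", "j"),
    score = 900L,
    sign_cancerA = c(1L, 1L, 1L, -1L, -1L),
    sign_cancerB = c(-1L, 0L, 1L, -1L, 1L))
  net <- make_net(edges)
  d <- edge_sign_diff(net)
  key <- paste(d$gene1, d$gene2)
  got <- setNames(d$diff, key)
  expect_equal(unname(got[c("a b", "c d", "e f", "g h", "i j")]),
               c(2, 1, 0, 0, 2))
})

test_that("gene mean difference averages module-internal edges only", {
  # hub gene with 2 in-module edges (diffs 2 and 0) plus one cross-module edge
  edges <- tibble::tibble(
    gene1 = c("hub", "hub", "hub"),
    gene2 = c("p1", "p2", "out"),
    score = 900L,
    sign_cancerA = c(1L, 1L, 1L),
    sign_cancerB = c(-1L, 1L, -1L))
  net <- make_net(edges)
  part <- tibble::tibble(gene = c("hub", "p1", "p2", "out"),
                         module = c("m1", "m1", "m1", "m2"),
                         module_size = c(3L, 3L, 3L, 1L),
                         analyzed = c(TRUE, TRUE, TRUE, FALSE))
  md <- gene_mean_diff(net, part)
  expect_equal(md$mean_diff[md$gene == "hub"], 1.0)   # (2 + 0) / 2
  expect_equal(md$n_edges[md$gene == "hub"], 2L)
  # 'out' has edges only to another module
  expect_equal(md$mean_diff[md$gene == "out"], 0)
  expect_equal(md$n_edges[md$gene == "out"], 0L)
  expect_error(gene_mean_diff(net, part, genes = "ghost"), "not in network")
})

test_that("an 18-interaction hub averages to 34/18", {
  # 16 discordant edges (diff 2) and 2 half-discordant (diff 1)
  partners <- sprintf("p%02d", 1:18)
  edges <- tibble::tibble(
    gene1 = "hub", gene2 = partners, score = 900L,
    sign_cancerA = c(rep(-1L, 16), 1L, 1L),
    sign_cancerB = c(rep(1L, 16), 0L, 0L))
  net <- make_net(edges)
  part <- tibble::tibble(gene = c("hub", partners), module = "m1",
                         module_size = 19L, analyzed = TRUE)
  md <- gene_mean_diff(net, part)
  expect_equal(md$mean_diff[md$gene == "hub"], 34 / 18)
})

test_that("gene scores obey the formula, its bounds, and the screen", {
  edges <- tibble::tibble(
    gene1 = c("a", "a", "b", "x", "x", "y"),
    gene2 = c("b", "c", "c", "y", "z", "z"),
    score = 900L,
    sign_cancerA = c(1L, 1L, 1L, 1L, 1L, 1L),
    sign_cancerB = c(-1L, -1L, -1L, 1L, 1L, 1L))
  net <- make_net(edges)
  part <- tibble::tibble(gene = c("a", "b", "c", "x", "y", "z"),
                         module = rep(c("m1", "m2"), each = 3),
                         module_size = 3L, analyzed = TRUE)
  spec_tbl <- tibble::tibble(module = c("m1", "m2"), auc = c(1.0, 0.05),
                             specificity = abs(auc - 0.5),
                             direction = "x", extreme = TRUE)
  sc <- score_genes(net, part, spec_tbl)
  # module m1: every edge discordant, auc 1 -> maximal score 1
  expect_equal(sc$score[sc$gene == "a"], 1.0)
  # module m2: concordant edges -> diff 0 -> score 0 despite extreme auc
  expect_equal(sc$score[sc$gene == "x"], 0)
  expect_true(all(abs(sc$score) <= 1))

  # auc = 0.5 zeroes every member score
  spec_half <- spec_tbl
  spec_half$auc <- c(0.95, 0.5)
  sc2 <- score_genes(net, part, spec_half, auc_hi = 0.4, auc_lo = 0.0)
  expect_true(all(sc2$score[sc2$module == "m2"] == 0))

  # no extreme module -> empty with a warning
  spec_none <- spec_tbl
  spec_none$auc <- c(0.6, 0.45)
  expect_warning(sc3 <- score_genes(net, part, spec_none), "no module")
  expect_equal(nrow(sc3), 0)
})

test_that("swapping the cancer conditions negates every score", {
  study <- small_study()
  res <- run_pipeline(study$expression, study$backbone)
  cfg <- pipeline_config(cancer_a = "cancerB", cancer_b = "cancerA")
  res_swap <- run_pipeline(study$expression, study$backbone, cfg)
  merged <- dplyr::inner_join(res$scores, res_swap$scores, by = "gene",
                              suffix = c("", "_swap"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$score_swap, -merged$score)
})

test_that("scores match direct formula evaluation on a small network", {
  study <- small_study()
  pcc <- lapply(study$expression, pairwise_pcc)
  sets <- purrr::imap(pcc, ~select_signed_pairs(.x, condition = .y))
  net <- build_network(sets, study$backbone)
  part <- partition_modules(net)
  me <- module_expression_all(study$expression, part)
  spec_tbl <- specificity_auc(me)
  sc <- score_genes(net, part, spec_tbl, auc_hi = 0.6, auc_lo = 0.4)

  membership <- setNames(part$module, part$gene)
  auc_by_module <- setNames(spec_tbl$auc, spec_tbl$module)
  oracle <- oracle_gene_scores(as.data.frame(net), as.list(membership),
                               as.list(auc_by_module))
  for (g in sc$gene) {
    expect_equal(sc$score[sc$gene == g], unname(oracle[[g]]),
                 tolerance = 1e-12)
  }
})

test_that("score magnitude is monotone in mean sign difference", {
  mk_edges <- function(n_disc) {
    tibble::tibble(gene1 = "hub", gene2 = sprintf("p%d", 1:4), score = 900L,
                   sign_cancerA = 1L,
                   sign_cancerB = c(rep(-1L, n_disc), rep(1L, 4 - n_disc)))
  }
  part <- tibble::tibble(gene = c("hub", sprintf("p%d", 1:4)), module = "m1",
                         module_size = 5L, analyzed = TRUE)
  spec_tbl <- tibble::tibble(module = "m1", auc = 0.95, specificity = 0.45,
                             direction = "x", extreme = TRUE)
  scores <- vapply(0:4, function(k) {
    sc <- score_genes(make_net(mk_edges(k)), part, spec_tbl)
    sc$score[sc$gene == "hub"]
  }, numeric(1))
  expect_true(all(diff(abs(scores)) >= 0))
})
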