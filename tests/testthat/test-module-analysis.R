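fake_partition <- function(genes, modules, analyzed = TRUE) {
  tibble::tibble(gene = genes, module = modules,
                 module_size = as.integer(ave(seq_along(genes), modules,
                                              FUN = length)),
                 analyzed = analyzed)
}

test_that("module expression uses the per-sample median with even-count convention", {
  ex <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                       s1 = c(1, 2, 9, 10, 4), s2 = c(1, 2, 3, 10, 5))
  part <- fake_partition(c("a", "b", "c", "d", "e"),
                         c("m1", "m1", "m1", "m1", "m2"))
  me <- module_expression(ex, part, "cancerA", analyzed_only = FALSE)
  # odd count within m1 for first three genes only would be 2; with 4 members
  # the even-count median is the mean of the central pair
  expect_equal(me$value[me$module == "m1" & me$sample == "s1"],
               median(c(1, 2, 9, 10)))
  expect_equal(me$value[me$module == "m1" & me$sample == "s2"], 2.5)
  # singleton module: identity
  expect_equal(me$value[me$module == "m2" & me$sample == "s1"], 4)
  # odd-count check: members (1,2,9) -> 2
  part3 <- fake_partition(c("a", "b", "c"), rep("m1", 3))
  me3 <- module_expression(ex[1:3, ], part3, "x", analyzed_only = FALSE)
  expect_equal(me3$value[me3$sample == "s1"], 2)
})

test_that("modules with no members present are skipped with a warning", {
  ex <- tibble::tibble(gene = "a", s1 = 1, s2 = 2)
  part <- fake_partition(c("a", "zz"), c("m1", "m2"))
  expect_warning(me <- module_expression(ex, part, "c", analyzed_only = FALSE),
                 "no member")
  expect_equal(unique(me$module), "m1")
})

test_that("module DE calls follow the FDR and fold-change thresholds", {
  set.seed(201)
  n <- 30
  mk <- function(module, condition, values) {
    tibble::tibble(module = module, condition = condition,
                   sample = sprintf("%s_%02d", condition, seq_along(values)),
                   value = values)
  }
  me <- dplyr::bind_rows(
    mk("shifted", "normal", rnorm(n, 0, 0.5)),
    mk("shifted", "cancerA", rnorm(n, 3, 0.5)),   # planted +3 log2 shift
    mk("null", "normal", rnorm(n, 0, 0.5)),
    mk("null", "cancerA", rnorm(n, 0, 0.5)),
    mk("small_shift", "normal", rnorm(n, 0, 0.1)),
    mk("small_shift", "cancerA", rnorm(n, 1, 0.1)))  # significant but lfc < 2
  de <- module_de(me, alpha = 0.01, lfc_min = 2)
  expect_equal(de$call[de$module == "shifted"], "up")
  expect_equal(de$call[de$module == "null"], "ns")
  expect_equal(de$call[de$module == "small_shift"], "ns")  # lfc filter bites
  expect_true(all(de$fdr >= de$p))                         # BH monotone
  expect_equal(de$lfc[de$module == "shifted"],
               mean(me$value[me$module == "shifted" & me$condition == "cancerA"]) -
                 mean(me$value[me$module == "shifted" & me$condition == "normal"]))
})

test_that("degenerate DE inputs use the zero-variance convention", {
  me <- dplyr::bind_rows(
    tibble::tibble(module = "m", condition = "normal",
                   sample = sprintf("n%d", 1:3), value = 5),
    tibble::tibble(module = "m", condition = "cancerA",
                   sample = sprintf("c%d", 1:3), value = 5))
  de <- module_de(me)
  expect_equal(de$p, 1)
  expect_equal(de$call, "ns")
})

test_that("cross-subtype categories are exhaustive", {
  calls <- expand.grid(a = c("up", "down", "ns"), b = c("up", "down", "ns"),
                       stringsAsFactors = FALSE)
  de <- dplyr::bind_rows(
    tibble::tibble(module = sprintf("m%d", 1:9), condition = "cancerA",
                   t = 0, p = 1, fdr = 1, lfc = 0, call = calls$a),
    tibble::tibble(module = sprintf("m%d", 1:9), condition = "cancerB",
                   t = 0, p = 1, fdr = 1, lfc = 0, call = calls$b))
  cat_tbl <- categorize_modules(de)
  got <- setNames(cat_tbl$category, cat_tbl$module)
  expect_equal(unname(got[sprintf("m%d", 1:9)]),
               c("both_up", "mixed", "B_only_up",
                 "mixed", "both_down", "B_only_down",
                 "A_only_up", "A_only_down", "ns"))
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  expect_equal(auc_mann_whitney(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auc_mann_whitney(c(1, 3), c(2, 4)),
               oracle_auc(c(1, 3), c(2, 4)))
  expect_equal(auc_mann_whitney(c(2, 2), c(2, 2)), 0.5)  # all tied
  set.seed(202)
  for (i in 1:25) {
    x <- round(rnorm(sample(1:20, 1)), 1)  # rounding creates ties
    y <- round(rnorm(sample(1:20, 1)), 1)
    expect_equal(auc_mann_whitney(x, y), oracle_auc(x, y))
    expect_equal(auc_mann_whitney(x, y) + auc_mann_whitney(y, x), 1)
  }
})

test_that("identical class distributions give AUC near one half", {
  set.seed(203)
  aucs <- replicate(50, auc_mann_whitney(rnorm(100), rnorm(100)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("module specificity orients and screens by AUC", {
  set.seed(204)
  mk <- function(module, condition, values) {
    tibble::tibble(module = module, condition = condition,
                   sample = sprintf("%s_%s_%02d", module, condition,
                                    seq_along(values)), value = values)
  }
  me <- dplyr::bind_rows(
    mk("upA", "cancerA", rnorm(40, 4)), mk("upA", "cancerB", rnorm(40, 0)),
    mk("upB", "cancerA", rnorm(40, 0)), mk("upB", "cancerB", rnorm(40, 4)),
    mk("flat", "cancerA", rnorm(40, 0)), mk("flat", "cancerB", rnorm(40, 0)))
  sp <- specificity_auc(me)
  expect_gt(sp$auc[sp$module == "upA"], 0.9)
  expect_lt(sp$auc[sp$module == "upB"], 0.1)
  expect_true(all(sp$extreme[sp$module %in% c("upA", "upB")]))
  expect_false(sp$extreme[sp$module == "flat"])
  expect_equal(sp$direction[sp$module == "upA"], "up_in_cancerA")
  expect_equal(sp$direction[sp$module == "upB"], "up_in_cancerB")
  expect_equal(sp$specificity, abs(sp$auc - 0.5))
})

test_that("null-spec module DE call rate stays near the nominal level", {
  spec <- planted_spec(n_genes = 300, n_modules = 10, module_size = 10,
                       samples_per_condition = c(normal = 30, cancerA = 30,
                                                 cancerB = 30),
                       de_shift = 0, flip_fraction = 0, seed = 31)
  study <- simulate_study(spec, n_background = 100, n_decoys = 0)
  # the empty-score-table warning is the expected null outcome
  res <- suppressWarnings(run_pipeline(study$expression, study$backbone))
  n_tests <- nrow(res$de)
  n_calls <- sum(res$de$call != "ns")
  # nominal FDR 0.01 under a global null: a single false call is already
  # beyond the 99.9% binomial envelope for ~20 tests, allow exactly that
  expect_lte(n_calls, qbinom(0.999, n_tests, 0.01) + 1)
})
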