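test_that("planted_spec validates its configuration", {
  expect_error(planted_spec(n_genes = 50, n_modules = 4, module_size = 25),
               "overflow")
  expect_error(planted_spec(within_module_corr = 0.1, background_corr = 0.5),
               "exceed")
  expect_error(planted_spec(de_shift = 0, flip_fraction = 0.5),
               "requires de_shift")
  expect_error(planted_spec(backbone_score_range = c(900, 600)), "interval")
  expect_error(planted_spec(samples_per_condition = c(normal = 10)), "must name")
})

test_that("ground truth respects the planted structure", {
  spec <- planted_spec(n_genes = 80, n_modules = 3, module_size = 10,
                       samples_per_condition = c(normal = 10, cancerA = 10,
                                                 cancerB = 10),
                       flip_fraction = 0.4, seed = 3)
  truth <- planted_truth(spec)
  expect_equal(sum(truth$membership$module != "background"), 30)
  expect_equal(nrow(truth$de_modules), 3)
  # discriminating genes live inside DE modules
  de_genes <- truth$membership$gene[
    truth$membership$module %in% truth$de_modules$module]
  expect_true(all(truth$discriminating_genes %in% de_genes))
  # the realised flipped-edge fraction is the closest achievable to request
  k <- sum(truth$discriminating_genes %in%
             truth$membership$gene[truth$membership$module == "planted_01"])
  realised <- k * (10 - k) / choose(10, 2)
  best <- min(abs(0:5 * (10 - 0:5) / choose(10, 2) - 0.4))
  expect_equal(abs(realised - 0.4), best)
})

test_that("expression generation is deterministic and plants correlation", {
  spec <- planted_spec(n_genes = 60, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 100, cancerA = 20,
                                                 cancerB = 20),
                       within_module_corr = 0.9, de_shift = 3,
                       flip_fraction = 0, seed = 5)
  e1 <- simulate_expression(spec, "normal")
  e2 <- simulate_expression(spec, "normal")
  expect_identical(e1, e2)

  truth <- planted_truth(spec)
  m <- as.matrix(e1[-1])
  rownames(m) <- e1$gene
  mod1 <- truth$membership$gene[truth$membership$module == "planted_01"]
  cc <- cor(t(m[mod1, ]))
  expect_gt(mean(cc[upper.tri(cc)]), 0.8)
  # background genes stay uncorrelated on average
  bg <- truth$membership$gene[truth$membership$module == "background"][1:10]
  cb <- cor(t(m[bg, ]))
  expect_lt(mean(abs(cb[upper.tri(cb)])), 0.2)
})

test_that("null spec plants no mean difference between conditions", {
  spec <- planted_spec(n_genes = 100, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 40, cancerA = 40,
                                                 cancerB = 40),
                       de_shift = 0, flip_fraction = 0, seed = 9)
  ea <- simulate_expression(spec, "cancerA")
  en <- simulate_expression(spec, "normal")
  truth <- planted_truth(spec)
  bg <- truth$membership$gene[truth$membership$module == "background"]
  pvals <- vapply(bg, function(g) {
    t.test(as.numeric(ea[ea$gene == g, -1]),
           as.numeric(en[en$gene == g, -1]))$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("flipped genes change correlation sign between the cancer subtypes", {
  spec <- planted_spec(n_genes = 60, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 30, cancerA = 60,
                                                 cancerB = 60),
                       flip_fraction = 0.5, de_shift = 3, seed = 13)
  truth <- planted_truth(spec)
  flip <- truth$discriminating_genes[1]
  mod <- truth$membership$module[truth$membership$gene == flip]
  keep <- truth$membership$gene[truth$membership$module == mod &
                                  !truth$membership$gene %in%
                                    truth$discriminating_genes][1]
  ea <- simulate_expression(spec, "cancerA")
  eb <- simulate_expression(spec, "cancerB")
  ca <- cor(as.numeric(ea[ea$gene == flip, -1]),
            as.numeric(ea[ea$gene == keep, -1]))
  cb <- cor(as.numeric(eb[eb$gene == flip, -1]),
            as.numeric(eb[eb$gene == keep, -1]))
  expect_gt(ca, 0.5)
  expect_lt(cb, -0.5)
})

test_that("backbone covers planted pairs and contains no duplicates", {
  spec <- planted_spec(n_genes = 60, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 10, cancerA = 10,
                                                 cancerB = 10),
                       flip_fraction = 0, de_shift = 3, seed = 2)
  truth <- planted_truth(spec)
  bb0 <- simulate_backbone(spec, truth, n_background = 0)
  expect_equal(nrow(bb0), 2 * choose(10, 2))
  expect_true(all(bb0$score > 500))          # planted scores survive retention
  expect_true(all(bb0$gene1 < bb0$gene2))    # canonical, no self edges
  expect_equal(anyDuplicated(bb0[c("gene1", "gene2")]), 0L)

  bb <- simulate_backbone(spec, truth, n_background = 300)
  expect_equal(nrow(bb), nrow(bb0) + 300)
  expect_equal(anyDuplicated(bb[c("gene1", "gene2")]), 0L)
  expect_identical(bb, simulate_backbone(spec, truth, n_background = 300))
})

test_that("gene-set generation matches truth and is byte-reproducible", {
  spec <- planted_spec(n_genes = 60, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 10, cancerA = 10,
                                                 cancerB = 10),
                       flip_fraction = 0, de_shift = 3, seed = 2)
  truth <- planted_truth(spec)
  gs0 <- simulate_gene_sets(truth, n_decoys = 0)
  expect_equal(length(unique(gs0$set)), 2)
  expect_setequal(gs0$gene[gs0$set == "SET_PLANTED_01"],
                  truth$membership$gene[truth$membership$module == "planted_01"])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(simulate_gene_sets(truth, n_decoys = 5, seed = 42), f1)
  write_gmt(simulate_gene_sets(truth, n_decoys = 5, seed = 42), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("annotations label every sample and plant recoverable stage effects", {
  spec <- planted_spec(n_genes = 80, n_modules = 2, module_size = 10,
                       samples_per_condition = c(normal = 10, cancerA = 10,
                                                 cancerB = 90),
                       flip_fraction = 0, de_shift = 3, seed = 21)
  eb <- simulate_expression(spec, "cancerB")
  expect_error(simulate_annotations(eb, spec, effect_genes = "nope"),
               "absent")
  ann0 <- simulate_annotations(eb, spec, n_stages = 3)
  expect_equal(nrow(ann0$annotations), 90)
  expect_equal(sum(table(ann0$annotations$stage)), 90)

  # a 3-log2-unit per-stage shift at n = 30/stage is recovered by the ANOVA
  eff <- eb$gene[31:40]
  ann <- simulate_annotations(eb, spec, n_stages = 3, effect_genes = eff,
                              stage_shift = 3)
  res <- anova_by_group(ann$expression, ann$annotations, "stage")
  expect_true(all(res$significant[res$gene %in% eff]))
  # and the null genes keep roughly uniform p-values
  null_p <- res$p[!res$gene %in% eff]
  expect_gt(mean(null_p > 0.05), 0.8)
})

test_that("simulate_study returns a coherent bundle", {
  study <- small_study()
  expect_named(study$expression, c("normal", "cancerA", "cancerB"))
  expect_equal(nrow(study$annotations),
               study$spec$samples_per_condition[["cancerB"]])
  expect_true(all(study$backbone$gene1 < study$backbone$gene2))
})
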