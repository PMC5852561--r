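test_that("generation is bit-identical under a fixed seed", {
  spec <- sim_spec(n_samples = 80, n_genes = 120, seed = 1)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$expr, b$expr)
  expect_identical(a$labels, b$labels)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("generated cohorts satisfy the container invariants", {
  spec <- sim_spec(n_samples = 100, n_genes = 200, seed = 5)
  sim <- gen_cohort(spec)
  expect_silent(validate_expression_matrix(sim$expr))
  expect_true(all(sim$labels %in% spec$classes))
  expect_true(all(spec$classes %in% sim$labels))
  ann <- sim$annotation
  expect_true(all(ann$biotype %in% c(LNC_BIOTYPES, "protein_coding",
                                     "miRNA")))
  expect_true(all(ann$end - ann$start + 1L == ann$length_bp))
  # some lnc-like genes fall under the 200 bp rule to exercise filtering
  lnc <- ann$biotype %in% LNC_BIOTYPES
  expect_gt(sum(ann$length_bp[lnc] < 200), 0)
  expect_gt(sum(ann$length_bp[lnc] >= 200), 0)
  # planted genes always survive the default biotype/length filter span
  planted <- unlist(sim$truth$informative)
  expect_true(all(ann$length_bp[match(planted, ann$gene_id)] >= 200))
  # lnc-like genes are scaled down versions: lower median expression
  expect_lt(median(sim$expr[sim$truth$lnc_genes, ]),
            median(sim$expr[setdiff(rownames(sim$expr),
                                    sim$truth$lnc_genes), ]))
})

test_that("spec validation rejects impossible configurations", {
  expect_error(sim_spec(class_proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(sim_spec(effect_size = -1), "effect_size")
  expect_error(sim_spec(censoring_rate = 1), "censoring_rate")
  expect_error(sim_spec(n_genes = 20, n_informative_per_class = 10),
               "more planted")
  expect_error(sim_spec(marker_penetrance = 0), "marker_penetrance")
})

test_that("censoring matches the requested rate and zero means no censoring", {
  spec <- sim_spec(n_samples = 600, n_genes = 60, censoring_rate = 0.3,
                   seed = 3)
  sim <- gen_expression(spec)
  clinical <- gen_survival(sim$expr, sim$truth, spec)
  expect_lt(abs(mean(1 - clinical$os_event) - 0.3), 0.05)
  expect_lt(abs(mean(1 - clinical$rfs_event) - 0.3), 0.05)
  spec0 <- sim_spec(n_samples = 200, n_genes = 60, censoring_rate = 0,
                    seed = 3)
  sim0 <- gen_expression(spec0)
  clin0 <- gen_survival(sim0$expr, sim0$truth, spec0)
  expect_true(all(clin0$os_event == 1))
})

test_that("survival endpoints share frailty and track planted betas", {
  spec <- sim_spec(n_samples = 400, n_genes = 60, censoring_rate = 0,
                   hazard_betas = 1, n_prognostic = 1, seed = 9)
  sim <- gen_expression(spec)
  clinical <- gen_survival(sim$expr, sim$truth, spec)
  # shared frailty induces positive OS/RFS dependence
  expect_gt(cor(log(clinical$os_time), log(clinical$rfs_time),
                method = "spearman"), 0.1)
  # the planted gene carries the strongest univariate Cox score
  uni <- univariate_cox_scores(sim$expr, clinical, "OS")
  best <- uni$gene_id[which.max(abs(uni$score))]
  expect_identical(best, sim$truth$prognostic)
})

test_that("null hazard betas give survival independent of expression", {
  spec <- sim_spec(n_samples = 300, n_genes = 40, hazard_betas = 0,
                   censoring_rate = 0.2, seed = 15)
  sim <- gen_expression(spec)
  clinical <- gen_survival(sim$expr, sim$truth, spec)
  uni <- univariate_cox_scores(sim$expr, clinical, "OS")
  expect_gt(min(abs(uni$p), na.rm = TRUE), 1e-4)  # nothing wildly significant
})

test_that("IHC status follows the conditional concordance matrix", {
  spec <- sim_spec(n_samples = 250, n_genes = 40, seed = 4)
  P <- spec$ihc_concordance
  P[] <- 0
  P["Basal", "ER-/PR-/HER2-"] <- 1
  P["Her2", "ER-/PR-/HER2+"] <- 1
  P["LumA", "ER+/PR+/HER2"] <- 1
  P["LumB", "ER+/PR+/HER2"] <- 1
  spec2 <- sim_spec(n_samples = 250, n_genes = 40, seed = 4,
                    ihc_concordance = P)
  sim <- gen_expression(spec2)
  ihc <- gen_ihc(sim$labels, spec2)
  basal <- ihc[match(names(sim$labels)[sim$labels == "Basal"],
                     ihc$sample_id), ]
  expect_true(all(basal$er == "-" & basal$pr == "-" & basal$her2 == "-"))
  expect_identical(gen_ihc(sim$labels, spec2), ihc)  # seeded
  P["Basal", ] <- c(2, 0, 0)
  expect_error(sim_spec(n_samples = 50, n_genes = 40, ihc_concordance = P),
               "probabilities")
})

test_that("downstream accuracy rises with the planted effect size", {
  accs <- vapply(c(0, 2, 3), function(eff) {
    spec <- sim_spec(n_samples = 120, n_genes = 120, effect_size = eff,
                     seed = 31)
    sim <- gen_expression(spec)
    X <- max_normalize(drop_constant_genes(sim$expr))
    planted <- intersect(unlist(sim$truth$informative), rownames(X))
    cv_accuracy(X[planted, , drop = FALSE], sim$labels, k = 5,
                repeats = 2, seed = 7)$mean_accuracy
  }, 0)
  expect_true(all(diff(accs) > -0.05))  # non-decreasing up to noise
  expect_lt(accs[1], 0.45)
  expect_gt(accs[3], 0.85)
})
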