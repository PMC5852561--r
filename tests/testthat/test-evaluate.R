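test_that("repeated stratified CV is near-perfect on separable blobs", {
  blobs <- make_blobs(n_per_class = 15, shift = 6)
  X <- max_normalize(blobs$X)
  rep <- cv_accuracy(X, blobs$labels, k = 5, repeats = 3, seed = 2)
  expect_gte(rep$mean_accuracy, 0.99)
  expect_lte(rep$ci_low, rep$mean_accuracy)
  expect_gte(rep$ci_high, rep$mean_accuracy)
  expect_equal(dim(rep$per_fold), c(5L, 3L))
  expect_length(rep$per_repeat, 3)
  # identical seed reproduces the report exactly
  rep2 <- cv_accuracy(X, blobs$labels, k = 5, repeats = 3, seed = 2)
  expect_identical(rep$per_fold, rep2$per_fold)
  # feature order does not matter
  rep3 <- cv_accuracy(X[rev(seq_len(nrow(X))), ], blobs$labels, k = 5,
                      repeats = 3, seed = 2)
  expect_equal(rep$per_fold, rep3$per_fold)
})

test_that("CV guards its fold preconditions", {
  blobs <- make_blobs(n_per_class = 6)
  expect_error(cv_accuracy(blobs$X, blobs$labels, k = 7), "smaller than k")
  expect_error(cv_accuracy(blobs$X, blobs$labels, k = 100),
               "exceeds the number of samples")
})

test_that("stratified folds spread every class across folds", {
  labels <- rep(SUBTYPE_LEVELS, times = c(20, 12, 28, 16))
  folds <- lncsig:::make_stratified_folds(labels, 4, seed = 3)
  expect_equal(sort(unique(folds)), 1:4)
  for (cl in SUBTYPE_LEVELS) {
    per_fold <- table(folds[labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("one-hot decision values give perfect per-class ROC", {
  labels <- rep(SUBTYPE_LEVELS, each = 10)
  dv <- sapply(SUBTYPE_LEVELS, function(cl) as.numeric(labels == cl))
  roc <- roc_per_subtype(dv, labels)
  expect_setequal(names(roc), SUBTYPE_LEVELS)
  for (r in roc) expect_equal(r$auc, 1.0)
})

test_that("uninformative decision values give chance-level AUC", {
  set.seed(5)
  labels <- rep(SUBTYPE_LEVELS, each = 100)
  dv <- matrix(rnorm(400 * 4), 400, 4,
               dimnames = list(NULL, SUBTYPE_LEVELS))
  roc <- roc_per_subtype(dv, labels)
  for (r in roc) expect_lt(abs(r$auc - 0.5), 0.1)
})

test_that("classes absent from labels are skipped with a warning", {
  labels <- rep(c("Basal", "LumA"), each = 10)
  dv <- matrix(rnorm(60), 20, 3,
               dimnames = list(NULL, c("Basal", "LumA", "Her2")))
  expect_warning(roc <- roc_per_subtype(dv, labels), "Her2")
  expect_setequal(names(roc), c("Basal", "LumA"))
  expect_warning(out <- roc_per_subtype(dv, rep("Basal", 20)),
                 "fewer than 2 classes")
  expect_length(out, 0)
})

test_that("t-SNE separates well-separated blobs without seeing labels", {
  # labels are not an argument of the embedding at all
  expect_false("labels" %in% names(formals(tsne_embed)))
  blobs <- make_blobs(n_per_class = 20, npc = 2, p_null = 4, shift = 8,
                      seed = 9)
  emb <- tsne_embed(max_normalize(blobs$X), perplexity = 10, seed = 4)
  expect_equal(dim(emb), c(80L, 2L))
  expect_true(all(is.finite(emb)))
  # silhouette of the true labels on the embedding
  d <- as.matrix(dist(emb))
  sil <- vapply(seq_len(nrow(emb)), function(i) {
    own <- blobs$labels[i]
    a <- mean(d[i, blobs$labels == own & seq_len(nrow(emb)) != i])
    b <- min(vapply(setdiff(unique(blobs$labels), own),
                    function(cl) mean(d[i, blobs$labels == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
  # deterministic under a fixed seed
  emb2 <- tsne_embed(max_normalize(blobs$X), perplexity = 10, seed = 4)
  expect_identical(emb, emb2)
  expect_error(tsne_embed(blobs$X, perplexity = 50), "perplexity")
})

test_that("duplicated samples embed at nearly identical coordinates", {
  blobs <- make_blobs(n_per_class = 20, shift = 6, seed = 2)
  X <- max_normalize(blobs$X)
  X2 <- cbind(X, dup = X[, 1])
  colnames(X2)[ncol(X2)] <- "dup"
  emb <- tsne_embed(X2, perplexity = 8, seed = 1)
  d_pair <- sqrt(sum((emb["s001", ] - emb["dup", ])^2))
  d_all <- median(dist(emb))
  expect_lt(d_pair, d_all / 4)
})

test_that("unlabeled-sample prediction is consistent with training", {
  blobs <- make_blobs(n_per_class = 15, shift = 5)
  X <- max_normalize(blobs$X)
  fit <- fit_l2svm(X, blobs$labels)
  pred <- predict_unlabeled(fit, X)
  expect_equal(agreement(pred, blobs$labels),
               mean(predict(fit, X) == blobs$labels))
  expect_equal(agreement(pred, predict_unlabeled(fit, X)), 1.0)
  # samples drawn from the Basal generator are mostly predicted Basal
  sim <- gen_expression(sim_spec(n_samples = 160, n_genes = 120,
                                 effect_size = 3, seed = 12))
  Xs <- max_normalize(drop_constant_genes(sim$expr))
  fit2 <- fit_l2svm(Xs, sim$labels)
  basal <- names(sim$labels)[sim$labels == "Basal"]
  pred2 <- predict_unlabeled(fit2, Xs[, basal, drop = FALSE])
  expect_gt(mean(pred2 == "Basal"), 0.5)
  # feature mismatch is an error
  expect_error(predict_unlabeled(fit, Xs), "feature mismatch")
})

test_that("IHC concordance cross-tab has column percentages summing to 100", {
  sim <- gen_expression(sim_spec(n_samples = 300, n_genes = 50, seed = 3))
  ihc <- gen_ihc(sim$labels, sim_spec(n_samples = 300, n_genes = 50,
                                      seed = 3))
  conc <- ihc_concordance(sim$labels, ihc)
  nonzero <- colSums(conc$counts) > 0
  expect_true(all(abs(colSums(conc$col_pct)[nonzero] - 100) < 0.1))
  expect_true(all(conc$counts >= 0))
})

test_that("degenerate IHC inputs give empty or single-cell tables", {
  clin <- data.frame(sample_id = c("s1", "s2"), er = c(NA, NA),
                     pr = c(NA, NA), her2 = c(NA, NA),
                     stringsAsFactors = FALSE)
  expect_warning(conc <- ihc_concordance(c(s1 = "Basal", s2 = "LumA"),
                                         clin),
                 "no samples")
  expect_equal(nrow(conc$counts), 0)
  clin1 <- data.frame(sample_id = "s1", er = "+", pr = "+", her2 = "-",
                      stringsAsFactors = FALSE)
  conc1 <- ihc_concordance(c(s1 = "LumA"), clin1)
  expect_equal(conc1$col_pct["LumA", "ER+/PR+/HER2"], 100)
  expect_equal(sum(conc1$counts), 1)
})
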