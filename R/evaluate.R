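#' Repeated stratified cross-validated accuracy
#'
#' Scores a gene signature by repeated stratified k-fold cross-validation
#' with the 2-Norm SVM evaluation classifier ([fit_l2svm()]). Each repeat
#' uses a distinct, seed-derived fold assignment; the confidence interval
#' is the t-interval over the repeat-level accuracies,
#' `mean +/- t(0.975, r-1) * sd / sqrt(r)`.
#'
#' @param X features x samples matrix restricted to the signature.
#' @param labels class label per sample; every class needs >= k members.
#' @param k folds (default 10).
#' @param repeats number of repeats (default 10).
#' @param seed master seed for fold assignments.
#' @param C2 tradeoff for the evaluation classifier.
#' @param control solver control.
#' @return object of class `cv_report`: `mean_accuracy`, `ci_low`,
#'   `ci_high`, `per_fold` (k x repeats accuracies), `per_repeat`, `k`,
#'   `repeats`, `seed`.
#' @export
cv_accuracy <- function(X, labels, k = 10L, repeats = 10L, seed = 1L,
                        C2 = 0.9, control = svm_control()) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(X))
  if (k > ncol(X)) stop("k exceeds the number of samples")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class(es) smaller than k = ", k, ": ",
         paste(names(tab)[tab < k], collapse = ", "),
         "; use a smaller k")
  }
  seeds <- derive_seeds(seed, repeats)
  per_fold <- matrix(NA_real_, k, repeats)
  per_repeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    folds <- make_stratified_folds(labels, k, seeds[r])
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_l2svm(X[, tr, drop = FALSE], labels[tr], C2 = C2,
                       control = control)
      pred <- predict(fit, X[, !tr, drop = FALSE])
      per_fold[f, r] <- mean(pred == labels[!tr])
      correct <- correct + sum(pred == labels[!tr])
    }
    per_repeat[r] <- correct / length(labels)
  }
  m <- mean(per_repeat)
  half <- if (repeats > 1) {
    qt(0.975, repeats - 1) * sd(per_repeat) / sqrt(repeats)
  } else 0
  structure(list(mean_accuracy = m, ci_low = m - half, ci_high = m + half,
                 per_fold = per_fold, per_repeat = per_repeat,
                 k = as.integer(k), repeats = as.integer(repeats),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats: accuracy %.1f%% [%.1f%%, %.1f%%]\n",
              x$k, x$repeats, 100 * x$mean_accuracy, 100 * x$ci_low,
              100 * x$ci_high))
  invisible(x)
}

#' Per-subtype one-vs-rest ROC curves
#'
#' For each class, treats that class as positive and its one-vs-rest
#' linear decision values as the score, returning sensitivity/specificity
#' coordinates and the AUC (via \pkg{pROC}).
#'
#' @param decision samples x classes matrix of decision values
#'   (e.g., from [decision_values()]).
#' @param labels true class per sample.
#' @return named list per class: `sensitivity`, `specificity`, `auc`.
#'   Classes absent from `labels` are skipped with a warning.
#' @export
roc_per_subtype <- function(decision, labels) {
  labels <- as.character(labels)
  stopifnot(is.matrix(decision), nrow(decision) == length(labels),
            !is.null(colnames(decision)))
  if (length(unique(labels)) < 2) {
    warning("fewer than 2 classes present; no ROC computed")
    return(list())
  }
  out <- list()
  for (cl in colnames(decision)) {
    if (!cl %in% labels) {
      warning("class absent from labels, skipped: ", cl)
      next
    }
    r <- pROC::roc(response = factor(labels == cl, c(FALSE, TRUE)),
                   predictor = decision[, cl], quiet = TRUE,
                   direction = "<")
    out[[cl]] <- list(sensitivity = r$sensitivities,
                      specificity = r$specificities,
                      auc = as.numeric(r$auc))
  }
  out
}

#' t-SNE embedding of samples
#'
#' Unsupervised 2-D embedding of the samples (columns) for visualization.
#' Class labels are deliberately not an argument: subtype information is
#' only ever used to color the resulting plot, never in the optimization.
#'
#' @param X features x samples matrix.
#' @param perplexity t-SNE perplexity; requires
#'   `ncol(X) - 1 >= 3 * perplexity`.
#' @param seed RNG seed (embedding is deterministic given it).
#' @param ... further arguments to [Rtsne::Rtsne()].
#' @return samples x 2 coordinate matrix with sample rownames.
#' @export
tsne_embed <- function(X, perplexity = 30, seed = 1L, ...) {
  n <- ncol(X)
  if (n - 1 < 3 * perplexity) {
    stop("perplexity too large: need ncol(X) - 1 >= 3 * perplexity")
  }
  emb <- with_seed(seed, Rtsne::Rtsne(t(X), dims = 2,
                                      perplexity = perplexity,
                                      pca = TRUE, partial_pca = FALSE,
                                      check_duplicates = FALSE,
                                      verbose = FALSE, ...))
  coords <- emb$Y
  rownames(coords) <- colnames(X)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Predict subtypes for unlabeled samples
#'
#' Applies a classifier trained on the labeled partition to new samples.
#'
#' @param classifier fitted `ovr_svm`.
#' @param X features x samples matrix of unlabeled samples (same feature
#'   set as training; mismatch is an error).
#' @return named character vector of predicted labels.
#' @export
predict_unlabeled <- function(classifier, X) {
  predict(classifier, X)
}

#' Agreement between two label assignments
#' @param labels_a,labels_b label vectors over the same samples (matched
#'   by names when both are named).
#' @return fraction of samples with identical labels.
#' @export
agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0) stop("no shared samples between label sets")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  }
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length and carry no names to match on")
  }
  mean(as.character(labels_a) == as.character(labels_b))
}

# IHC category from ER/PR/HER2 status strings ("+", "-", "" / NA)
ihc_category <- function(er, pr, her2) {
  out <- rep(NA_character_, length(er))
  out[er == "-" & pr == "-" & her2 == "-"] <- "ER-/PR-/HER2-"
  out[er == "-" & pr == "-" & her2 == "+"] <- "ER-/PR-/HER2+"
  out[er == "+" & pr == "+"] <- "ER+/PR+/HER2"
  out
}

#' Concordance of predicted subtypes with IHC marker categories
#'
#' Cross-tabulates predicted subtypes against the three clinically used
#' immunohistochemistry categories: triple negative (ER-/PR-/HER2-),
#' ER-/PR-/HER2+, and ER+/PR+ with HER2 status unrestricted (written
#' "ER+/PR+/HER2"). Samples that fall in none of the categories, or lack
#' marker status, are excluded with a logged count. Column percentages
#' sum to 100.
#'
#' @param predicted named character vector of predicted subtypes.
#' @param clinical clinical `data.frame` with `sample_id`, `er`, `pr`,
#'   `her2` columns.
#' @return object of class `concordance_table`: `counts` (subtype x
#'   category), `col_pct`, `n_excluded`.
#' @export
ihc_concordance <- function(predicted, clinical) {
  stopifnot(!is.null(names(predicted)),
            all(c("sample_id", "er", "pr", "her2") %in% names(clinical)))
  idx <- match(names(predicted), clinical$sample_id)
  cat3 <- ihc_category(as.character(clinical$er[idx]),
                       as.character(clinical$pr[idx]),
                       as.character(clinical$her2[idx]))
  keep <- !is.na(cat3) & !is.na(predicted)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    log_msg("ihc_concordance: %d sample(s) outside the three categories",
            n_excluded)
  }
  cats <- c("ER-/PR-/HER2-", "ER-/PR-/HER2+", "ER+/PR+/HER2")
  if (!any(keep)) {
    warning("no samples with usable IHC status")
    counts <- matrix(0L, 0, 3, dimnames = list(NULL, cats))
    return(structure(list(counts = counts, col_pct = counts,
                          n_excluded = n_excluded),
                     class = "concordance_table"))
  }
  subtypes <- class_order(predicted[keep])
  counts <- table(factor(predicted[keep], subtypes),
                  factor(cat3[keep], cats))
  counts <- unclass(counts)
  tot <- colSums(counts)
  col_pct <- sweep(counts, 2, pmax(tot, 1), "/") * 100
  structure(list(counts = counts, col_pct = col_pct,
                 n_excluded = n_excluded),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("predicted subtype x IHC category (column %):\n")
  print(round(x$col_pct, 1))
  invisible(x)
}
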