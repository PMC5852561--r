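#' Default tradeoff grid for the selection sweep
#'
#' Log-spaced, strictly decreasing values of the tradeoff `C` from near 1
#' (loss-dominated, dense) down to near 0 (penalty-dominated, empty).
#'
#' @param n number of grid points.
#' @param from,to endpoints, both in (0, 1), `from > to`.
#' @return decreasing numeric vector.
#' @export
default_c_grid <- function(n = 30L, from = 0.99, to = 1e-3) {
  stopifnot(from > to, from < 1, to > 0)
  exp(seq(log(from), log(to), length.out = n))
}

#' Sweep the tradeoff grid and record the selection curve
#'
#' For each `C` in a decreasing grid, fits a one-vs-rest sparse SVM on the
#' full data (warm-started from the previous grid point) and records the
#' training accuracy, the pooled nonzero-gene count (union over the
#' per-class models — a gene active in two classifiers counts once), and
#' optionally stratified k-fold cross-validated accuracy.
#'
#' @param X features x samples matrix (max-normalized expression).
#' @param labels class label per sample.
#' @param c_grid strictly decreasing values in (0, 1).
#' @param cv_folds folds for the CV-accuracy column; `0` skips CV (the
#'   selection rule itself uses training accuracy only).
#' @param seed seed for CV fold assignment.
#' @param eps_w relative nonzero threshold for gene counting.
#' @param control solver control.
#' @param keep_fits if `TRUE`, attach the fitted `ovr_svm` per grid point.
#' @return `data.frame` (class `selection_curve`) with columns `C`,
#'   `train_accuracy`, `cv_accuracy`, `n_nonzero`; fitted models in
#'   `attr(, "fits")` when requested.
#' @export
sweep_c <- function(X, labels, c_grid = default_c_grid(), cv_folds = 0L,
                    seed = 1L, eps_w = 1e-6, control = svm_control(),
                    keep_fits = FALSE) {
  labels <- as.character(labels)
  if (length(c_grid) == 0) stop("c_grid must be non-empty")
  if (any(diff(c_grid) >= 0)) {
    if (length(c_grid) > 1) stop("c_grid must be strictly decreasing")
  }
  if (any(c_grid <= 0 | c_grid >= 1)) stop("c_grid values must be in (0, 1)")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")

  folds <- if (cv_folds > 0) make_stratified_folds(labels, cv_folds, seed)
  warm <- NULL
  cv_warm <- vector("list", max(cv_folds, 0L))
  fits <- if (keep_fits) vector("list", length(c_grid))
  out <- data.frame(C = c_grid, train_accuracy = NA_real_,
                    cv_accuracy = NA_real_, n_nonzero = NA_integer_)
  for (i in seq_along(c_grid)) {
    C <- c_grid[i]
    fit <- fit_ovr(X, labels, C, penalty = "l1", warm = warm,
                   control = control)
    warm <- lapply(fit$models, function(m) list(w = m$w, b = m$b))
    pred <- predict(fit, X)
    out$train_accuracy[i] <- mean(pred == labels)
    out$n_nonzero[i] <- length(unique(nonzero_genes(fit, eps_w)$gene_id))
    if (keep_fits) fits[[i]] <- fit
    if (cv_folds > 0) {
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        cf <- fit_ovr(X[, tr, drop = FALSE], labels[tr], C, penalty = "l1",
                      warm = cv_warm[[f]], control = control)
        cv_warm[[f]] <- lapply(cf$models, function(m) list(w = m$w, b = m$b))
        correct <- correct +
          sum(predict(cf, X[, !tr, drop = FALSE]) == labels[!tr])
      }
      out$cv_accuracy[i] <- correct / length(labels)
    }
  }
  class(out) <- c("selection_curve", "data.frame")
  if (keep_fits) attr(out, "fits") <- fits
  out
}

# stratified fold ids (1..k), seeded; every class spread across folds
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Iteration 1: find the accuracy-threshold tradeoff and the gene pool
#'
#' Sweeps `C` downward and stops at `C*`, the smallest grid value whose
#' full-data training accuracy still meets the threshold `theta` (0.9 by
#' default). The gene pool is the union of nonzero-weight genes across the
#' one-vs-rest models at `C*`.
#'
#' @inheritParams sweep_c
#' @param theta training-accuracy threshold in (0, 1].
#' @return list with `C_star`, `gene_pool` (character), `curve`
#'   (the [sweep_c()] table) and `fit` (the `ovr_svm` at `C_star`).
#' @export
select_iteration1 <- function(X, labels, c_grid = default_c_grid(),
                              theta = 0.9, eps_w = 1e-6,
                              control = svm_control(), cv_folds = 0L,
                              seed = 1L) {
  stopifnot(theta > 0 || theta == 0, theta <= 1)
  curve <- sweep_c(X, labels, c_grid, cv_folds = cv_folds, seed = seed,
                   eps_w = eps_w, control = control, keep_fits = TRUE)
  ok <- which(curve$train_accuracy >= theta)
  if (length(ok) == 0) {
    stop("no grid point reaches training accuracy theta = ", theta,
         "; use a denser or larger C grid (best = ",
         signif(max(curve$train_accuracy), 3), ")")
  }
  i_star <- max(ok)  # grid is decreasing, so max index = smallest C
  fit <- attr(curve, "fits")[[i_star]]
  attr(curve, "fits") <- NULL
  pool <- unique(nonzero_genes(fit, eps_w)$gene_id)
  list(C_star = curve$C[i_star], gene_pool = pool, curve = curve, fit = fit)
}

#' Iteration 2: shrink the pool to a target signature size
#'
#' Restricted to the iteration-1 gene pool, sweeps `C` again and returns
#' the gene set at the largest `C` whose pooled nonzero count is at most
#' `target_n` (closest from below); if every grid point selects more than
#' `target_n` genes, the point minimizing `|count - target_n|` is used.
#' Each selected gene is attributed to the subtypes whose one-vs-rest
#' classifier gave it nonzero weight.
#'
#' @inheritParams sweep_c
#' @param target_n desired signature size (>= 1).
#' @return list with `genes`, `attribution` (named list gene -> subtypes),
#'   `weights` (named max |w| per gene), `C_selected`, `curve`, `fit`.
#' @export
select_iteration2 <- function(X, labels, target_n = 50L,
                              c_grid = default_c_grid(), eps_w = 1e-6,
                              control = svm_control(), cv_folds = 0L,
                              seed = 1L) {
  if (nrow(X) == 0) stop("gene pool is empty")
  stopifnot(target_n >= 1)
  curve <- sweep_c(X, labels, c_grid, cv_folds = cv_folds, seed = seed,
                   eps_w = eps_w, control = control, keep_fits = TRUE)
  below <- which(curve$n_nonzero <= target_n & curve$n_nonzero > 0)
  i_sel <- if (length(below) > 0) {
    min(below)  # grid decreasing: smallest index = largest C
  } else {
    which.min(abs(curve$n_nonzero - target_n))
  }
  fit <- attr(curve, "fits")[[i_sel]]
  attr(curve, "fits") <- NULL
  nz <- nonzero_genes(fit, eps_w)
  genes <- unique(nz$gene_id)
  # a gene marks the subtypes whose classifiers it pushes toward (positive
  # weight on non-negative expression); negative weights encode "the rest"
  # and only stand in when a gene has no positive weight anywhere
  attribution <- lapply(genes, function(g) {
    rows <- nz[nz$gene_id == g, , drop = FALSE]
    pos <- rows$subtype[rows$coef > 0]
    if (length(pos) > 0) unique(pos) else unique(rows$subtype)
  })
  names(attribution) <- genes
  weights <- vapply(split(nz$weight, nz$gene_id), max, 0)[genes]
  list(genes = genes, attribution = attribution, weights = weights,
       C_selected = curve$C[i_sel], curve = curve, fit = fit)
}

#' Two-iteration recursive gene selection
#'
#' The full recursive procedure: iteration 1 sweeps `C` down to the
#' training-accuracy threshold `theta` and pools all nonzero-weight genes;
#' iteration 2 re-runs the sweep on that pool alone and shrinks to at most
#' `target_n` genes, attributing each survivor to the subtypes that use
#' it. Rather than jumping to a very small `C` in one step, the two-stage
#' descent yields a stable short list. Optionally a biotype/length filter
#' is re-applied to the final set (mirroring post-hoc exclusion of short
#' or uncertain transcripts).
#'
#' @inheritParams select_iteration1
#' @param target_n iteration-2 signature size.
#' @param c_grid1,c_grid2 tradeoff grids for the two iterations.
#' @param refilter optional list(annotation=, spec=) applied to the final
#'   gene set via the same predicate as [filter_noncoding()].
#' @param seed seed recorded and used for any CV folds.
#' @return object of class `selection_result` with fields
#'   `iteration1_genes`, `iteration2_genes`, `C_star`, `C_selected`,
#'   `theta`, `target_n`, `attribution`, `weights`, `curves` (list of two
#'   selection curves), `seed`, and the iteration-2 `fit`.
#' @export
recursive_select <- function(X, labels, theta = 0.9, target_n = 50L,
                             c_grid1 = default_c_grid(),
                             c_grid2 = default_c_grid(),
                             eps_w = 1e-6, control = svm_control(),
                             cv_folds = 0L, seed = 1L, refilter = NULL) {
  it1 <- select_iteration1(X, labels, c_grid = c_grid1, theta = theta,
                           eps_w = eps_w, control = control,
                           cv_folds = cv_folds, seed = seed)
  if (length(it1$gene_pool) == 0) {
    stop("iteration 1 selected no genes at C* = ", signif(it1$C_star, 3))
  }
  it2 <- select_iteration2(X[it1$gene_pool, , drop = FALSE], labels,
                           target_n = target_n, c_grid = c_grid2,
                           eps_w = eps_w, control = control,
                           cv_folds = cv_folds, seed = seed)
  genes <- it2$genes
  attribution <- it2$attribution
  weights <- it2$weights
  if (!is.null(refilter)) {
    ann <- refilter$annotation[!duplicated(refilter$annotation$gene_id), ]
    idx <- match(genes, ann$gene_id)
    keep <- !is.na(idx) &
      canonical_biotype(ann$biotype[idx]) %in% refilter$spec$allowed_biotypes &
      ann$length_bp[idx] >= refilter$spec$min_length_bp
    log_msg("post-selection biotype filter kept %d of %d genes",
            sum(keep), length(genes))
    genes <- genes[keep]
    attribution <- attribution[genes]
    weights <- weights[genes]
  }
  structure(list(iteration1_genes = it1$gene_pool,
                 iteration2_genes = genes,
                 C_star = it1$C_star, C_selected = it2$C_selected,
                 theta = theta, target_n = as.integer(target_n),
                 attribution = attribution, weights = weights,
                 curves = list(iteration1 = it1$curve,
                               iteration2 = it2$curve),
                 seed = seed, fit = it2$fit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "recursive sparse-SVM selection: %d genes in pool (C* = %.3g, theta = %g), %d in final signature (C = %.3g)\n",
    length(x$iteration1_genes), x$C_star, x$theta,
    length(x$iteration2_genes), x$C_selected))
  ns <- lengths(x$attribution)
  if (length(ns) > 0) {
    cat(sprintf("genes attributed to a single subtype: %d of %d\n",
                sum(ns == 1), length(ns)))
  }
  invisible(x)
}
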