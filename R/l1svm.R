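#' Fit a binary sparse squared-hinge SVM
#'
#' Minimizes, over weights `w` (one per gene) and an unpenalized intercept
#' `b`,
#' \deqn{C \sum_i \max(0, 1 - y_i (w^T x_i + b))^2 + (1 - C)\,\|w\|_1,}
#' the 1-Norm SVM objective whose convex-combination tradeoff `C` in (0, 1)
#' balances the squared-hinge loss against the sparsity-inducing L1 penalty
#' (equivalently, a penalty parameter `lambda = (1 - C)/C`). Small `C`
#' drives `w` to exactly zero; `C` near 1 fits the data as well as the
#' model can. Solved by accelerated proximal gradient (FISTA) with
#' backtracking; warm starts are supported for regularization paths.
#'
#' @param X numeric matrix, features x samples (genes as rows).
#' @param y labels coercible to -1/+1 (one per sample); a two-level factor
#'   or character vector is mapped with the second level of
#'   [class_order] semantics for `positive_class`.
#' @param C tradeoff, strictly inside (0, 1).
#' @param penalty `"l1"` (default, sparse) or `"l2"` (ridge; used for the
#'   evaluation classifier).
#' @param positive_class label treated as +1 when `y` is not numeric.
#' @param warm optional list with elements `w`, `b` to start from.
#' @param control list with `max_iter` and `tol` for the solver.
#' @return object of class `l1svm`: `w` (named), `b`, `C`, `penalty`,
#'   `positive_class`, `objective_value`, `iterations`, `converged`.
#' @export
fit_l1svm <- function(X, y, C, penalty = c("l1", "l2"),
                      positive_class = NULL, warm = NULL,
                      control = svm_control()) {
  penalty <- match.arg(penalty)
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (any(!is.finite(X))) stop("X must be finite")
  if (length(y) != ncol(X)) stop("length(y) must equal ncol(X)")
  if (!is.numeric(C) || length(C) != 1 || C <= 0 || C >= 1) {
    stop("C must lie strictly inside (0, 1)")
  }
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must be coded -1/+1")
    yy <- y
    if (is.null(positive_class)) positive_class <- "+1"
  } else {
    y <- as.character(y)
    if (is.null(positive_class)) positive_class <- class_order(y)[1]
    yy <- ifelse(y == positive_class, 1, -1)
  }
  if (length(unique(yy)) < 2) stop("y must contain both classes")

  p <- nrow(X)
  w0 <- if (!is.null(warm)) as.numeric(warm$w) else numeric(p)
  b0 <- if (!is.null(warm)) as.numeric(warm$b) else 0
  fit <- .svm_solve_cpp(t(X), yy, C, penalty == "l1", w0, b0,
                        as.integer(control$max_iter), control$tol)
  w <- as.numeric(fit$w)
  names(w) <- rownames(X)
  structure(list(w = w, b = fit$b, C = C, penalty = penalty,
                 positive_class = positive_class,
                 objective_value = fit$objective,
                 iterations = fit$iterations, converged = fit$converged),
            class = "l1svm")
}

#' Solver control parameters
#' @param max_iter iteration cap for the proximal-gradient solver.
#' @param tol relative objective-change tolerance (must hold for 5
#'   consecutive iterations).
#' @return list of control parameters.
#' @export
svm_control <- function(max_iter = 20000L, tol = 1e-11) {
  list(max_iter = as.integer(max_iter), tol = tol)
}

#' Evaluate the sparse-SVM objective at given coefficients
#'
#' @param w weight vector; @param b intercept; @param X features x samples;
#' @param y -1/+1 labels; @param C tradeoff; @param penalty "l1" or "l2".
#' @return scalar objective value.
#' @export
svm_objective <- function(w, b, X, y, C, penalty = c("l1", "l2")) {
  penalty <- match.arg(penalty)
  h <- pmax(0, 1 - y * (drop(crossprod(X, w)) + b))
  pen <- if (penalty == "l1") sum(abs(w)) else sum(w^2)
  C * sum(h^2) + (1 - C) * pen
}

#' @export
print.l1svm <- function(x, ...) {
  cat(sprintf("sparse squared-hinge SVM (%s): %d features, %d nonzero, C = %g\n",
              x$penalty, length(x$w), sum(x$w != 0), x$C))
  invisible(x)
}

#' Linear decision values of a binary SVM
#' @param object fitted `l1svm`.
#' @param X features x samples matrix with the training feature set.
#' @param ... unused.
#' @return numeric vector of `w'x + b` per sample.
#' @export
predict.l1svm <- function(object, X, ...) {
  if (!setequal(rownames(X), names(object$w))) {
    stop("feature mismatch between model and prediction matrix")
  }
  X <- X[names(object$w), , drop = FALSE]
  drop(crossprod(X, object$w)) + object$b
}

#' Fit a one-vs-rest multiclass sparse SVM
#'
#' Fits one binary [fit_l1svm()] per class (that class positive, the rest
#' negative) on a shared feature space. Prediction takes the argmax of the
#' per-class linear decision values, breaking exact ties toward the
#' earliest class in the fixed ordering (Basal, Her2, LumA, LumB, then
#' alphabetical).
#'
#' @inheritParams fit_l1svm
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param warm optional named list of per-class warm starts.
#' @return object of class `ovr_svm` with `models` (named list of `l1svm`),
#'   `classes`, `C`, `penalty`.
#' @export
fit_ovr <- function(X, labels, C, penalty = c("l1", "l2"), warm = NULL,
                    control = svm_control()) {
  penalty <- match.arg(penalty)
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) stop("labels must match ncol(X)")
  classes <- class_order(labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  models <- lapply(classes, function(cl) {
    fit_l1svm(X, ifelse(labels == cl, 1, -1), C, penalty = penalty,
              positive_class = cl, warm = warm[[cl]], control = control)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes, C = C,
                 penalty = penalty), class = "ovr_svm")
}

#' Fit the 2-Norm SVM evaluation classifier
#'
#' One-vs-rest linear SVM with squared hinge loss and a squared 2-norm
#' penalty — the dense, non-sparsifying counterpart of [fit_ovr()] used to
#' score selected gene signatures. Deterministic given the data and `C2`.
#'
#' @param X features x samples matrix.
#' @param labels class label per sample.
#' @param C2 tradeoff in (0, 1) for loss vs ridge penalty.
#' @param control solver control.
#' @return `ovr_svm` object with `penalty = "l2"`.
#' @export
fit_l2svm <- function(X, labels, C2 = 0.9, control = svm_control()) {
  fit_ovr(X, labels, C2, penalty = "l2", control = control)
}

#' Per-class decision values of a one-vs-rest SVM
#' @param object fitted `ovr_svm`.
#' @param X features x samples matrix.
#' @return samples x classes matrix of linear decision values.
#' @export
decision_values <- function(object, X) {
  stopifnot(inherits(object, "ovr_svm"))
  vapply(object$models, function(m) predict(m, X),
         numeric(ncol(X)))
}

#' Predict class labels with a one-vs-rest SVM
#' @param object fitted `ovr_svm`.
#' @param X features x samples matrix.
#' @param type `"class"` for labels, `"decision"` for the score matrix.
#' @param ... unused.
#' @return character vector of labels, or the decision matrix.
#' @export
predict.ovr_svm <- function(object, X, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dv <- decision_values(object, X)
  if (!is.matrix(dv)) dv <- matrix(dv, ncol = length(object$models),
                                   dimnames = list(NULL, object$classes))
  if (type == "decision") return(dv)
  # max.col ties are random; resolve toward the earliest class explicitly
  idx <- apply(dv, 1, function(r) which(r == max(r))[1])
  setNames(object$classes[idx], colnames(X))
}

#' @export
print.ovr_svm <- function(x, ...) {
  nz <- vapply(x$models, function(m) sum(m$w != 0), 0L)
  cat(sprintf("one-vs-rest %s SVM, C = %g\n", x$penalty, x$C))
  print(nz)
  invisible(x)
}

#' Genes with numerically nonzero weight
#'
#' A weight counts as nonzero when `|w_k| > eps_w * max(1, max|w|)`, a
#' relative tolerance because "nonzero" is floating-point-dependent. With
#' `eps_w = 0` the test is exact.
#'
#' @param model fitted `l1svm` or `ovr_svm`.
#' @param eps_w relative zero threshold (default 1e-6).
#' @return for `l1svm`, a named numeric vector of `|w|` over selected
#'   genes; for `ovr_svm`, a `data.frame` with `gene_id`, `subtype`,
#'   `weight` (one row per class in which the gene is active).
#' @export
nonzero_genes <- function(model, eps_w = 1e-6) {
  UseMethod("nonzero_genes")
}

#' @export
nonzero_genes.l1svm <- function(model, eps_w = 1e-6) {
  aw <- abs(model$w)
  thr <- eps_w * max(1, max(aw, 0))
  sel <- if (eps_w == 0) aw > 0 else aw > thr
  aw[sel]
}

#' @export
nonzero_genes.ovr_svm <- function(model, eps_w = 1e-6) {
  parts <- lapply(names(model$models), function(cl) {
    nz <- nonzero_genes(model$models[[cl]], eps_w)
    if (length(nz) == 0) return(NULL)
    data.frame(gene_id = names(nz), subtype = cl, weight = unname(nz),
               coef = unname(model$models[[cl]]$w[names(nz)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), subtype = character(),
                      weight = numeric(), coef = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
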