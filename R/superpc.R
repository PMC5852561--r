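#' @importFrom mclust Mclust mclustBIC
NULL

# survival response for an endpoint, with row filtering for missing values
endpoint_surv <- function(clinical, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  tc <- if (endpoint == "OS") "os_time" else "rfs_time"
  ec <- if (endpoint == "OS") "os_event" else "rfs_event"
  if (!all(c(tc, ec) %in% names(clinical))) {
    stop("clinical table lacks ", tc, "/", ec, " columns")
  }
  ok <- !is.na(clinical[[tc]]) & !is.na(clinical[[ec]])
  list(surv = survival::Surv(clinical[[tc]][ok], clinical[[ec]][ok]),
       ok = ok, sample_id = clinical$sample_id[ok])
}

#' Per-gene univariate Cox proportional-hazards scores
#'
#' Fits one single-covariate Cox model per gene (Efron tie handling) of
#' the chosen survival endpoint on that gene's expression, and returns
#' the signed Wald z statistic ("Cox score"), hazard ratio with 95%
#' confidence interval, and p-value. Constant genes cannot be scored and
#' are flagged `excluded`.
#'
#' @param X features x samples matrix (signature genes).
#' @param clinical clinical table with `sample_id` and endpoint columns.
#' @param endpoint `"OS"` or `"RFS"`.
#' @return `data.frame`: `gene_id`, `coef`, `score` (Wald z), `hr`,
#'   `ci_low`, `ci_high`, `p`, `excluded`.
#' @export
univariate_cox_scores <- function(X, clinical, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  stopifnot(!is.null(colnames(X)))
  clinical <- clinical[match(colnames(X), clinical$sample_id), , drop = FALSE]
  es <- endpoint_surv(clinical, endpoint)
  if (sum(es$surv[, "status"]) == 0) stop("no events observed for ", endpoint)
  Xo <- X[, es$ok, drop = FALSE]
  res <- lapply(rownames(Xo), function(g) {
    x <- Xo[g, ]
    if (max(x) == min(x)) {
      return(data.frame(gene_id = g, coef = NA_real_, score = NA_real_,
                        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, excluded = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- survival::coxph(es$surv ~ x, ties = "efron")
    s <- summary(fit)
    data.frame(gene_id = g, coef = unname(coef(fit)),
               score = unname(s$coefficients[1, "z"]),
               hr = unname(s$conf.int[1, "exp(coef)"]),
               ci_low = unname(s$conf.int[1, "lower .95"]),
               ci_high = unname(s$conf.int[1, "upper .95"]),
               p = unname(s$coefficients[1, "Pr(>|z|)"]),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# PC1 risk machinery on a centered/scaled gene block
pc1_fit <- function(Xr) {
  ctr <- rowMeans(Xr)
  scl <- apply(Xr, 1, sd)
  scl[scl == 0] <- 1
  Z <- (Xr - ctr) / scl            # genes x samples
  sv <- svd(t(Z), nu = 0, nv = 1)  # loadings over genes, unit norm
  list(center = ctr, scale = scl, loadings = drop(sv$v))
}

pc1_scores <- function(pc, Xr) {
  Z <- (Xr - pc$center) / pc$scale
  drop(crossprod(Z, pc$loadings))
}

#' Fit a supervised principal-components survival model
#'
#' The superPC procedure: score every gene by its univariate Cox Wald z,
#' keep genes whose absolute score exceeds a threshold `tau`, and use the
#' first principal component of the surviving genes (centered/scaled on
#' training data) as a single continuous risk predictor. `tau` is chosen
#' from quantiles of the absolute scores by k-fold cross-validation,
#' maximizing the mean held-out Cox partial-likelihood ratio statistic of
#' the training-fold PC projected onto the held-out samples. The final
#' component is re-estimated on the full data; its sign is oriented so
#' that a larger risk score means a larger hazard.
#'
#' @param X features x samples matrix (the gene signature).
#' @param clinical clinical table.
#' @param endpoint `"OS"` or `"RFS"`.
#' @param threshold_grid candidate `tau` values; default the 0, 5, ...,
#'   95% quantiles of the absolute gene scores (20 values).
#' @param k_folds CV folds for threshold selection.
#' @param seed fold-assignment seed.
#' @return object of class `superpc_model`: `gene_scores` (univariate
#'   table), `threshold`, `retained_genes`, `loadings` (unit norm),
#'   `center`, `scale`, `sign`, `endpoint`, `cv_table`, and training
#'   `risk_scores`.
#' @export
fit_superpc <- function(X, clinical, endpoint = c("OS", "RFS"),
                        threshold_grid = NULL, k_folds = 10L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (nrow(X) < 2) stop("need at least 2 genes")
  clinical <- clinical[match(colnames(X), clinical$sample_id), , drop = FALSE]
  es <- endpoint_surv(clinical, endpoint)
  Xo <- X[, es$ok, drop = FALSE]
  clin_o <- clinical[es$ok, , drop = FALSE]
  uni <- univariate_cox_scores(Xo, clin_o, endpoint)
  absc <- abs(uni$score)
  absc[uni$excluded] <- 0
  if (is.null(threshold_grid)) {
    threshold_grid <- unique(quantile(absc, seq(0, 0.95, by = 0.05),
                                      names = FALSE))
  }
  threshold_grid <- sort(unique(threshold_grid))

  ev <- as.integer(es$surv[, "status"])
  folds <- make_stratified_folds(ifelse(ev == 1, "event", "censored"),
                                 k_folds, seed)
  cv_stat <- matrix(NA_real_, length(threshold_grid), k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (sum(ev[tr]) == 0 || sum(ev[!tr]) == 0) next
    uni_f <- univariate_cox_scores(Xo[, tr, drop = FALSE],
                                   clin_o[tr, , drop = FALSE], endpoint)
    absf <- abs(uni_f$score)
    absf[uni_f$excluded] <- 0
    surv_te <- survival::Surv(es$surv[!tr, "time"], es$surv[!tr, "status"])
    for (ti in seq_along(threshold_grid)) {
      keep <- absf > threshold_grid[ti]
      if (sum(keep) < 2) next
      pc <- pc1_fit(Xo[keep, tr, drop = FALSE])
      sc <- pc1_scores(pc, Xo[keep, !tr, drop = FALSE])
      if (max(sc) == min(sc)) next
      fit <- tryCatch(survival::coxph(surv_te ~ sc, ties = "efron"),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      cv_stat[ti, f] <- 2 * diff(fit$loglik)  # LR statistic on held-out fold
    }
  }
  mean_stat <- rowMeans(cv_stat, na.rm = TRUE)
  mean_stat[is.nan(mean_stat)] <- -Inf
  usable <- vapply(threshold_grid, function(t) sum(absc > t) >= 2, TRUE)
  mean_stat[!usable] <- -Inf
  if (all(!is.finite(mean_stat))) {
    stop("no threshold retains at least 2 genes with a usable CV fit")
  }
  tau <- threshold_grid[which.max(mean_stat)]
  retained <- uni$gene_id[absc > tau]
  pc <- pc1_fit(Xo[retained, , drop = FALSE])
  sc <- pc1_scores(pc, Xo[retained, , drop = FALSE])
  orient <- survival::coxph(es$surv ~ sc, ties = "efron")
  sgn <- if (unname(coef(orient)) < 0) -1 else 1
  structure(list(gene_scores = uni, threshold = tau,
                 retained_genes = retained,
                 loadings = setNames(sgn * pc$loadings, retained),
                 center = pc$center, scale = pc$scale, sign = sgn,
                 endpoint = endpoint,
                 cv_table = data.frame(tau = threshold_grid,
                                       mean_cv_stat = mean_stat),
                 risk_scores = setNames(sgn * sc, es$sample_id),
                 seed = seed),
            class = "superpc_model")
}

#' @export
print.superpc_model <- function(x, ...) {
  cat(sprintf(
    "superPC (%s): %d of %d genes retained at |z| > %.3g; PC1 risk score\n",
    x$endpoint, length(x$retained_genes), nrow(x$gene_scores), x$threshold))
  invisible(x)
}

#' Risk scores from a fitted superPC model
#'
#' Projects samples onto the supervised first principal component:
#' `score = loadings' * (x - center) / scale` over the retained genes,
#' oriented so a higher score means a higher hazard on training data.
#'
#' @param model fitted `superpc_model`.
#' @param X features x samples matrix containing all retained genes.
#' @return named numeric vector of risk scores.
#' @export
risk_scores <- function(model, X) {
  stopifnot(inherits(model, "superpc_model"))
  missing <- setdiff(model$retained_genes, rownames(X))
  if (length(missing) > 0) {
    stop("retained gene(s) missing from X: ",
         paste(head(missing, 5), collapse = ", "))
  }
  Xr <- X[model$retained_genes, , drop = FALSE]
  Z <- (Xr - model$center) / model$scale
  setNames(drop(crossprod(Z, model$loadings)), colnames(X))
}

#' Split risk scores into high and low groups by a Gaussian mixture
#'
#' Fits a two-component univariate normal mixture to the risk scores by
#' EM (\pkg{mclust}) and places the cutoff where the two components'
#' posterior probabilities are equal, between the component means. The
#' component with the larger mean is the high-risk group. Degenerate
#' fits (a component holding fewer than 2 samples) fall back to a median
#' split with a warning.
#'
#' @param scores numeric vector of risk scores (>= 10, non-constant).
#' @return object of class `risk_grouping`: `means`, `variances`,
#'   `weights`, `cutoff`, `group` (factor high/low per sample),
#'   `fallback`.
#' @export
split_risk_groups <- function(scores) {
  if (length(scores) < 10) stop("need at least 10 samples")
  if (max(scores) == min(scores)) stop("risk scores are constant")
  fit <- tryCatch(
    suppressWarnings(Mclust(scores, G = 2, modelNames = c("E", "V"),
                            verbose = FALSE)),
    error = function(e) NULL)
  degenerate <- is.null(fit) || min(table(fit$classification)) < 2 ||
    min(fit$parameters$variance$sigmasq) <= 0 ||
    diff(range(fit$parameters$mean)) == 0
  if (degenerate) {
    warning("degenerate mixture fit; falling back to a median split")
    cutoff <- median(scores)
    grp <- setNames(factor(ifelse(scores > cutoff, "high", "low"),
                           c("low", "high")), names(scores))
    return(structure(list(means = NULL, variances = NULL, weights = NULL,
                          cutoff = cutoff, group = grp, fallback = TRUE),
                     class = "risk_grouping"))
  }
  mu <- fit$parameters$mean
  va <- fit$parameters$variance$sigmasq
  if (length(va) == 1) va <- rep(va, 2)
  pr <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; va <- va[o]; pr <- pr[o]
  post_diff <- function(x) {
    pr[1] * dnorm(x, mu[1], sqrt(va[1])) - pr[2] * dnorm(x, mu[2], sqrt(va[2]))
  }
  cutoff <- tryCatch(
    uniroot(post_diff, lower = mu[1], upper = mu[2], tol = 1e-10)$root,
    error = function(e) mean(mu))
  grp <- setNames(factor(ifelse(scores > cutoff, "high", "low"),
                         c("low", "high")), names(scores))
  structure(list(means = unname(mu), variances = unname(va),
                 weights = unname(pr), cutoff = cutoff, group = grp,
                 fallback = FALSE),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("risk grouping: cutoff %.3g; %d low / %d high%s\n",
              x$cutoff, sum(x$group == "low"), sum(x$group == "high"),
              if (x$fallback) " (median-split fallback)" else ""))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for risk groups
#'
#' @param groups factor of group labels per sample (e.g., from
#'   [split_risk_groups()]), named by sample or aligned with `clinical`.
#' @param clinical clinical table.
#' @param endpoint `"OS"` or `"RFS"`.
#' @return list with `fit` (a [survival::survfit] object), `p` (two-sided
#'   log-rank p-value, `NA` with a warning when the test is undefined),
#'   `table` (per-group n and events).
#' @export
km_logrank <- function(groups, clinical, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  if (!is.null(names(groups))) {
    clinical <- clinical[match(names(groups), clinical$sample_id), ,
                         drop = FALSE]
  }
  stopifnot(length(groups) == nrow(clinical))
  es <- endpoint_surv(clinical, endpoint)
  g <- factor(groups[es$ok])
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 non-empty groups")
  df <- data.frame(time = es$surv[, "time"], status = es$surv[, "status"],
                   group = droplevels(g))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df)
  p <- tryCatch({
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
    pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }, error = function(e) {
    warning("log-rank test undefined: ", conditionMessage(e))
    NA_real_
  })
  tab <- data.frame(group = levels(df$group),
                    n = as.integer(table(df$group)),
                    events = as.integer(tapply(df$status, df$group, sum)))
  list(fit = fit, p = p, table = tab)
}

#' Cox proportional-hazards fit with explained variation
#'
#' Fits a Cox model (Efron ties) of the chosen endpoint on one or more
#' covariates, reporting per-covariate hazard ratios with 95% confidence
#' intervals and Wald p-values, plus the likelihood-ratio explained
#' variation \eqn{R^2 = 1 - \exp(-LR/n)}. Rows with missing covariates
#' are dropped complete-case with a logged count.
#'
#' @param covariates numeric vector (univariate) or `data.frame` of
#'   covariates, aligned with `clinical` rows or matched by names /
#'   rownames against `sample_id`.
#' @param clinical clinical table.
#' @param endpoint `"OS"` or `"RFS"`.
#' @param reference_levels named list: reference level per categorical
#'   covariate (defaults: first level alphabetically unless given).
#' @return object of class `cox_summary`: `table` (term, hr, ci_low,
#'   ci_high, p), `r_squared`, `lr_statistic`, `p_lr`, `n_used`,
#'   `n_dropped`, `fit`.
#' @export
cox_with_r2 <- function(covariates, clinical, endpoint = c("OS", "RFS"),
                        reference_levels = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.data.frame(covariates)) {
    nm <- names(covariates)
    covariates <- data.frame(risk = covariates, stringsAsFactors = FALSE)
    if (!is.null(nm)) rownames(covariates) <- nm
  }
  if (!is.null(rownames(covariates)) &&
      all(rownames(covariates) %in% clinical$sample_id)) {
    clinical <- clinical[match(rownames(covariates), clinical$sample_id), ,
                         drop = FALSE]
  }
  stopifnot(nrow(covariates) == nrow(clinical))
  es <- endpoint_surv(clinical, endpoint)
  cov_o <- covariates[es$ok, , drop = FALSE]
  for (j in names(cov_o)) {
    if (is.character(cov_o[[j]])) cov_o[[j]] <- factor(cov_o[[j]])
    if (is.factor(cov_o[[j]]) && !is.null(reference_levels[[j]])) {
      cov_o[[j]] <- stats::relevel(cov_o[[j]], ref = reference_levels[[j]])
    }
  }
  cc <- stats::complete.cases(cov_o)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    log_msg("cox_with_r2: dropped %d incomplete row(s)", n_dropped)
  }
  df <- cov_o[cc, , drop = FALSE]
  df$.time <- es$surv[cc, "time"]
  df$.status <- es$surv[cc, "status"]
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", setdiff(names(df), c(".time", ".status"))),
          collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) || anyNA(coef(fit))) {
    stop("Cox model did not converge cleanly; check covariates")
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = unname(s$conf.int[, "exp(coef)"]),
                    ci_low = unname(s$conf.int[, "lower .95"]),
                    ci_high = unname(s$conf.int[, "upper .95"]),
                    p = unname(s$coefficients[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  n <- fit$n
  lr <- 2 * diff(fit$loglik)
  structure(list(table = tab, r_squared = 1 - exp(-lr / n),
                 lr_statistic = unname(lr),
                 p_lr = pchisq(unname(lr), df = length(coef(fit)),
                               lower.tail = FALSE),
                 n_used = n, n_dropped = n_dropped, fit = fit),
            class = "cox_summary")
}

#' @export
print.cox_summary <- function(x, ...) {
  cat(sprintf("Cox PH fit, n = %d (%d dropped), R^2 = %.3f, LR p = %.3g\n",
              x$n_used, x$n_dropped, x$r_squared, x$p_lr))
  print(transform(x$table, hr = round(hr, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2), p = signif(p, 2)))
  invisible(x)
}

#' Top prognostic genes of a superPC model
#'
#' Genes whose univariate Cox coefficient exceeds `coef_threshold` in
#' absolute value, ranked by decreasing absolute Cox score. With the
#' default `coef_threshold = 0` every scored signature gene is returned,
#' ranked.
#'
#' @param model fitted `superpc_model` (its univariate table is used), or
#'   a univariate score table from [univariate_cox_scores()].
#' @param coef_threshold minimum `|coef|`.
#' @return ranked `data.frame` subset of the univariate table.
#' @export
top_prognostic_genes <- function(model, coef_threshold = 0) {
  uni <- if (inherits(model, "superpc_model")) model$gene_scores else model
  stopifnot(is.data.frame(uni), all(c("gene_id", "coef", "score") %in%
                                      names(uni)))
  keep <- !is.na(uni$coef) & abs(uni$coef) > coef_threshold
  out <- uni[keep, , drop = FALSE]
  out <- out[order(-abs(out$score)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
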