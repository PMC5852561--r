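# small survival cohort with one planted prognostic gene
surv_fixture <- function(n = 300, beta = 1, seed = 1, censor = 0.3,
                         p_null = 9) {
  set.seed(seed)
  p <- p_null + 1
  X <- matrix(2^rnorm(p * n, 4, 1), p, n,
              dimnames = list(c("hit", paste0("null", seq_len(p_null))),
                              sprintf("s%03d", seq_len(n))))
  z <- as.numeric(scale(X["hit", ]))
  tt <- rexp(n, rate = 0.05 * exp(beta * z))
  if (censor > 0) {
    u <- uniroot(function(u) mean(1 - pmin(tt / u, 1)) - censor,
                 c(1e-6, 1e6))$root
    cc <- runif(n, 0, u)
  } else {
    cc <- rep(Inf, n)
  }
  clinical <- data.frame(sample_id = colnames(X),
                         os_time = pmin(tt, cc),
                         os_event = as.integer(tt <= cc),
                         rfs_time = pmin(tt, cc),
                         rfs_event = as.integer(tt <= cc),
                         stringsAsFactors = FALSE)
  list(X = X, clinical = clinical, z = z)
}

test_that("per-gene Cox fits match a hand-written Efron partial likelihood", {
  fx <- surv_fixture(n = 40, beta = 0.8, seed = 5)
  uni <- univariate_cox_scores(fx$X, fx$clinical, "OS")
  g <- fx$X["hit", ]
  hand <- optimize(efron_neg_loglik, c(-5, 5),
                   time = fx$clinical$os_time,
                   status = fx$clinical$os_event, x = g, tol = 1e-9)
  expect_equal(uni$coef[uni$gene_id == "hit"], hand$minimum,
               tolerance = 1e-4)
})

test_that("univariate Cox recovers a planted hazard ratio", {
  hrs <- vapply(1:5, function(s) {
    fx <- surv_fixture(n = 300, beta = 1, seed = s)
    # standardize genes so the fitted HR is per SD, on the e^beta scale
    uni <- univariate_cox_scores(t(scale(t(fx$X))), fx$clinical, "OS")
    uni$hr[uni$gene_id == "hit"]
  }, 0)
  expect_gt(mean(hrs), 2.0)
  expect_lt(mean(hrs), 3.7)
})

test_that("constant genes are excluded and zero events are an error", {
  fx <- surv_fixture(n = 50, seed = 2)
  fx$X["null1", ] <- 3
  uni <- univariate_cox_scores(fx$X, fx$clinical, "OS")
  expect_true(uni$excluded[uni$gene_id == "null1"])
  expect_true(is.na(uni$score[uni$gene_id == "null1"]))
  fx$clinical$os_event <- 0L
  expect_error(univariate_cox_scores(fx$X, fx$clinical, "OS"), "no events")
})

test_that("superPC with a vacuous threshold equals plain PC1 Cox", {
  fx <- surv_fixture(n = 120, beta = 0.8, seed = 7)
  model <- fit_superpc(fx$X, fx$clinical, "OS", threshold_grid = 0,
                       k_folds = 5, seed = 1)
  expect_setequal(model$retained_genes, rownames(fx$X))
  sc <- risk_scores(model, fx$X)
  Z <- t(scale(t(fx$X)))  # genes x samples, centered/scaled per gene
  pc1 <- prcomp(t(Z), center = FALSE, scale. = FALSE)$x[, 1]
  expect_gt(abs(cor(sc, pc1)), 0.999)
})

test_that("a dominant single gene drives the risk score when tau is high", {
  fx <- surv_fixture(n = 200, beta = 1.5, seed = 3)
  model <- fit_superpc(fx$X, fx$clinical, "OS", k_folds = 5, seed = 1)
  sc <- risk_scores(model, fx$X)
  expect_true("hit" %in% model$retained_genes)
  if (length(model$retained_genes) == 1) {
    expect_gt(abs(cor(sc, fx$X["hit", ])), 0.99)
  }
  # orientation: higher score, higher hazard on training data
  cf <- survival::coxph(survival::Surv(fx$clinical$os_time,
                                       fx$clinical$os_event) ~ sc)
  expect_gte(unname(coef(cf)), 0)
})

test_that("risk scores are centered on training data and per-sample", {
  fx <- surv_fixture(n = 150, beta = 1, seed = 11)
  model <- fit_superpc(fx$X, fx$clinical, "OS", k_folds = 5, seed = 2)
  sc <- risk_scores(model, fx$X)
  expect_lt(abs(mean(sc)), 1e-8)
  X2 <- cbind(fx$X, dup = fx$X[, 3])
  colnames(X2)[ncol(X2)] <- "dup"
  sc2 <- risk_scores(model, X2)
  expect_equal(unname(sc2["dup"]), unname(sc2[3]))
  expect_error(risk_scores(model, fx$X[-1, , drop = FALSE]), "missing")
})

test_that("mixture risk grouping finds the between-mode cutoff", {
  set.seed(13)
  scores <- c(rnorm(200, 0, 1), rnorm(200, 10, 1))
  grp <- split_risk_groups(scores)
  expect_false(grp$fallback)
  expect_gt(grp$cutoff, 2.5)
  expect_lt(grp$cutoff, 7.5)
  truth <- rep(c("low", "high"), each = 200)
  expect_gte(mean(as.character(grp$group) == truth), 0.99)
  # cutoff strictly between component means; groups partition the cohort
  expect_true(grp$means[1] < grp$cutoff && grp$cutoff < grp$means[2])
  expect_equal(sum(table(grp$group)), 400)
})

test_that("a symmetric mixture is cut near zero", {
  set.seed(17)
  scores <- c(rnorm(300, -3, 1), rnorm(300, 3, 1))
  grp <- split_risk_groups(scores)
  expect_lt(abs(grp$cutoff), 0.2)
})

test_that("degenerate risk-score inputs are handled", {
  expect_error(split_risk_groups(rep(1, 50)), "constant")
  expect_error(split_risk_groups(rnorm(5)), "at least 10")
})

test_that("log-rank separates a planted 3x hazard difference", {
  set.seed(21)
  n <- 200
  tt <- c(rexp(n, 0.05), rexp(n, 0.15))
  clinical <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n)),
                         os_time = tt, os_event = 1L,
                         stringsAsFactors = FALSE)
  groups <- setNames(rep(c("low", "high"), each = n), clinical$sample_id)
  km <- km_logrank(groups, clinical, "OS")
  expect_lt(km$p, 0.001)
  expect_equal(sum(km$table$n), 2 * n)
  expect_error(km_logrank(setNames(rep("low", 2 * n), clinical$sample_id),
                          clinical, "OS"),
               "2 non-empty groups")
})

test_that("Cox summaries report HR, CI, p and explained variation", {
  set.seed(23)
  n <- 500
  grp <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(log(2.5) * grp))
  clinical <- data.frame(sample_id = sprintf("s%03d", 1:n),
                         os_time = tt, os_event = 1L,
                         stringsAsFactors = FALSE)
  cs <- cox_with_r2(setNames(ifelse(grp == 1, "high", "low"),
                             clinical$sample_id),
                    clinical, "OS", reference_levels = list(risk = "low"))
  expect_gt(cs$table$hr, 2.1)
  expect_lt(cs$table$hr, 3.0)
  expect_true(cs$table$ci_low <= cs$table$hr &
                cs$table$hr <= cs$table$ci_high)
  expect_gte(cs$r_squared, 0)
  expect_lt(cs$r_squared, 1)
  # an uninformative covariate explains (almost) nothing
  cs0 <- cox_with_r2(setNames(rnorm(n), clinical$sample_id), clinical, "OS")
  expect_lt(cs0$r_squared, 0.02)
})

test_that("multivariate fits drop incomplete rows and honor references", {
  sim <- gen_cohort(sim_spec(n_samples = 150, n_genes = 60, seed = 8))
  clin <- sim$clinical
  clin$age[1:5] <- NA
  covs <- data.frame(risk = rnorm(150), age = clin$age, stage = clin$stage,
                     row.names = clin$sample_id)
  cs <- cox_with_r2(covs, clin, "OS",
                    reference_levels = list(stage = "T1"))
  expect_equal(cs$n_dropped, 5)
  expect_true(any(grepl("stageT2", cs$table$term)))
  expect_false(any(grepl("stageT1$", cs$table$term)))
})

test_that("top prognostic genes are ranked by absolute Cox score", {
  fx <- surv_fixture(n = 200, beta = 1.2, seed = 31)
  model <- fit_superpc(fx$X, fx$clinical, "OS", k_folds = 5, seed = 1)
  top <- top_prognostic_genes(model, coef_threshold = 0)
  expect_equal(top$gene_id[1], "hit")
  expect_true(all(diff(abs(top$score)) <= 1e-12))
  none <- top_prognostic_genes(model,
                               coef_threshold = max(abs(top$coef)) + 1)
  expect_equal(nrow(none), 0)
})
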