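#' Specification of a synthetic cohort
#'
#' Describes a simulated expression/survival cohort with the structure the
#' selection pipeline assumes: a large null background of log-normal
#' genes, a few subtype-discriminative genes per class (mean shift on the
#' log scale in SD units), lncRNA-like genes at systematically lower
#' expression with biotypes/lengths spanning the 200 bp filter boundary,
#' exponential survival driven by a small planted prognostic set with
#' uniform censoring, and IHC marker status drawn conditionally on the
#' subtype.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_classes number of subtype classes (default 4; the first four
#'   take the canonical names Basal, Her2, LumA, LumB).
#' @param class_proportions class mixing proportions (sum to 1).
#' @param n_informative_per_class planted discriminative genes per class.
#' @param effect_size class mean shift, in units of the log-scale SD.
#' @param lnc_fraction fraction of genes flagged as long non-coding-like.
#' @param lnc_expression_scale multiplicative down-scaling (< 1) applied
#'   to lnc-like genes, mimicking their lower expression.
#' @param n_prognostic planted survival-associated genes (drawn from the
#'   informative set so they survive selection).
#' @param marker_penetrance probability that an informative gene's class
#'   shift is expressed in a given sample of its class; markers of a
#'   subtype are not uniformly expressed across its tumors, which is the
#'   redundancy that makes multi-gene panels necessary.
#' @param hazard_betas log-hazard coefficients for the prognostic genes
#'   (per SD of normalized expression); recycled to `n_prognostic`.
#' @param censoring_rate target fraction censored, in \[0, 1).
#' @param frailty_sd SD of the shared log-frailty coupling OS and RFS.
#' @param ihc_concordance matrix of P(IHC category | subtype): one row
#'   per class, columns `ER-/PR-/HER2-`, `ER-/PR-/HER2+`, `ER+/PR+/HER2`;
#'   rows must sum to <= 1 (remainder = no usable status).
#' @param seed master RNG seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 200L, n_genes = 500L, n_classes = 4L,
                     class_proportions = NULL,
                     n_informative_per_class = 10L, effect_size = 2,
                     lnc_fraction = 0.5, lnc_expression_scale = 0.1,
                     n_prognostic = 5L, marker_penetrance = 0.6,
                     hazard_betas = c(0.5, 1.0),
                     censoring_rate = 0.3, frailty_sd = 0.5,
                     ihc_concordance = NULL, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  if (lnc_expression_scale <= 0) stop("lnc_expression_scale must be > 0")
  if (marker_penetrance <= 0 || marker_penetrance > 1) {
    stop("marker_penetrance must be in (0, 1]")
  }
  if (n_informative_per_class * n_classes > n_genes) {
    stop("more planted informative genes than genes in total")
  }
  classes <- if (n_classes <= 4) SUBTYPE_LEVELS[seq_len(n_classes)] else
    c(SUBTYPE_LEVELS, paste0("Class", seq_len(n_classes - 4)))
  if (is.null(ihc_concordance)) {
    ihc_concordance <- default_ihc_concordance(classes)
  }
  if (!all(rowSums(ihc_concordance) <= 1 + 1e-8) ||
      any(ihc_concordance < 0)) {
    stop("ihc_concordance rows must be probabilities summing to <= 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), n_classes = n_classes,
                 classes = classes,
                 class_proportions = class_proportions,
                 n_informative_per_class = as.integer(n_informative_per_class),
                 effect_size = effect_size, lnc_fraction = lnc_fraction,
                 lnc_expression_scale = lnc_expression_scale,
                 n_prognostic = as.integer(n_prognostic),
                 marker_penetrance = marker_penetrance,
                 hazard_betas = rep_len(hazard_betas, n_prognostic),
                 censoring_rate = censoring_rate, frailty_sd = frailty_sd,
                 ihc_concordance = ihc_concordance, seed = as.integer(seed)),
            class = "sim_spec")
}

# clinically motivated default P(IHC category | subtype); Basal is mostly
# triple negative, luminal subtypes mostly ER+/PR+
default_ihc_concordance <- function(classes) {
  base <- rbind(Basal = c(0.90, 0.05, 0.03),
                Her2  = c(0.10, 0.70, 0.15),
                LumA  = c(0.02, 0.03, 0.90),
                LumB  = c(0.03, 0.10, 0.82))
  m <- matrix(1 / 3, length(classes), 3,
              dimnames = list(classes,
                              c("ER-/PR-/HER2-", "ER-/PR-/HER2+",
                                "ER+/PR+/HER2")))
  known <- intersect(classes, rownames(base))
  m[known, ] <- base[known, ]
  m
}

#' Generate a synthetic expression cohort
#'
#' Background expression is log-normal: log2 values are N(mu_g, sd_g)
#' with per-gene baselines mu_g ~ N(4, 1) and dispersions
#' sd_g ~ U(1.5, 2.5), the overdispersed regime typical of bulk RNA-seq
#' across tumors. Each class's informative genes get a
#' +`effect_size * sd_g` shift (i.e., `effect_size` in SD units on the
#' log scale) in samples of that class, expressed per sample with
#' probability `marker_penetrance`. lnc-flagged genes are multiplied by
#' `lnc_expression_scale` on
#' the expression scale (a location shift in log space, preserving shape)
#' and receive long non-coding biotypes with lengths straddling the
#' 200 bp boundary; the remaining genes are protein_coding, plus a few
#' miRNA-like short features among the nulls to exercise the filter.
#'
#' @param spec a [sim_spec()].
#' @param seed optional override of `spec$seed`.
#' @return list with `expr` (genes x samples matrix), `labels` (named
#'   character), `annotation` (as from [read_annotation()]), `truth`
#'   (list: `informative` per class, `lnc_genes`, `prognostic`,
#'   `betas`).
#' @export
gen_expression <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_samples; p <- spec$n_genes; K <- spec$n_classes
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(p))
    samples <- sprintf("S%04d", seq_len(n))
    labels <- sample(spec$classes, n, replace = TRUE,
                     prob = spec$class_proportions)
    # guarantee every class is represented
    for (k in seq_len(K)) {
      if (!spec$classes[k] %in% labels) labels[k] <- spec$classes[k]
    }
    names(labels) <- samples

    mu <- rnorm(p, 4, 1)
    sd_g <- runif(p, 1.5, 2.5)
    logx <- matrix(rnorm(p * n, mu, sd_g), p, n)
    informative <- split(
      genes[seq_len(spec$n_informative_per_class * K)],
      rep(spec$classes, each = spec$n_informative_per_class))
    informative <- informative[spec$classes]
    for (k in seq_len(K)) {
      gidx <- match(informative[[k]], genes)
      sidx <- which(labels == spec$classes[k])
      on <- matrix(rbinom(length(gidx) * length(sidx), 1,
                          spec$marker_penetrance),
                   length(gidx), length(sidx))
      logx[gidx, sidx] <- logx[gidx, sidx] +
        on * (spec$effect_size * sd_g[gidx])
    }
    expr <- 2^logx
    dimnames(expr) <- list(genes, samples)

    # lnc-like block: scaled down, long-non-coding biotypes, lengths
    # spanning the 200 bp rule; planted genes keep lengths >= 200
    n_lnc <- round(spec$lnc_fraction * p)
    planted <- unlist(informative, use.names = FALSE)
    lnc_genes <- sample(genes, n_lnc)
    expr[lnc_genes, ] <- expr[lnc_genes, ] * spec$lnc_expression_scale
    biotype <- rep("protein_coding", p)
    names(biotype) <- genes
    biotype[lnc_genes] <- sample(LNC_BIOTYPES, n_lnc, replace = TRUE)
    length_bp <- setNames(sample(500:5000, p, replace = TRUE), genes)
    short_pool <- setdiff(lnc_genes, planted)
    n_short <- min(length(short_pool), max(3L, round(0.1 * n_lnc)))
    if (n_short > 0) {
      short <- sample(short_pool, n_short)
      length_bp[short] <- sample(c(120:199, 200, 201), n_short,
                                 replace = TRUE)
    }
    null_pcg <- setdiff(genes[biotype == "protein_coding"], planted)
    n_mirna <- min(length(null_pcg), max(2L, round(0.02 * p)))
    if (n_mirna > 0) {
      mir <- sample(null_pcg, n_mirna)
      biotype[mir] <- "miRNA"
      length_bp[mir] <- sample(60:120, n_mirna, replace = TRUE)
    }
    start <- sample(1e4:1e6, p)
    annotation <- data.frame(gene_id = genes, biotype = unname(biotype),
                             chrom = sample(paste0("chr", 1:22), p,
                                            replace = TRUE),
                             start = start,
                             end = start + unname(length_bp) - 1L,
                             length_bp = unname(length_bp),
                             is_coding = unname(biotype) == "protein_coding",
                             stringsAsFactors = FALSE)
    prognostic <- sample(planted, min(spec$n_prognostic, length(planted)))
    truth <- list(informative = informative, lnc_genes = lnc_genes,
                  prognostic = prognostic,
                  betas = setNames(spec$hazard_betas[seq_along(prognostic)],
                                   prognostic),
                  labels = labels)
    list(expr = expr, labels = labels, annotation = annotation,
         truth = truth)
  })
}

#' Generate survival and clinical covariates for a synthetic cohort
#'
#' Event times are exponential with log-hazard
#' `sum_g beta_g * z_g + frailty`, where `z_g` is the standardized
#' (max-normalized) expression of planted prognostic gene `g` and the
#' shared log-normal frailty couples OS and RFS (RFS runs on a faster
#' baseline). Censoring is independent Uniform(0, u) with `u` solved so
#' the expected censored fraction matches `censoring_rate`. Demographic
#' and treatment covariates are drawn independently of survival.
#'
#' @param expr expression matrix from [gen_expression()].
#' @param truth truth list from [gen_expression()].
#' @param spec the [sim_spec()] used.
#' @param seed RNG seed (default derived from `spec$seed`).
#' @return clinical `data.frame`: `sample_id`, `os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`, `age`, `race`, `treatment`, `stage`,
#'   `histology` (ER/PR/HER2 added by [gen_ihc()]).
#' @export
gen_survival <- function(expr, truth, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- ncol(expr)
  prog <- truth$prognostic
  stopifnot(all(prog %in% rownames(expr)))
  with_seed(seed, {
    Z <- max_normalize(expr[prog, , drop = FALSE])
    Z <- t(scale(t(Z)))
    lp <- drop(crossprod(Z, truth$betas[prog]))
    frailty <- rnorm(n, 0, spec$frailty_sd)
    eta_os <- lp + frailty
    eta_rfs <- lp + frailty
    if (any(abs(eta_os) > 30)) stop("hazard overflow: extreme betas")
    t_os <- rexp(n, rate = 0.02 * exp(eta_os)) * 365
    t_rfs <- rexp(n, rate = 0.03 * exp(eta_rfs)) * 365
    censor1 <- function(tt, q) {
      if (q <= 0) {
        return(list(time = tt, event = rep(1L, length(tt))))
      }
      # with C ~ U(0, u): P(censored | T_i) = P(C < T_i) = min(T_i, u)/u,
      # so the expected censored fraction is mean(pmin(T/u, 1))
      f <- function(u) mean(pmin(tt / u, 1)) - q
      u <- uniroot(f, lower = min(tt) * 1e-6, upper = max(tt) * 1e6,
                   tol = 1e-8)$root
      cc <- runif(length(tt), 0, u)
      list(time = pmin(tt, cc), event = as.integer(tt <= cc))
    }
    os <- censor1(t_os, spec$censoring_rate)
    rfs <- censor1(t_rfs, spec$censoring_rate)
    data.frame(
      sample_id = colnames(expr),
      os_time = os$time, os_event = os$event,
      rfs_time = rfs$time, rfs_event = rfs$event,
      age = round(rnorm(n, 58, 12)),
      race = sample(c("White", "Black", "Asian"), n, TRUE,
                    prob = c(0.7, 0.2, 0.1)),
      treatment = sample(c("Untreated or other", "Chemotherapy",
                           "Radiation therapy", "Hormone therapy"), n, TRUE),
      stage = sample(paste0("T", 1:4), n, TRUE,
                     prob = c(0.3, 0.45, 0.15, 0.1)),
      histology = sample(c("Infiltrating Ductal Carcinoma",
                           "Infiltrating Lobular Carcinoma",
                           "Mixed Histology"), n, TRUE,
                         prob = c(0.75, 0.15, 0.1)),
      stringsAsFactors = FALSE)
  })
}

#' Generate IHC marker status conditional on subtype
#'
#' Draws one of the three IHC categories (or none) per sample from
#' `spec$ihc_concordance` and converts it to ER/PR/HER2 status strings.
#'
#' @param labels named subtype vector.
#' @param spec the [sim_spec()] used.
#' @param seed RNG seed.
#' @return `data.frame`: `sample_id`, `er`, `pr`, `her2`.
#' @export
gen_ihc <- function(labels, spec, seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "sim_spec"))
  P <- spec$ihc_concordance
  if (any(P < 0) || any(rowSums(P) > 1 + 1e-8)) {
    stop("invalid ihc_concordance probabilities")
  }
  with_seed(seed, {
    cats <- colnames(P)
    draw <- vapply(as.character(labels), function(cl) {
      pr <- if (cl %in% rownames(P)) P[cl, ] else rep(1 / 3, 3)
      sample(c(cats, "none"), 1, prob = c(pr, max(0, 1 - sum(pr))))
    }, "")
    er <- pr_ <- her2 <- rep(NA_character_, length(labels))
    er[draw == "ER-/PR-/HER2-"] <- "-"
    pr_[draw == "ER-/PR-/HER2-"] <- "-"
    her2[draw == "ER-/PR-/HER2-"] <- "-"
    er[draw == "ER-/PR-/HER2+"] <- "-"
    pr_[draw == "ER-/PR-/HER2+"] <- "-"
    her2[draw == "ER-/PR-/HER2+"] <- "+"
    pos <- draw == "ER+/PR+/HER2"
    er[pos] <- "+"
    pr_[pos] <- "+"
    her2[pos] <- sample(c("+", "-"), sum(pos), replace = TRUE)
    data.frame(sample_id = names(labels), er = er, pr = pr_, her2 = her2,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [gen_expression()], [gen_survival()] and
#' [gen_ihc()] and merging the clinical columns.
#'
#' @param spec a [sim_spec()].
#' @return list with `expr`, `labels`, `annotation`, `clinical`
#'   (including ER/PR/HER2), `truth`.
#' @export
gen_cohort <- function(spec) {
  g <- gen_expression(spec)
  clinical <- gen_survival(g$expr, g$truth, spec)
  ihc <- gen_ihc(g$labels, spec)
  clinical <- merge(clinical, ihc, by = "sample_id", sort = FALSE)
  clinical <- clinical[match(colnames(g$expr), clinical$sample_id), ]
  rownames(clinical) <- NULL
  list(expr = g$expr, labels = g$labels, annotation = g$annotation,
       clinical = clinical, truth = g$truth)
}
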