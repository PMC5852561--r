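# Independent convex-programming oracle for the sparse squared-hinge SVM:
# epigraph QP over z = (w+, w-, b, s),
#   min C s's + (1-C) 1'(w+ + w-)   s.t.  y_i(x_i'(w+-w-) + b) + s_i >= 1,
#                                          s >= 0, w+- >= 0,
# solved with quadprog (a 1e-8 ridge on the w/b block makes the Hessian
# positive definite; the perturbation is far below the tolerances used).
oracle_l1svm <- function(X, y, C, ridge = 1e-8) {
  n <- nrow(X)
  p <- ncol(X)
  m <- 2 * p + 1 + n
  D <- diag(rep(ridge, m))
  D[(2 * p + 2):m, (2 * p + 2):m] <- diag(2 * C, n)
  d <- c(rep(-(1 - C), 2 * p), 0, rep(0, n))
  Yx <- X * y
  A1 <- cbind(Yx, -Yx, y, diag(n))
  A2 <- cbind(matrix(0, n, 2 * p), 0, diag(n))
  A3 <- cbind(diag(2 * p), 0, matrix(0, 2 * p, n))
  sol <- quadprog::solve.QP(D, d, t(rbind(A1, A2, A3)),
                            c(rep(1, n), rep(0, n + 2 * p)))
  z <- sol$solution
  w <- z[1:p] - z[(p + 1):(2 * p)]
  b <- z[2 * p + 1]
  h <- pmax(0, 1 - y * (drop(X %*% w) + b))
  list(w = w, b = b, objective = C * sum(h^2) + (1 - C) * sum(abs(w)))
}

# random small binary SVM instance
random_svm_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:20, 1)
  p <- sample(2:10, 1)
  X <- matrix(rnorm(n * p), n, p)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(X = X, y = y)
}

# hand-written Cox negative log partial likelihood (Efron ties), used as
# an independent check of the per-gene Cox fits at tiny n
efron_neg_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  ll <- 0
  for (t in unique(time[status == 1])) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    m <- length(D)
    sum_r <- sum(exp(eta[R]))
    sum_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(m) - 1) {
      ll <- ll - log(sum_r - (l / m) * sum_d)
    }
  }
  -ll
}
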