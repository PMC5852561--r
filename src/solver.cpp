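// Proximal-gradient (FISTA) solver for the sparse squared-hinge SVM
//
//   min_{w,b}  C * sum_i max(0, 1 - y_i (x_i' w + b))^2  +  (1 - C) * P(w)
//
// with P(w) = ||w||_1 (feature selection) or ||w||_2^2 (evaluation
// classifier).  The intercept b is never penalized.  The squared hinge is
// C^1-smooth, so accelerated proximal gradient with backtracking and
// adaptive restart converges at the usual O(1/k^2) rate; the L1 prox is a
// soft threshold on w only.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// smooth part of the objective at (w, b); penalty_l2 adds the ridge term
static double smooth_obj(const mat& X, const vec& y, const vec& w, double b,
                         double C, bool penalty_l2) {
  vec h = 1.0 - y % (X * w + b);
  h.transform([](double v) { return v > 0.0 ? v : 0.0; });
  double val = C * dot(h, h);
  if (penalty_l2) val += (1.0 - C) * dot(w, w);
  return val;
}

static void smooth_grad(const mat& X, const vec& y, const vec& w, double b,
                        double C, bool penalty_l2, vec& gw, double& gb,
                        double& fval) {
  vec h = 1.0 - y % (X * w + b);
  h.transform([](double v) { return v > 0.0 ? v : 0.0; });
  vec hy = h % y;
  gw = -2.0 * C * (X.t() * hy);
  gb = -2.0 * C * accu(hy);
  fval = C * dot(h, h);
  if (penalty_l2) {
    gw += 2.0 * (1.0 - C) * w;
    fval += (1.0 - C) * dot(w, w);
  }
}

static inline double soft(double v, double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// [[Rcpp::export(name = ".svm_solve_cpp")]]
Rcpp::List svm_solve_cpp(const arma::mat& X,      // samples x features
                         const arma::vec& y,      // +1 / -1
                         double C,
                         bool penalty_l1,
                         const arma::vec& w0,
                         double b0,
                         int max_iter,
                         double tol) {
  const uword p = X.n_cols;
  const bool l2 = !penalty_l1;
  const double lam = (1.0 - C);  // L1 weight (prox step)

  vec w = w0, wv = w0;
  double b = b0, bv = b0;

  // Lipschitz upper bound for grad of C*sum h^2 over (w,b):
  // 2C * ||[X 1]||_2^2 <= 2C * (||X||_F^2 + n); backtracking refines it.
  double L = 2.0 * C * (accu(square(X)) + (double)X.n_rows);
  if (L < 1e-12) L = 1e-12;

  double t = 1.0;
  vec gw(p);
  double gb, fv;

  auto full_obj = [&](const vec& ww, double bb) {
    double f = smooth_obj(X, y, ww, bb, C, l2);
    if (penalty_l1) f += lam * accu(abs(ww));
    return f;
  };

  double F_old = full_obj(w, b);
  int stall = 0, iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    smooth_grad(X, y, wv, bv, C, l2, gw, gb, fv);

    // backtracking line search from the extrapolated point (wv, bv)
    L *= 0.9;  // allow the estimate to shrink between iterations
    vec w_new(p);
    double b_new;
    for (;;) {
      double step = 1.0 / L;
      for (uword k = 0; k < p; ++k) {
        double u = wv[k] - step * gw[k];
        w_new[k] = penalty_l1 ? soft(u, step * lam) : u;
      }
      b_new = bv - step * gb;  // unpenalized
      double f_new = smooth_obj(X, y, w_new, b_new, C, l2);
      vec dw = w_new - wv;
      double db = b_new - bv;
      double quad = fv + dot(gw, dw) + gb * db +
                    0.5 * L * (dot(dw, dw) + db * db);
      if (f_new <= quad + 1e-12 * std::abs(quad)) break;
      L *= 2.0;
      if (L > 1e18) break;
    }

    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    double mom = (t - 1.0) / t_new;
    wv = w_new + mom * (w_new - w);  // w still holds the previous iterate
    bv = b_new + mom * (b_new - b);

    double F_new = full_obj(w_new, b_new);
    if (F_new > F_old) {  // adaptive restart: drop momentum
      t_new = 1.0;
      wv = w_new;
      bv = b_new;
    }

    double rel = std::abs(F_old - F_new) / std::max(1.0, std::abs(F_new));
    stall = (rel < tol) ? stall + 1 : 0;

    w = w_new;
    b = b_new;
    F_old = F_new;
    t = t_new;

    if (stall >= 5) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("w") = w, Rcpp::Named("b") = b,
      Rcpp::Named("objective") = F_old,
      Rcpp::Named("iterations") = iter + 1,
      Rcpp::Named("converged") = converged);
}
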