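#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-thresholding operator used by the lasso coordinate updates.
static inline double soft(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// Block coordinate descent for the l1-penalized Gaussian likelihood
//   max_{Theta > 0} log det Theta - tr(S Theta) - lam * sum_{j != k} |Theta_jk|
// (diagonal unpenalized). Each outer sweep solves, for every column j, the
// lasso subproblem
//   min_beta 1/2 beta' W11 beta - s12' beta + lam |beta|_1
// on the current working covariance W, as in the classical graphical-lasso
// block algorithm; Theta is recovered from the converged W and the lasso
// coefficients, so off-diagonal zeros of Theta are exact zeros of beta.
//
// warm_W / warm_B allow warm starts along a penalty path (calibration).
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lam, double tol, int maxit,
                      Rcpp::Nullable<Rcpp::NumericMatrix> warm_W = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> warm_B = R_NilValue) {
  const uword p = S.n_rows;
  mat W, B;
  if (warm_W.isNotNull() && warm_B.isNotNull()) {
    W = Rcpp::as<mat>(warm_W.get());
    B = Rcpp::as<mat>(warm_B.get());
    W.diag() = S.diag(); // diagonal unpenalized: w_jj stays s_jj
  } else {
    W = S;
    B.zeros(p, p);
  }

  const double s_off = p > 1 ? (accu(abs(S)) - accu(abs(S.diag()))) /
                                   (double)(p * (p - 1))
                             : 0.0;
  const double thr = tol * std::max(s_off, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = (p == 1);
  double delta = 0.0;
  int it = 0;

  for (it = 0; it < maxit && p > 1; ++it) {
    delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);

      // inner coordinate descent on the lasso subproblem
      for (int inner = 0; inner < 200; ++inner) {
        double dmax = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double wkk = W11(k, k);
          double grad = s12(k) - dot(W11.row(k), beta) + wkk * beta(k);
          double bnew = soft(grad, lam) / wkk;
          double d = std::abs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < thr * 0.1) break;
      }

      vec w12 = W11 * beta;
      vec old = W.col(j);
      old = old.elem(idx);
      double d = abs(w12 - old).max();
      if (d > delta) delta = d;
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (delta < thr) { converged = true; break; }
  }

  // recover Theta from W and the per-column lasso coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword k = 0; k < p - 1; ++k) {
      Theta(idx(k), j) = -beta(k) * t22;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());
  // entries the lasso zeroed on both sides stay exactly zero after averaging

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta, Rcpp::Named("W") = W,
      Rcpp::Named("B") = B, Rcpp::Named("iterations") = it + 1,
      Rcpp::Named("converged") = converged, Rcpp::Named("delta") = delta);
}
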