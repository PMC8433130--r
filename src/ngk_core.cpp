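// Numerical core of the NGK fit: garrote-weighted Gaussian kernel,
// xi-step objective/gradient, and the damped-Newton ridge kernel-logistic
// alpha step. Exponents are floored at -700 before exponentiation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat weightedGram(const mat& X, const vec& xi) {
  const rowvec s = sqrt(xi).t();
  mat Xw = X;
  Xw.each_row() %= s;
  const vec q = sum(square(Xw), 1);
  mat D = -2.0 * (Xw * Xw.t());
  D.each_col() += q;
  D.each_row() += q.t();
  D.clamp(0.0, datum::inf);
  D *= -1.0;
  D.elem(find_nonfinite(D)).fill(-700.0);  // overflowed distances
  D.clamp(-700.0, 0.0);
  return exp(D);
}

static double sumLog1pExp(const vec& eta) {
  double out = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    const double e = eta(i);
    out += (e > 0.0) ? e + std::log1p(std::exp(-e))
                     : std::log1p(std::exp(e));
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cppGram(const arma::mat& X, const arma::vec& xi) {
  return weightedGram(X, xi);
}

// [[Rcpp::export]]
arma::mat cppCrossGram(const arma::mat& A, const arma::mat& B,
                       const arma::vec& xi) {
  const rowvec s = sqrt(xi).t();
  mat Aw = A; Aw.each_row() %= s;
  mat Bw = B; Bw.each_row() %= s;
  const vec qa = sum(square(Aw), 1);
  const vec qb = sum(square(Bw), 1);
  mat D = -2.0 * (Aw * Bw.t());
  D.each_col() += qa;
  D.each_row() += qb.t();
  D.clamp(0.0, datum::inf);
  D *= -1.0;
  D.elem(find_nonfinite(D)).fill(-700.0);
  D.clamp(-700.0, 0.0);
  return exp(D);
}

// Penalized objective and its xi-gradient at (xi, alpha fixed):
//   value = sum log(1+exp(eta)) - y'eta + lambdaAlpha a'Ka + lambdaXi sum(xi)
//   grad_j = sum_kl M_kl * -(x_jk - x_jl)^2 + lambdaXi,
//   M = K o ((p - y) a' + lambdaAlpha a a')
// [[Rcpp::export]]
Rcpp::List cppXiObjGrad(const arma::mat& X, const arma::vec& xi,
                        const arma::vec& alpha, const arma::vec& y,
                        double lambdaAlpha, double lambdaXi,
                        double xiTotal) {
  const mat K = weightedGram(X, xi);
  const vec eta = K * alpha;
  const vec pr = 1.0 / (1.0 + exp(-eta));
  const double value = sumLog1pExp(eta) - dot(y, eta) +
    lambdaAlpha * dot(alpha, eta) + lambdaXi * xiTotal;
  mat M = (pr - y) * alpha.t() + lambdaAlpha * (alpha * alpha.t());
  M %= K;
  const vec r = sum(M, 1);
  const rowvec c = sum(M, 0);
  const mat X2 = square(X);
  const rowvec t1 = r.t() * X2;
  const rowvec t2 = c * X2;
  const rowvec t3 = sum(X % (M * X), 0);
  vec grad = -(t1 + t2 - 2.0 * t3).t();
  grad += lambdaXi;
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("grad") = grad);
}

// Damped Newton for the convex alpha step:
//   min_a sum log(1+exp(Ka)) - y'Ka + lambdaAlpha a'Ka
// Halving line search guarantees a non-increasing objective.
// [[Rcpp::export]]
Rcpp::List cppAlphaNewton(const arma::mat& K, const arma::vec& y,
                          arma::vec alpha, double lambdaAlpha,
                          int maxit, double gtol) {
  vec eta = K * alpha;
  auto objOf = [&](const vec& e, const vec& a) {
    return sumLog1pExp(e) - dot(y, e) + lambdaAlpha * dot(a, e);
  };
  double f = objOf(eta, alpha);
  for (int it = 0; it < maxit; ++it) {
    const vec pr = 1.0 / (1.0 + exp(-eta));
    const vec g = K * (pr - y) + 2.0 * lambdaAlpha * eta;
    if (abs(g).max() < gtol * std::max(1.0, std::fabs(f))) break;
    const vec w = pr % (1.0 - pr);
    mat KW = K;
    KW.each_col() %= w;          // diag(w) * K
    mat H = K * KW + 2.0 * lambdaAlpha * K;
    H.diag() += 1e-10;
    vec delta;
    if (!solve(delta, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-6;
      delta = solve(H, g);
    }
    double step = 1.0, fc = f;
    vec cand, etac;
    while (true) {
      cand = alpha - step * delta;
      etac = K * cand;
      fc = objOf(etac, cand);
      if (fc <= f + 1e-12 || step < 1e-8) break;
      step *= 0.5;
    }
    if (fc > f) break;           // no descent left: numerically converged
    const double moved = f - fc;
    alpha = cand;
    eta = etac;
    f = fc;
    if (moved < 1e-12 * std::max(1.0, std::fabs(f))) break;
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("value") = f);
}
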