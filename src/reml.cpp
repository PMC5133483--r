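#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Profile REML for y ~ N(Xb, sg2 * K + se2 * I) after rotation by the
// eigenvectors of K: ytil = U'y, Xtil = U'X, d = eigenvalues of K.
// The only free parameter is the variance ratio lambda = sg2/se2; beta and
// se2 have closed forms at each lambda, so the fit is a 1-D optimisation
// over log(lambda).

// Negative restricted log-likelihood at a given log(lambda).
// Convention: l_R = -0.5 * [ (n-p) log(2*pi) + log|V| + log|X'V^-1 X|
//                            + (y-Xb)' V^-1 (y-Xb) ]
// with se2 profiled out (the quadratic form then equals n-p).
static double reml_nll(double loglam,
                       const arma::vec& y,
                       const arma::mat& X,
                       const arma::vec& d,
                       double* out_se2,
                       arma::vec* out_beta,
                       arma::mat* out_Ainv,
                       double* out_logdet_terms) {
  const double lam = std::exp(loglam);
  const arma::uword n = y.n_elem, p = X.n_cols;
  arma::vec den = lam * d + 1.0;           // eigenvalues of V / se2
  arma::vec w = 1.0 / den;
  arma::mat Xw = X.each_col() % w;
  arma::mat A = X.t() * Xw;                // X' W X
  arma::vec rhs = Xw.t() * y;
  arma::vec beta = arma::solve(A, rhs, arma::solve_opts::likely_sympd);
  arma::vec r = y - X * beta;
  double rss = arma::accu(w % r % r);
  if (rss < 1e-280) rss = 1e-280;          // exact fit: keep se2 > 0
  const double df = (double)(n - p);
  double se2 = rss / df;
  double val, sign;
  arma::log_det(val, sign, A);
  double sumlog = arma::accu(arma::log(den));
  double nll = 0.5 * (df * std::log(2.0 * M_PI * se2) + sumlog + val + df);
  if (out_se2) *out_se2 = se2;
  if (out_beta) *out_beta = beta;
  if (out_Ainv) *out_Ainv = arma::inv_sympd(arma::symmatu(A));
  if (out_logdet_terms) *out_logdet_terms = sumlog + val;
  return nll;
}

// Golden-section minimisation of reml_nll over [lo, hi] in log(lambda).
static double golden_min(double lo, double hi, double tol,
                         const arma::vec& y, const arma::mat& X,
                         const arma::vec& d) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), e = a + gr * (b - a);
  double fc = reml_nll(c, y, X, d, nullptr, nullptr, nullptr, nullptr);
  double fe = reml_nll(e, y, X, d, nullptr, nullptr, nullptr, nullptr);
  while (b - a > tol) {
    if (fc < fe) {
      b = e; e = c; fe = fc;
      c = b - gr * (b - a);
      fc = reml_nll(c, y, X, d, nullptr, nullptr, nullptr, nullptr);
    } else {
      a = c; c = e; fc = fe;
      e = a + gr * (b - a);
      fe = reml_nll(e, y, X, d, nullptr, nullptr, nullptr, nullptr);
    }
  }
  return (a + b) / 2.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_reml_fit(const arma::vec& ytil,
                        const arma::mat& Xtil,
                        const arma::vec& d,
                        double lambda_min,
                        double lambda_max,
                        double tol,
                        int n_grid) {
  const double lo = std::log(lambda_min), hi = std::log(lambda_max);
  // Coarse grid guards against multimodality, then golden-section refines.
  double best_ll = lo, best_f = R_PosInf;
  for (int i = 0; i < n_grid; ++i) {
    double ll = lo + (hi - lo) * i / (double)(n_grid - 1);
    double f = reml_nll(ll, ytil, Xtil, d, nullptr, nullptr, nullptr, nullptr);
    if (f < best_f) { best_f = f; best_ll = f == f ? ll : best_ll; }
  }
  double step = (hi - lo) / (double)(n_grid - 1);
  double a = std::max(lo, best_ll - step), b = std::min(hi, best_ll + step);
  double opt = golden_min(a, b, tol, ytil, Xtil, d);
  if (best_f < reml_nll(opt, ytil, Xtil, d, nullptr, nullptr, nullptr, nullptr))
    opt = best_ll;

  double se2 = 0.0, logdet_terms = 0.0;
  arma::vec beta;
  arma::mat Ainv;
  double nll = reml_nll(opt, ytil, Xtil, d, &se2, &beta, &Ainv, &logdet_terms);
  double lam = std::exp(opt);
  arma::vec se = arma::sqrt(se2 * Ainv.diag());
  bool at_lower = opt <= lo + 2.0 * tol;
  bool at_upper = opt >= hi - 2.0 * tol;
  return Rcpp::List::create(
      Rcpp::Named("lambda") = lam,
      Rcpp::Named("sigma_e2") = se2,
      Rcpp::Named("sigma_g2") = lam * se2,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("loglik_reml") = -nll,
      Rcpp::Named("boundary") = at_lower || at_upper,
      Rcpp::Named("at_lower") = at_lower,
      Rcpp::Named("converged") = std::isfinite(nll));
}

// [[Rcpp::export]]
double cpp_reml_nll(double loglambda,
                    const arma::vec& ytil,
                    const arma::mat& Xtil,
                    const arma::vec& d) {
  return reml_nll(loglambda, ytil, Xtil, d, nullptr, nullptr, nullptr, nullptr);
}
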