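// Collapsed-likelihood kernels. All partition-dependent quantities reduce to
// J-dimensional Gram matrices (see R/linmodel.R); these kernels evaluate the
// multivariate-t / improper-limit log densities from those Grams, and are the
// hot path of the partition sweep. A pure-R reference implementation of each
// is kept in R/linmodel.R and checked for equality in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Improper limit (kappa, lambda -> 0, tau -> inf; sigma-scaled flat block):
// constants shared by all series at fixed data are included once.
// [[Rcpp::export]]
double ll_improper_gram_cpp(const arma::mat& FtF, const arma::vec& Fty,
                            const arma::mat& FtW, const arma::vec& Wty,
                            const arma::mat& WtW, double yty, int N,
                            const arma::mat& B, double phi) {
  const int qf = FtF.n_rows;
  const double cst = lgamma(N / 2.0) - (N - qf) / 2.0 * std::log(2.0 * M_PI);
  const int p = B.n_cols;
  if (phi <= 0.0 || p == 0) {
    mat cF = chol(FtF);
    vec u = solve(trimatl(cF.t()), Fty);
    double S0 = yty - dot(u, u);
    return cst - accu(log(cF.diag())) - N / 2.0 * std::log(S0 / 2.0);
  }
  mat Om_inv = B.t() * WtW * B;
  Om_inv.diag() += 1.0 / (phi * phi);
  mat cO = chol(Om_inv);
  vec sy = solve(trimatl(cO.t()), B.t() * Wty);
  mat sF = solve(trimatl(cO.t()), B.t() * FtW.t());
  mat Fq = FtF - sF.t() * sF;
  vec fy = Fty - sF.t() * sy;
  double yy = yty - dot(sy, sy);
  mat cFq = chol(Fq);
  vec u = solve(trimatl(cFq.t()), fy);
  double S0 = yy - dot(u, u);
  double ld0 = p * std::log(phi * phi) + 2.0 * accu(log(cO.diag()));
  return cst - ld0 / 2.0 - accu(log(cFq.diag())) - N / 2.0 * std::log(S0 / 2.0);
}

// Exact multivariate-t log density with finite hyperparameters.
// [[Rcpp::export]]
double ll_finite_gram_cpp(const arma::mat& FtF, const arma::vec& Fty,
                          const arma::mat& FtW, const arma::vec& Wty,
                          const arma::mat& WtW, double yty, int N,
                          const arma::mat& B, double phi, double kappa,
                          double lambda, double tau) {
  const int qf = FtF.n_rows;
  const int pe = (phi > 0.0) ? B.n_cols : 0;
  const int p = qf + pe;
  mat XtX(p, p);
  vec Xty(p);
  XtX.submat(0, 0, qf - 1, qf - 1) = FtF;
  Xty.subvec(0, qf - 1) = Fty;
  vec sc(p, fill::value(tau));
  if (pe > 0) {
    mat FtWB = FtW * B;
    XtX.submat(0, qf, qf - 1, p - 1) = FtWB;
    XtX.submat(qf, 0, p - 1, qf - 1) = FtWB.t();
    XtX.submat(qf, qf, p - 1, p - 1) = B.t() * WtW * B;
    Xty.subvec(qf, p - 1) = B.t() * Wty;
    sc.subvec(qf, p - 1).fill(phi);
  }
  mat G = XtX;
  G.each_col() %= sc;
  G.each_row() %= sc.t();
  G.diag() += 1.0;
  mat cG = chol(G);
  vec u = solve(trimatl(cG.t()), sc % Xty);
  double Q = yty - dot(u, u);
  return lgamma((kappa + N) / 2.0) - lgamma(kappa / 2.0) +
    kappa / 2.0 * std::log(lambda / 2.0) - N / 2.0 * std::log(2.0 * M_PI) -
    accu(log(cG.diag())) - (kappa + N) / 2.0 * std::log((lambda + Q) / 2.0);
}

// Inclusion-exclusion sum for the rate-marginalized branch configuration
// prior, accumulated in extended precision: the alternating terms are O(1)
// while the result can be small, so double-precision accumulation can lose
// several digits.
// [[Rcpp::export]]
double ie_marginal_cpp(const arma::vec& mut_lengths, double L0, double a_alpha,
                       double b_alpha) {
  const int m = mut_lengths.n_elem;
  std::vector<long double> sums(1, 0.0L);
  std::vector<int> sign(1, 1);
  sums.reserve(1 << m);
  sign.reserve(1 << m);
  for (int i = 0; i < m; ++i) {
    const size_t n = sums.size();
    for (size_t j = 0; j < n; ++j) {
      sums.push_back(sums[j] + (long double)mut_lengths[i]);
      sign.push_back(-sign[j]);
    }
  }
  long double acc = 0.0L;
  for (size_t j = 0; j < sums.size(); ++j) {
    long double t = powl((long double)b_alpha /
                         ((long double)b_alpha + 0.5L * ((long double)L0 + sums[j])),
                         (long double)a_alpha);
    acc += sign[j] * t;
  }
  if (acc < 0.0L) acc = 0.0L;
  return (double)acc;
}
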