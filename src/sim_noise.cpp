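// Spatio-temporally correlated noise: Gaussian innovations mixed across
// channels by the Cholesky factor of the spatial covariance, then passed
// through a channel-wise AR(1) recursion with a stationary start value.
// RcppArmadillo routes fill::randn through R's RNG, so reproducibility
// flows from set.seed() at the R level.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".sim_noise")]]
arma::mat sim_noise(int p, int n, const arma::mat& chol_upper,
                    double phi, double noise_sd) {
  arma::mat innov(p, n, arma::fill::randn);
  arma::vec start(p, arma::fill::randn);

  double innov_sd = noise_sd * std::sqrt(1.0 - phi * phi);
  innov = (chol_upper.t() * innov) * innov_sd;
  start = (chol_upper.t() * start) * noise_sd;

  arma::vec prev = start;
  for (int t = 0; t < n; ++t) {
    prev = phi * prev + innov.col(t);
    innov.col(t) = prev;
  }
  return innov;
}
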