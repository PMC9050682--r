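// Per-timepoint regularised LDA with leave-one-sequence-out CV.
//
// For every timepoint and held-out sequence, the classifier is the
// closed-form two-class LDA on the training trials: pooled within-class
// covariance S (unbiased, n-2 denominator), shrunk as
// S_r = S + lambda * mean(diag(S)) * I, discriminant w = S_r^-1 (mu1 - mu0),
// threshold at the midpoint of the projected class means. Training
// statistics per fold are obtained by subtracting the held-out sequence's
// sufficient statistics from the totals, so each timepoint costs one pass
// over the trials plus one small solve per fold.
//
// The caller passes the data as a (channels x trials x time) cube with
// trials sorted by (fold, class), so every (fold, class) cell is a
// contiguous column range and all heavy operations run on contiguous
// memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".decode_core")]]
Rcpp::List decode_core(const arma::cube& X,      // channels x trials x time
                       const arma::ivec& y,      // class 0/1, sorted trials
                       const arma::ivec& fold,   // fold 1..K, sorted trials
                       double lambda) {
  const arma::uword p = X.n_rows, n = X.n_cols, T = X.n_slices;
  const int K = fold.max();

  // contiguous column ranges per (fold, class) cell and per fold
  std::vector<arma::uword> c_start(2 * K, 0), c_end(2 * K, 0), c_n(2 * K, 0);
  std::vector<arma::uword> f_start(K, 0), f_end(K, 0);
  {
    std::vector<bool> seen(2 * K, false), fseen(K, false);
    int prev_cell = -1;
    for (arma::uword i = 0; i < n; ++i) {
      int k = fold(i) - 1;
      int cell = 2 * k + y(i);
      if (cell < prev_cell)
        Rcpp::stop("trials must be sorted by (fold, class)");
      prev_cell = cell;
      if (!seen[cell]) { c_start[cell] = i; seen[cell] = true; }
      c_end[cell] = i;
      c_n[cell] += 1;
      if (!fseen[k]) { f_start[k] = i; fseen[k] = true; }
      f_end[k] = i;
    }
  }

  double n0tot = 0, n1tot = 0;
  for (int k = 0; k < K; ++k) {
    if (c_n[2 * k] + c_n[2 * k + 1] == 0) Rcpp::stop("empty fold");
    n0tot += c_n[2 * k];
    n1tot += c_n[2 * k + 1];
  }

  arma::vec acc(T, arma::fill::zeros);
  arma::vec ntest(T, arma::fill::zeros);
  std::vector<arma::mat> Ck(2 * K);
  std::vector<arma::vec> sk(2 * K);

  for (arma::uword t = 0; t < T; ++t) {
    const arma::mat& Xt = X.slice(t);
    arma::mat C0tot(p, p, arma::fill::zeros), C1tot(p, p, arma::fill::zeros);
    arma::vec s0tot(p, arma::fill::zeros), s1tot(p, arma::fill::zeros);
    for (int k = 0; k < K; ++k) {
      for (int c = 0; c < 2; ++c) {
        int cell = 2 * k + c;
        if (c_n[cell] == 0) {
          Ck[cell].zeros(p, p);
          sk[cell].zeros(p);
          continue;
        }
        arma::mat V = Xt.cols(c_start[cell], c_end[cell]);
        Ck[cell] = V * V.t();
        sk[cell] = arma::sum(V, 1);
        if (c == 0) { C0tot += Ck[cell]; s0tot += sk[cell]; }
        else        { C1tot += Ck[cell]; s1tot += sk[cell]; }
      }
    }
    double correct = 0, total = 0;
    for (int k = 0; k < K; ++k) {
      double n0 = n0tot - c_n[2 * k];
      double n1 = n1tot - c_n[2 * k + 1];
      if (n0 < 2 || n1 < 2) Rcpp::stop("fewer than 2 training trials in a class");
      arma::vec mu0 = (s0tot - sk[2 * k]) / n0;
      arma::vec mu1 = (s1tot - sk[2 * k + 1]) / n1;
      arma::mat S = (C0tot - Ck[2 * k] - n0 * (mu0 * mu0.t()) +
                     C1tot - Ck[2 * k + 1] - n1 * (mu1 * mu1.t())) / (n0 + n1 - 2);
      double ridge = lambda * arma::mean(S.diag());
      if (ridge <= 0) ridge = 1e-12;  // degenerate (noise-free) covariance
      S.diag() += ridge;
      arma::vec w = arma::solve(S, mu1 - mu0, arma::solve_opts::likely_sympd);
      double thr = arma::dot(w, (mu0 + mu1) / 2);
      arma::rowvec proj = w.t() * Xt.cols(f_start[k], f_end[k]);
      for (arma::uword j = 0; j < proj.n_elem; ++j) {
        int pred = proj(j) > thr ? 1 : 0;
        correct += (pred == y(f_start[k] + j));
        total += 1;
      }
    }
    acc(t) = correct / total;
    ntest(t) = total;
  }
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("n_test") = ntest);
}
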