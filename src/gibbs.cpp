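// Conjugate Gibbs sampler for the Gaussian phylogenetic mixed model.
// All randomness comes from R's RNG (via Rcpp sugar), so chains are
// reproducible from set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// theta = (beta, u_plot, u_species, a_phylo); the joint full conditional
// is N(A^{-1} b, A^{-1}) with A = W'W/s2e + prior precision (diagonal
// except the phylogenetic block, which carries Cinv/s2a).
// [[Rcpp::export(name = ".gibbs_loop")]]
Rcpp::List gibbs_loop(const arma::mat& W, const arma::vec& y,
                      const arma::mat& Cinv,
                      int p, int np, int ns,
                      const arma::vec& prior_v, const arma::vec& prior_nu,
                      int iterations, int burn_in, int thinning,
                      double prior_prec_beta) {
  const int n = y.n_elem;
  const int q = W.n_cols;
  const mat WtW = W.t() * W;
  const vec Wty = W.t() * y;
  const double yty = dot(y, y);

  const int n_keep = (iterations - burn_in) / thinning;
  mat draws(n_keep, p + 4);

  double s2_plot = 1.0, s2_phy = 1.0, s2_sp = 1.0, s2_e = 1.0;
  vec theta(q, fill::zeros);

  // component order: 0 plot, 1 phylo, 2 species, 3 residual
  auto draw_var = [&](double ss, double k, int comp) {
    double shape = (prior_nu(comp) + k) / 2.0;
    double rate = (prior_nu(comp) * prior_v(comp) + ss) / 2.0;
    if (shape <= 0.0) return NA_REAL;
    return 1.0 / R::rgamma(shape, 1.0 / rate);
  };

  int kept = 0;
  for (int it = 1; it <= iterations; ++it) {
    mat A = WtW / s2_e;
    for (int j = 0; j < p; ++j) A(j, j) += prior_prec_beta;
    for (int j = p; j < p + np; ++j) A(j, j) += 1.0 / s2_plot;
    for (int j = p + np; j < p + np + ns; ++j) A(j, j) += 1.0 / s2_sp;
    A.submat(p + np + ns, p + np + ns, q - 1, q - 1) += Cinv / s2_phy;

    mat R_ = chol(A); // upper: A = R'R
    vec m = solve(trimatu(R_), solve(trimatl(R_.t()), Wty / s2_e));
    vec z(q);
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    theta = m + solve(trimatu(R_), z);

    // residual SS through the normal equations: r'r = y'y - 2 th'W'y + th'W'W th
    double rss = yty - 2.0 * dot(theta, Wty) + as_scalar(theta.t() * WtW * theta);
    if (rss < 0.0) rss = 0.0;
    vec u = theta.subvec(p, p + np - 1);
    vec s = theta.subvec(p + np, p + np + ns - 1);
    vec a = theta.subvec(p + np + ns, q - 1);

    s2_e = draw_var(rss, (double)n, 3);
    s2_plot = draw_var(dot(u, u), (double)np, 0);
    s2_sp = draw_var(dot(s, s), (double)ns, 2);
    s2_phy = draw_var(as_scalar(a.t() * Cinv * a), (double)ns, 1);

    if (it > burn_in && (it - burn_in) % thinning == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) draws(kept, j) = theta(j);
      draws(kept, p) = s2_plot;
      draws(kept, p + 1) = s2_phy;
      draws(kept, p + 2) = s2_sp;
      draws(kept, p + 3) = s2_e;
      ++kept;
    }
  }
  return Rcpp::List::create(Rcpp::Named("draws") = draws.rows(0, kept - 1));
}
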