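#include <Rcpp.h>
using namespace Rcpp;

// BayesC Gibbs sampler with heterogeneous residual weights.
//
// Model: y = 1*mu + sum_j z_j a_j delta_j + e,  e ~ N(0, R sigma2_e),
// R = diag(rdiag) fixed, a_j ~ N(0, sigma2_a) given delta_j = 1,
// P(delta_j = 1) = 1 - pi. Scaled inverse chi-squared priors on sigma2_a
// (nu_a, S_a) and sigma2_e (nu_e, S_e). delta and a are sampled jointly
// per SNP from the collapsed full conditional (a integrated out for the
// inclusion odds). Uses R's RNG, so set.seed() in R governs
// reproducibility.
//
// The residual vector e and the score vector zre = Z'W e are both
// maintained incrementally. When the weighted Gram matrix G = Z'WZ is
// supplied, an effect change at SNP k updates all scores via column k of
// G, so a sweep costs O(M + n * m1) with m1 the number of SNPs currently
// in the model, instead of O(n * M). The scores are refreshed from scratch
// periodically to stop floating-point drift.
// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix Z, NumericVector rdiag,
                  double pi_zero, int n_iter, int burn_in, int thin,
                  double nu_a, double nu_e, double S_a, double S_e,
                  double sigma2_a0, double sigma2_e0,
                  Nullable<NumericMatrix> gram = R_NilValue) {
  const int n = y.size();
  const int M = Z.ncol();
  const double pi_incl = 1.0 - pi_zero;
  const bool has_gram = gram.isNotNull();
  NumericMatrix G;
  if (has_gram) G = NumericMatrix(gram);

  std::vector<double> winv(n);
  for (int i = 0; i < n; ++i) winv[i] = 1.0 / rdiag[i];
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += winv[i];

  // z'Wz per SNP and z'W column sums (for mu updates of the scores)
  std::vector<double> czz(M), zwsum(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0, cs = 0.0;
    const double* zj = &Z(0, j);
    for (int i = 0; i < n; ++i) {
      s += zj[i] * zj[i] * winv[i];
      cs += zj[i] * winv[i];
    }
    czz[j] = s;
    zwsum[j] = cs;
  }

  std::vector<double> a(M, 0.0);
  std::vector<int> delta(M, 0);
  double mu = 0.0, sigma2_a = sigma2_a0, sigma2_e = sigma2_e0;
  std::vector<double> e(n), zre(M);
  auto refresh = [&]() {
    for (int j = 0; j < M; ++j) {
      double s = 0.0;
      const double* zj = &Z(0, j);
      for (int i = 0; i < n; ++i) s += zj[i] * e[i] * winv[i];
      zre[j] = s;
    }
  };
  for (int i = 0; i < n; ++i) e[i] = y[i];
  refresh();

  const int n_kept = (n_iter - burn_in) / thin;
  NumericVector pip(M), ahat(M);
  NumericVector mu_chain(n_kept), s2a_chain(n_kept), s2e_chain(n_kept);
  IntegerVector m1_chain(n_kept);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // overall mean
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += (e[i] + mu) * winv[i];
    double mu_new = R::rnorm(rsum / sw, std::sqrt(sigma2_e / sw));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    for (int j = 0; j < M; ++j) zre[j] -= dmu * zwsum[j];
    mu = mu_new;

    // SNP effects, joint (delta, a) update
    int m1 = 0;
    double ssa = 0.0;
    for (int j = 0; j < M; ++j) {
      if (czz[j] <= 0.0) { a[j] = 0.0; delta[j] = 0; continue; }
      const double* zj = &Z(0, j);
      double cur = a[j];
      double zre_j = zre[j];
      if (!has_gram) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += zj[i] * e[i] * winv[i];
        zre_j = s;
      }
      double rhs = (zre_j + czz[j] * cur) / sigma2_e;  // z'W(e + z*cur)
      double lhs = czz[j] / sigma2_e;
      double vpost = 1.0 / (lhs + 1.0 / sigma2_a);
      double mean = vpost * rhs;
      int incl;
      if (pi_zero <= 0.0) {
        incl = 1;
      } else if (pi_incl <= 0.0) {
        incl = 0;
      } else {
        double log_lr = 0.5 * (std::log(vpost) - std::log(sigma2_a))
                        + 0.5 * mean * mean / vpost;
        double log_odds = std::log(pi_incl) - std::log(pi_zero) + log_lr;
        double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        incl = (R::unif_rand() < p1) ? 1 : 0;
      }
      double a_new = 0.0;
      if (incl) a_new = R::rnorm(mean, std::sqrt(vpost));
      double da = a_new - cur;
      if (da != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= zj[i] * da;
        if (has_gram) {
          const double* gj = &G(0, j);
          for (int k = 0; k < M; ++k) zre[k] -= da * gj[k];
        }
      }
      a[j] = a_new;
      delta[j] = incl;
      if (incl) { ++m1; ssa += a_new * a_new; }
    }

    // variance of SNP effects: scaled inverse chi-squared
    sigma2_a = (ssa + nu_a * S_a) / R::rchisq(nu_a + m1);

    // residual variance with R-weighted sum of squares
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i] * winv[i];
    sigma2_e = (sse + nu_e * S_e) / R::rchisq(nu_e + n);

    if (has_gram && it % 2000 == 0) refresh();

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < M; ++j) {
        if (delta[j]) { pip[j] += 1.0; ahat[j] += a[j]; }
      }
      mu_chain[kept] = mu;
      s2a_chain[kept] = sigma2_a;
      s2e_chain[kept] = sigma2_e;
      m1_chain[kept] = m1;
      ++kept;
    }
  }
  for (int j = 0; j < M; ++j) { pip[j] /= n_kept; ahat[j] /= n_kept; }

  return List::create(_["pip"] = pip, _["ahat"] = ahat,
                      _["mu_chain"] = mu_chain, _["s2a_chain"] = s2a_chain,
                      _["s2e_chain"] = s2e_chain, _["m1_chain"] = m1_chain,
                      _["n_kept"] = n_kept);
}
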