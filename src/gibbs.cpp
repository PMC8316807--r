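// Conjugate Gibbs sampler for the Gaussian mixed model
//   y = X beta + u_species[sp] + u_group[gr] + e
// with diffuse normal priors on beta and univariate inverse-Wishart
// (inverse-gamma) priors IG(nu/2, nu*V/2) on each variance component.
// Uses R's RNG so chains are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double scale) {
  // X ~ Gamma(shape, rate = scale) => 1/X ~ InvGamma(shape, scale)
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// [[Rcpp::export(name = ".gibbs_lmm_cpp")]]
List gibbs_lmm_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::ivec& sp, const arma::ivec& gr,
                   double V, double nu, double beta_var,
                   int n_iter, int burn_in, int thin,
                   double fix_sp, double fix_gr, double fix_res) {
  RNGScope scope;
  const int n = y.n_elem, p = X.n_cols;
  const int ns = sp.max() + 1, ng = gr.max() + 1;

  arma::mat XtX = X.t() * X;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec us(ns, arma::fill::zeros), ug(ng, arma::fill::zeros);
  double s2s = NA_REAL, s2g = NA_REAL, s2e = NA_REAL;
  s2s = R_IsNA(fix_sp) ? 1.0 : fix_sp;
  s2g = R_IsNA(fix_gr) ? 1.0 : fix_gr;
  s2e = R_IsNA(fix_res) ? 1.0 : fix_res;

  arma::ivec n_sp(ns, arma::fill::zeros), n_gr(ng, arma::fill::zeros);
  for (int i = 0; i < n; i++) { n_sp[sp[i]]++; n_gr[gr[i]]++; }

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat beta_draws(n_keep, p), sig_draws(n_keep, 3);
  arma::vec us_mean(ns, arma::fill::zeros), ug_mean(ng, arma::fill::zeros);
  int kept = 0;

  for (int it = 0; it < n_iter; it++) {
    // beta | rest
    arma::vec resid = y;
    for (int i = 0; i < n; i++) resid[i] -= us[sp[i]] + ug[gr[i]];
    arma::mat A = XtX / s2e;
    A.diag() += 1.0 / beta_var;
    arma::vec b = X.t() * resid / s2e;
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), b));
    arma::vec z(p);
    for (int j = 0; j < p; j++) z[j] = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), z);

    arma::vec xb = X * beta;

    // species intercepts | rest
    arma::vec rs(ns, arma::fill::zeros);
    for (int i = 0; i < n; i++) rs[sp[i]] += y[i] - xb[i] - ug[gr[i]];
    for (int j = 0; j < ns; j++) {
      double v = 1.0 / (n_sp[j] / s2e + 1.0 / s2s);
      us[j] = v * rs[j] / s2e + std::sqrt(v) * R::norm_rand();
    }

    // group-within-species intercepts | rest
    arma::vec rg(ng, arma::fill::zeros);
    for (int i = 0; i < n; i++) rg[gr[i]] += y[i] - xb[i] - us[sp[i]];
    for (int j = 0; j < ng; j++) {
      double v = 1.0 / (n_gr[j] / s2e + 1.0 / s2g);
      ug[j] = v * rg[j] / s2e + std::sqrt(v) * R::norm_rand();
    }

    // variances | rest
    if (R_IsNA(fix_sp))
      s2s = rinvgamma((nu + ns) / 2.0, (nu * V + arma::dot(us, us)) / 2.0);
    if (R_IsNA(fix_gr))
      s2g = rinvgamma((nu + ng) / 2.0, (nu * V + arma::dot(ug, ug)) / 2.0);
    if (R_IsNA(fix_res)) {
      double ssr = 0.0;
      for (int i = 0; i < n; i++) {
        double r = y[i] - xb[i] - us[sp[i]] - ug[gr[i]];
        ssr += r * r;
      }
      s2e = rinvgamma((nu + n) / 2.0, (nu * V + ssr) / 2.0);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_draws.row(kept) = beta.t();
      sig_draws(kept, 0) = s2s;
      sig_draws(kept, 1) = s2g;
      sig_draws(kept, 2) = s2e;
      us_mean += us;
      ug_mean += ug;
      kept++;
    }
  }
  us_mean /= kept;
  ug_mean /= kept;

  return List::create(_["beta"] = beta_draws, _["sigma2"] = sig_draws,
                      _["u_species"] = us_mean, _["u_group"] = ug_mean);
}
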