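#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of one group's data under the location-scale Student-t
// t(mu, sigma, nu): density f(x) = Gamma((nu+1)/2) / (Gamma(nu/2) sqrt(nu pi) sigma)
//                   * (1 + ((x-mu)/sigma)^2 / nu)^(-(nu+1)/2)
static double group_loglik(const NumericVector& y, double mu, double sigma,
                           double nu) {
  const int n = y.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double z = (y[i] - mu) / sigma;
    s += std::log1p(z * z / nu);
  }
  double cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
    - 0.5 * std::log(nu * M_PI) - std::log(sigma);
  return n * cst - (nu + 1.0) / 2.0 * s;
}

struct BestTarget {
  const List& groups;        // list of numeric vectors
  double M, S, L, H;         // prior: mu ~ N(M, S^2), sigma ~ U(L, H)
  double nu_offset, nu_mean; // nu = nu_offset + Exp(mean = nu_mean)
  int G;

  BestTarget(const List& g, double M_, double S_, double L_, double H_,
             double no_, double nm_)
    : groups(g), M(M_), S(S_), L(L_), H(H_), nu_offset(no_), nu_mean(nm_),
      G(g.size()) {}

  // conditional log-posterior for mu of group g (other params fixed)
  double lp_mu(int g, double mu, double sigma_g, double nu) const {
    NumericVector y = groups[g];
    return group_loglik(y, mu, sigma_g, nu)
      + R::dnorm(mu, M, S, 1);
  }
  // sigma prior is uniform on [L, H]; bounds are enforced by the slice window
  double lp_sigma(int g, double mu_g, double sigma, double nu) const {
    NumericVector y = groups[g];
    return group_loglik(y, mu_g, sigma, nu);
  }
  // nu_raw = nu - nu_offset >= 0, exponential prior with mean nu_mean
  double lp_nu(double nu_raw, const std::vector<double>& mu,
               const std::vector<double>& sigma) const {
    double nu = nu_offset + nu_raw;
    double lp = -nu_raw / nu_mean;
    for (int g = 0; g < G; ++g) {
      NumericVector y = groups[g];
      lp += group_loglik(y, mu[g], sigma[g], nu);
    }
    return lp;
  }
};

// One-dimensional slice update (Neal 2003: stepping out + shrinkage),
// restricted to (lower, upper).
template <class F>
static double slice_update(double x0, double w, double lower, double upper,
                           F logpost) {
  const int max_steps = 100;
  double lp0 = logpost(x0);
  double ys = lp0 - R::exp_rand(); // log of vertical slice level

  // stepping out
  double l = x0 - w * R::unif_rand();
  double r = l + w;
  int jl = 0, jr = 0;
  while (l > lower && jl < max_steps && logpost(l) > ys) { l -= w; ++jl; }
  while (r < upper && jr < max_steps && logpost(r) > ys) { r += w; ++jr; }
  if (l < lower) l = lower;
  if (r > upper) r = upper;

  // shrinkage
  for (int it = 0; it < 1000; ++it) {
    double x1 = l + (r - l) * R::unif_rand();
    if (logpost(x1) >= ys) return x1;
    if (x1 < x0) l = x1; else r = x1;
  }
  return x0; // numerically degenerate slice: keep current value
}

//' @title Single-chain slice sampler for the robust group-comparison model
//' @description Internal workhorse: coordinate-wise slice sampling of
//'   (mu_1..mu_G, sigma_1..sigma_G, nu) under per-group location-scale
//'   Student-t likelihoods with shared nu. Uses R's RNG stream.
//' @keywords internal
// [[Rcpp::export(name = ".best_slice_chain")]]
NumericMatrix best_slice_chain(List groups, NumericVector init,
                               double M, double S, double L, double H,
                               double nu_offset, double nu_mean,
                               int n_iter, int warmup) {
  const int G = groups.size();
  BestTarget tgt(groups, M, S, L, H, nu_offset, nu_mean);

  std::vector<double> mu(G), sigma(G);
  for (int g = 0; g < G; ++g) {
    mu[g] = init[g];
    sigma[g] = std::min(std::max((double)init[G + g], L), H);
  }
  double nu_raw = std::max((double)init[2 * G] - nu_offset, 1e-3);

  // initial slice widths from the data scale
  std::vector<double> w_mu(G), w_sigma(G);
  for (int g = 0; g < G; ++g) {
    NumericVector y = groups[g];
    double sdg = Rcpp::sd(y);
    if (!(sdg > 0)) sdg = 1.0;
    w_mu[g] = 3.0 * sdg / std::sqrt((double)y.size()) + 1e-6;
    w_sigma[g] = w_mu[g];
  }
  double w_nu = 5.0;

  NumericMatrix out(n_iter, 2 * G + 1);
  for (int it = 0; it < warmup + n_iter; ++it) {
    for (int g = 0; g < G; ++g) {
      double sg = sigma[g]; double nu = nu_offset + nu_raw;
      mu[g] = slice_update(mu[g], w_mu[g], R_NegInf, R_PosInf,
                           [&](double x) { return tgt.lp_mu(g, x, sg, nu); });
      double mg = mu[g];
      sigma[g] = slice_update(sigma[g], w_sigma[g], L, H,
                              [&](double x) { return tgt.lp_sigma(g, mg, x, nu); });
    }
    nu_raw = slice_update(nu_raw, w_nu, 0.0, R_PosInf,
                          [&](double x) { return tgt.lp_nu(x, mu, sigma); });
    if (it >= warmup) {
      int row = it - warmup;
      for (int g = 0; g < G; ++g) {
        out(row, g) = mu[g];
        out(row, G + g) = sigma[g];
      }
      out(row, 2 * G) = nu_offset + nu_raw;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
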