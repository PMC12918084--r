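// Polya-Gamma data augmentation for the Bernoulli/binomial logistic
// multilevel model (Polson, Scott & Windle 2013, JASA).  One function
// samples PG(b, z) variates (Devroye's alternating-series rejection for
// b = 1, summed for small integer b, moment-matched normal for large b);
// a second runs the full Gibbs sampler for
//
//   s_i ~ Binomial(t_i, logit^-1(z_i' theta)),
//   theta = (intercept, fixed effects, group effects u_1..u_J),
//   u_j ~ N(mu, sigma^2),  mu ~ N(0, mu_sd^2),  sigma ~ HalfNormal(sigma_scale),
//   intercept ~ N(0, b0_sd^2),  fixed effects ~ N(0, fe_sd^2).
//
// All randomness comes from R's RNG so draws are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PG_TRUNC = 0.64; // Devroye's series switch point

// n-th coefficient of the alternating series for the Jacobi density
static double a_coef(int n, double x, double t) {
  double np = n + 0.5;
  if (x > t)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// P(X <= t) for X ~ inverse-Gaussian with mean 1/z, shape 1 (z >= 0).
// Parameterised by z so the z -> 0 (Levy) limit is exact.
static double pigauss(double t, double z) {
  double rt = std::sqrt(1.0 / t);
  double lp1 = R::pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 1);
  double lp2 = 2.0 * z + R::pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 1);
  return std::exp(lp1) + std::exp(lp2);
}

// inverse-Gaussian(1/z, 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  if (t * z < 1.0) { // mean beyond truncation point: tilted-Levy rejection
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      double x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  for (;;) { // Michael-Schucany-Haas, reject above t
    double nu = R::norm_rand();
    double y = nu * nu;
    double muy = mu * y;
    double x = mu + 0.5 * mu * muy -
               0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

// one PG(1, z) draw
static double rpg1(double z) {
  double c = 0.5 * std::fabs(z);
  double t = PG_TRUNC;
  double K = M_PI * M_PI / 8.0 + 0.5 * c * c;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * t);
  double q = 2.0 * std::exp(-c) * pigauss(t, c);
  for (;;) {
    double x;
    if (R::unif_rand() < p / (p + q))
      x = t + R::exp_rand() / K; // exponential tail beyond t
    else
      x = rtigauss(c, t);
    double s = a_coef(0, x, t);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x, t);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x, t);
        if (y > s) break;
      }
    }
  }
}

// PG(b, z) for integer b: exact sum for small b, moment-matched normal
// for large b (relative error of the approximation is O(1/b)).
static double rpg(int b, double z) {
  if (b <= 0) return 0.0;
  if (b <= 60) {
    double s = 0.0;
    for (int i = 0; i < b; ++i) s += rpg1(z);
    return s;
  }
  double az = std::fabs(z);
  double m, v;
  if (az < 1e-4) {
    m = b * (0.25 - az * az / 48.0);
    v = b / 24.0;
  } else {
    m = b * std::tanh(az / 2.0) / (2.0 * az);
    double ch = std::cosh(az / 2.0);
    v = b * (std::sinh(az) - az) / (4.0 * az * az * az * ch * ch);
  }
  double x = m + std::sqrt(v) * R::norm_rand();
  return x > 0.0 ? x : m; // negative draws have negligible probability
}

// [[Rcpp::export]]
NumericVector rpg_vec(IntegerVector b, NumericVector z) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg(b[i], z[i]);
  return out;
}

// Univariate slice sampler step for sigma > 0 with log-density
//   -J log(sigma) - ss / (2 sigma^2) - sigma^2 / (2 scale^2)
static double slice_sigma(double cur, int J, double ss, double scale) {
  auto f = [&](double s) {
    return -J * std::log(s) - ss / (2.0 * s * s) -
           s * s / (2.0 * scale * scale);
  };
  double y = f(cur) - R::exp_rand();
  double w = 0.5;
  double L = cur - w * R::unif_rand();
  double R_ = L + w;
  if (L < 1e-12) L = 1e-12;
  // step out
  int steps = 0;
  while (L > 1e-12 && f(L) > y && steps++ < 50) {
    L -= w;
    if (L < 1e-12) { L = 1e-12; break; }
  }
  steps = 0;
  while (f(R_) > y && steps++ < 50) R_ += w;
  // shrink
  for (int it = 0; it < 100; ++it) {
    double x = L + R::unif_rand() * (R_ - L);
    if (f(x) > y) return x;
    if (x < cur) L = x; else R_ = x;
  }
  return cur;
}

// Gibbs sampler for one chain.  Z: M x P design (intercept, K fixed-effect
// dummies, J group indicators in that order).  Returns (iter) x (P + 2)
// matrix of post-warmup draws: theta, mu, sigma.
// [[Rcpp::export]]
arma::mat pg_gibbs_chain(const arma::mat& Z, const arma::vec& succ,
                         const arma::vec& trials, int n_fixed, int n_group,
                         double b0_sd, double fe_sd, double mu_sd,
                         double sigma_scale, int warmup, int iter,
                         const arma::vec& theta_init, double mu_init,
                         double sigma_init) {
  const int M = Z.n_rows;
  const int P = Z.n_cols; // 1 + n_fixed + n_group
  arma::vec theta = theta_init;
  double mu = mu_init;
  double sigma = sigma_init;
  arma::vec kappa = succ - trials / 2.0;
  arma::vec Ztkappa = Z.t() * kappa;
  arma::mat out(iter, P + 2);
  arma::vec omega(M);

  for (int it = 0; it < warmup + iter; ++it) {
    // 1. Polya-Gamma latents
    arma::vec eta = Z * theta;
    for (int i = 0; i < M; ++i)
      omega(i) = rpg((int)trials(i), eta(i));

    // 2. joint update of theta | omega, sigma.  The group mean mu is
    // collapsed out of the u prior (u ~ N(0, sigma^2 I + mu_sd^2 11')),
    // so the whole theta vector is drawn from its exact joint Gaussian
    // conditional and no weakly identified intercept/group direction is
    // left to mix by random walk.  Sherman-Morrison gives the u-block
    // prior precision: I/sigma^2 - (mu_sd^2 / (sigma^2 (sigma^2 +
    // J mu_sd^2))) 11'.
    arma::mat V = Z.t() * (Z.each_col() % omega);
    V(0, 0) += 1.0 / (b0_sd * b0_sd);
    for (int k = 1; k <= n_fixed; ++k) V(k, k) += 1.0 / (fe_sd * fe_sd);
    {
      double s2 = sigma * sigma, m2 = mu_sd * mu_sd;
      double off = m2 / (s2 * (s2 + n_group * m2));
      for (int j = 1 + n_fixed; j < P; ++j) {
        for (int k = 1 + n_fixed; k < P; ++k) V(j, k) -= off;
        V(j, j) += 1.0 / s2;
      }
    }
    arma::mat L = arma::chol(V, "lower");
    arma::vec mvec = arma::solve(arma::trimatu(L.t()),
                                 arma::solve(arma::trimatl(L), Ztkappa));
    arma::vec zdraw(P);
    for (int k = 0; k < P; ++k) zdraw(k) = R::norm_rand();
    theta = mvec + arma::solve(arma::trimatu(L.t()), zdraw);

    // 3. group mean mu
    arma::vec u = theta.subvec(1 + n_fixed, P - 1);
    double prec_mu = n_group / (sigma * sigma) + 1.0 / (mu_sd * mu_sd);
    double mean_mu = arma::accu(u) / (sigma * sigma) / prec_mu;
    mu = mean_mu + R::norm_rand() / std::sqrt(prec_mu);

    // 4. group sd sigma (slice)
    double ss = arma::accu(arma::square(u - mu));
    sigma = slice_sigma(sigma, n_group, ss, sigma_scale);

    if (it >= warmup) {
      int r = it - warmup;
      for (int k = 0; k < P; ++k) out(r, k) = theta(k);
      out(r, P) = mu;
      out(r, P + 1) = sigma;
    }
  }
  return out;
}
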