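// Componentwise adaptive random-walk Metropolis sampler for the eight
// continuous dose-response models, operating on a rescaled problem
// (dose / max dose, response / 100) for numerical stability.
//
// Parameters are sampled on an unconstrained scale z and mapped to the
// constrained scale through scaled-logistic transforms; box priors are
// uniform on the constrained scale (their log-density enters through the
// transform Jacobian), and the residual SD has a half-Cauchy prior.
//
// Model ids: 1 exp2, 2 exp3, 3 exp4, 4 exp5, 5 hill, 6 power,
//            7 michaelis-menten, 8 linear.
#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_BIG = -1e10;

static inline double ilogit(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// log u(1-u) for u = ilogit(z), the Jacobian of the logistic transform
static inline double log_jac_logistic(double z) {
  double ez = std::exp(z), emz = std::exp(-z);
  double den = 2.0 + ez + emz;
  if (!R_finite(den)) return NEG_BIG;
  return -std::log(den);
}

static int n_free(int model) {
  switch (model) {
  case 1: return 2; // exp2: a, u_b
  case 2: return 3; // exp3: a, u_b, g
  case 3: return 3; // exp4: a, b, u_c
  case 4: return 4; // exp5: a, b, u_c, g
  case 5: return 4; // hill: a, u_b, c, g
  case 6: return 3; // power: a, u_b, g
  case 7: return 3; // michaelis-menten: a, u_b, c
  case 8: return 2; // linear: a, u_b
  }
  return 0;
}

// Map unconstrained z (length n_free, curve parameters only) to
// (a, b, c, g) on the rescaled problem. The joint support keeps the mean
// function within (0, plateau] over the observed dose range:
//   * exp2/exp3:  b = u * log(plateau / a)   so f(1) = a e^b <= plateau
//   * exp4/exp5:  c = 1 + u * (plateau/a - 1) so the asymptote a*c <= plateau
//   * hill/mm/power/linear: b = u * (plateau - a)
static void z_to_theta(int model, const double *z, double amax, double bmax,
                       double cmax, double gmin, double gmax, double plateau,
                       double *th) {
  double a = amax * ilogit(z[0]);
  double b = NA_REAL, c = NA_REAL, g = NA_REAL;
  switch (model) {
  case 1:
    b = ilogit(z[1]) * std::log(plateau / a);
    break;
  case 2:
    b = ilogit(z[1]) * std::log(plateau / a);
    g = gmin + (gmax - gmin) * ilogit(z[2]);
    break;
  case 3:
    b = bmax * ilogit(z[1]);
    c = 1.0 + ilogit(z[2]) * (plateau / a - 1.0);
    break;
  case 4:
    b = bmax * ilogit(z[1]);
    c = 1.0 + ilogit(z[2]) * (plateau / a - 1.0);
    g = gmin + (gmax - gmin) * ilogit(z[3]);
    break;
  case 5:
    b = ilogit(z[1]) * (plateau - a);
    c = cmax * ilogit(z[2]);
    g = gmin + (gmax - gmin) * ilogit(z[3]);
    break;
  case 6:
    b = ilogit(z[1]) * (plateau - a);
    g = gmin + (gmax - gmin) * ilogit(z[2]);
    break;
  case 7:
    b = ilogit(z[1]) * (plateau - a);
    c = cmax * ilogit(z[2]);
    break;
  case 8:
    b = ilogit(z[1]) * (plateau - a);
    break;
  }
  th[0] = a; th[1] = b; th[2] = c; th[3] = g;
}

static inline double f_mean(int model, const double *th, double x) {
  double a = th[0], b = th[1], c = th[2], g = th[3];
  switch (model) {
  case 1: return a * std::exp(b * x);
  case 2: return a * std::exp(b * std::pow(x, g));
  case 3: return a * (c - (c - 1.0) * std::exp(-b * x));
  case 4: return a * (c - (c - 1.0) * std::exp(-b * std::pow(x, g)));
  case 5: {
    double xg = std::pow(x, g);
    return a + b * xg / (std::pow(c, g) + xg);
  }
  case 6: return a + b * std::pow(x, g);
  case 7: return a + b * x / (c + x);
  case 8: return a + b * x;
  }
  return NA_REAL;
}

// Summary-statistic normal log-likelihood (scaled units, additive constant
// -(N/2) log 2pi omitted): sum_i [ -n_i log s - (ss_i + n_i (y_i-f_i)^2)/(2 s^2) ]
// where ss_i = (n_i - 1) sd_i^2.
// With lognormal = 1 the response summaries are log-scale (y_i = mean log
// response, ss_i = (n_i - 1) x log-scale variance) and f parameterizes the
// median response, so the residual is y_i - log f_i.
static double log_lik(int model, const double *th, double sig,
                      const NumericVector &x, const NumericVector &y,
                      const NumericVector &n, const NumericVector &ss,
                      int lognormal) {
  double s2 = sig * sig, ll = 0.0, logsig = std::log(sig);
  int m = x.size();
  for (int i = 0; i < m; ++i) {
    double f = f_mean(model, th, x[i]);
    if (lognormal) {
      if (!(f > 0.0)) return R_NegInf;
      f = std::log(f);
    }
    double r = y[i] - f;
    ll += -n[i] * logsig - (ss[i] + n[i] * r * r) / (2.0 * s2);
  }
  return ll;
}

// Log posterior (up to a constant). z has length n_free(model) + 1; the last
// entry is log(sigma). Fills th[0..4] = (a,b,c,g,sigma) and *llout.
static double log_post(int model, const double *z,
                       const NumericVector &x, const NumericVector &y,
                       const NumericVector &n, const NumericVector &ss,
                       double amax, double bmax, double cmax, double gmin,
                       double gmax, double plateau, double sig_scale,
                       int lognormal, double *th, double *llout) {
  int p = n_free(model);
  double lp = 0.0;
  for (int j = 0; j < p; ++j) {
    double lj = log_jac_logistic(z[j]);
    if (lj <= NEG_BIG) { *llout = NEG_BIG; return NEG_BIG; }
    lp += lj;
  }
  double sig = std::exp(z[p]);
  if (!R_finite(sig) || sig <= 0.0) { *llout = NEG_BIG; return NEG_BIG; }
  // half-Cauchy(0, sig_scale) density on sigma plus log-Jacobian z[p]
  double r = sig / sig_scale;
  lp += z[p] - std::log1p(r * r);
  z_to_theta(model, z, amax, bmax, cmax, gmin, gmax, plateau, th);
  double ll = log_lik(model, th, sig, x, y, n, ss, lognormal);
  if (!R_finite(ll)) { *llout = NEG_BIG; return NEG_BIG; }
  th[4] = sig;
  *llout = ll;
  lp += ll;
  return R_finite(lp) ? lp : NEG_BIG;
}

// [[Rcpp::export]]
double cw_logpost(int model, NumericVector z, NumericVector x, NumericVector y,
                  NumericVector n, NumericVector ss, double amax, double bmax,
                  double cmax, double gmin, double gmax, double plateau,
                  double sig_scale, int lognormal) {
  if (z.size() != n_free(model) + 1) stop("wrong parameter vector length");
  double th[5], ll;
  return log_post(model, z.begin(), x, y, n, ss, amax, bmax, cmax, gmin,
                  gmax, plateau, sig_scale, lognormal, th, &ll);
}

// [[Rcpp::export]]
NumericVector cw_theta(int model, NumericVector z, double amax, double bmax,
                       double cmax, double gmin, double gmax, double plateau) {
  if (z.size() != n_free(model) + 1) stop("wrong parameter vector length");
  double th[5];
  z_to_theta(model, z.begin(), amax, bmax, cmax, gmin, gmax, plateau, th);
  th[4] = std::exp(z[n_free(model)]);
  return NumericVector(th, th + 5);
}

// [[Rcpp::export]]
List cw_sampler(int model, NumericVector z0, NumericVector x, NumericVector y,
                NumericVector n, NumericVector ss, double amax, double bmax,
                double cmax, double gmin, double gmax, double plateau,
                double sig_scale, int lognormal, int iterations,
                double warmup_frac) {
  int k = n_free(model) + 1;
  if (z0.size() != k) stop("wrong initial value length");
  int warm = (int)std::floor(iterations * warmup_frac);
  int keep = iterations - warm;
  if (keep < 1) stop("no post-warmup iterations");

  NumericMatrix theta(keep, 5); // a, b, c, g, sigma (rescaled problem)
  NumericVector llkeep(keep);
  std::vector<double> z(z0.begin(), z0.end()), zp(z0.begin(), z0.end());
  std::vector<double> step(k, 0.5);
  std::vector<int> acc(k, 0), tot(k, 0);
  NumericVector acc_rate(k);
  double th[5], thp[5], ll, llp;

  double lp = log_post(model, z.data(), x, y, n, ss, amax, bmax, cmax,
                       gmin, gmax, plateau, sig_scale, lognormal, th, &ll);
  if (lp <= NEG_BIG)
    stop("non-finite log posterior at the initial value");

  RNGScope scope;
  int batch = 0, in_batch = 0;
  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < k; ++j) {
      zp[j] = z[j] + step[j] * norm_rand();
      double lpp = log_post(model, zp.data(), x, y, n, ss, amax, bmax, cmax,
                            gmin, gmax, plateau, sig_scale, lognormal, thp,
                            &llp);
      if (lpp > NEG_BIG && std::log(unif_rand()) < lpp - lp) {
        z[j] = zp[j];
        lp = lpp;
        ll = llp;
        for (int q = 0; q < 5; ++q) th[q] = thp[q];
        acc[j]++;
      } else {
        zp[j] = z[j];
      }
      tot[j]++;
    }
    if (it < warm) {
      if (++in_batch == 50) { // Robbins-Monro step-size adaptation, target 0.44
        ++batch;
        double d = std::min(0.25, 1.0 / std::sqrt((double)batch));
        for (int j = 0; j < k; ++j) {
          double r = (double)acc[j] / tot[j];
          step[j] *= std::exp(r > 0.44 ? d : -d);
          acc[j] = 0;
          tot[j] = 0;
        }
        in_batch = 0;
      }
    } else {
      int row = it - warm;
      for (int q = 0; q < 5; ++q) theta(row, q) = th[q];
      llkeep[row] = ll;
    }
  }
  for (int j = 0; j < k; ++j)
    acc_rate[j] = tot[j] > 0 ? (double)acc[j] / tot[j] : NA_REAL;

  return List::create(_["theta"] = theta, _["loglik"] = llkeep,
                      _["accept"] = acc_rate, _["step"] = NumericVector(step.begin(), step.end()));
}
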