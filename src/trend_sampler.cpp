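#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// numerically safe log(1 + exp(x))
static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log prior kernel for a hierarchical SD; family: 0 half-Cauchy, 1 uniform(0, scale), 2 half-normal
static inline double lp_sd(double s, int family, double scale) {
  if (s <= 0.0) return R_NegInf;
  switch (family) {
  case 0: return -std::log1p((s / scale) * (s / scale));
  case 1: return (s < scale) ? 0.0 : R_NegInf;
  default: return -0.5 * (s / scale) * (s / scale);
  }
}

static inline double dnorm_l(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * z * z - std::log(s);
}

// binomial kernel with real-valued success count (quasi-likelihood on
// design-effect-adjusted counts): y*eta - n*log(1+exp(eta))
static inline double obs_ll(double y, double n, double eta) {
  return y * eta - n * log1pexp_(eta);
}

struct Adapt {
  double scale;
  int acc, tot;
  Adapt(double s = 0.2) : scale(s), acc(0), tot(0) {}
  void tune() {
    if (tot == 0) return;
    double rate = (double)acc / tot;
    scale *= std::exp(0.8 * (rate - 0.44));
    if (scale < 1e-4) scale = 1e-4;
    if (scale > 25.0) scale = 25.0;
    acc = 0; tot = 0;
  }
};

// One MCMC chain for the hierarchical binomial-logit trend model.
// logit(p_s) = alpha[c(s)] + beta[c(s)] * td_s + g_sdi * sdi_s + g_hrh * hrh_s
// Uses R's RNG: seed with set.seed() before calling.
// proj_a / proj_b give, per country and covariate, the within-country
// least-squares projection of the covariate onto (1, td): used by shear
// moves that shift a covariate coefficient together with the compensating
// country intercepts/slopes along the confounded posterior ridge.
// [[Rcpp::export(.trend_chain_cpp)]]
List trend_chain_cpp(NumericVector y, NumericVector n, IntegerVector country,
                     NumericVector td, NumericVector sdi, NumericVector hrh,
                     NumericMatrix proj_a, NumericMatrix proj_b,
                     int n_country, IntegerVector region, int n_region,
                     NumericVector alpha0, NumericVector beta0,
                     double g_sdi0, double g_hrh0,
                     double mu_a0, double mu_b0, double sig_a0, double sig_b0,
                     bool use_cov, bool hierarchical, bool fit_slope,
                     bool region_hierarchy,
                     int intercept_prior, // 0 normal(0, prior_sd_fixed), 1 standard logistic
                     double prior_sd_fixed, int sd_family, double sd_scale,
                     int n_iter, int burn_in, int thin) {
  const int S = y.size();
  std::vector< std::vector<int> > rows(n_country);
  for (int s = 0; s < S; ++s) rows[country[s]].push_back(s);
  std::vector< std::vector<int> > reg_members(std::max(n_region, 1));
  for (int i = 0; i < n_country; ++i) reg_members[region[i]].push_back(i);

  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  double g_sdi = g_sdi0, g_hrh = g_hrh0;
  double mu_a = mu_a0, mu_b = mu_b0, sig_a = sig_a0, sig_b = sig_b0;
  std::vector<double> mu_a_reg(std::max(n_region, 1), mu_a0);
  double sig_mu = 1.0; // SD of region means around the global mean

  std::vector<double> eta(S);
  for (int s = 0; s < S; ++s)
    eta[s] = alpha[country[s]] + beta[country[s]] * td[s] +
             (use_cov ? g_sdi * sdi[s] + g_hrh * hrh[s] : 0.0);

  std::vector<Adapt> ad_a(n_country, Adapt(0.3)), ad_b(n_country, Adapt(0.3));
  Adapt ad_gs(0.1), ad_gh(0.1), ad_sa(0.4), ad_sb(0.4), ad_sm(0.4);
  Adapt ad_shear[2] = {Adapt(0.3), Adapt(0.3)};

  const int n_keep = (n_iter - burn_in) / thin;
  const int n_par = 2 * n_country + 2 + 4 + n_region + 1;
  NumericMatrix draws(n_keep, n_par);
  int kept = 0;

  double pf2 = prior_sd_fixed * prior_sd_fixed;

  for (int it = 1; it <= n_iter; ++it) {
    // country intercepts
    for (int i = 0; i < n_country; ++i) {
      double prop = alpha[i] + norm_rand() * ad_a[i].scale;
      double d = 0.0;
      for (size_t k = 0; k < rows[i].size(); ++k) {
        int s = rows[i][k];
        double e1 = eta[s] + (prop - alpha[i]);
        d += obs_ll(y[s], n[s], e1) - obs_ll(y[s], n[s], eta[s]);
      }
      double m_i = hierarchical ? (region_hierarchy ? mu_a_reg[region[i]] : mu_a) : 0.0;
      if (hierarchical)
        d += dnorm_l(prop, m_i, sig_a) - dnorm_l(alpha[i], m_i, sig_a);
      else if (intercept_prior == 1)
        d += (prop - 2.0 * log1pexp_(prop)) - (alpha[i] - 2.0 * log1pexp_(alpha[i]));
      else
        d += dnorm_l(prop, 0.0, prior_sd_fixed) - dnorm_l(alpha[i], 0.0, prior_sd_fixed);
      ad_a[i].tot++;
      if (std::log(unif_rand()) < d) {
        for (size_t k = 0; k < rows[i].size(); ++k) eta[rows[i][k]] += prop - alpha[i];
        alpha[i] = prop; ad_a[i].acc++;
      }
    }
    // country slopes
    if (fit_slope) for (int i = 0; i < n_country; ++i) {
      double prop = beta[i] + norm_rand() * ad_b[i].scale;
      double d = 0.0;
      for (size_t k = 0; k < rows[i].size(); ++k) {
        int s = rows[i][k];
        double e1 = eta[s] + (prop - beta[i]) * td[s];
        d += obs_ll(y[s], n[s], e1) - obs_ll(y[s], n[s], eta[s]);
      }
      if (hierarchical)
        d += dnorm_l(prop, mu_b, sig_b) - dnorm_l(beta[i], mu_b, sig_b);
      else
        d += dnorm_l(prop, 0.0, prior_sd_fixed) - dnorm_l(beta[i], 0.0, prior_sd_fixed);
      ad_b[i].tot++;
      if (std::log(unif_rand()) < d) {
        for (size_t k = 0; k < rows[i].size(); ++k)
          eta[rows[i][k]] += (prop - beta[i]) * td[rows[i][k]];
        beta[i] = prop; ad_b[i].acc++;
      }
    }
    // covariate coefficients (full-data blocks)
    if (use_cov) {
      double prop = g_sdi + norm_rand() * ad_gs.scale, d = 0.0;
      for (int s = 0; s < S; ++s)
        d += obs_ll(y[s], n[s], eta[s] + (prop - g_sdi) * sdi[s]) - obs_ll(y[s], n[s], eta[s]);
      d += dnorm_l(prop, 0.0, prior_sd_fixed) - dnorm_l(g_sdi, 0.0, prior_sd_fixed);
      ad_gs.tot++;
      if (std::log(unif_rand()) < d) {
        for (int s = 0; s < S; ++s) eta[s] += (prop - g_sdi) * sdi[s];
        g_sdi = prop; ad_gs.acc++;
      }
      prop = g_hrh + norm_rand() * ad_gh.scale; d = 0.0;
      for (int s = 0; s < S; ++s)
        d += obs_ll(y[s], n[s], eta[s] + (prop - g_hrh) * hrh[s]) - obs_ll(y[s], n[s], eta[s]);
      d += dnorm_l(prop, 0.0, prior_sd_fixed) - dnorm_l(g_hrh, 0.0, prior_sd_fixed);
      ad_gh.tot++;
      if (std::log(unif_rand()) < d) {
        for (int s = 0; s < S; ++s) eta[s] += (prop - g_hrh) * hrh[s];
        g_hrh = prop; ad_gh.acc++;
      }
      // shear moves: shift a covariate coefficient by delta while moving
      // every country intercept/slope by the compensating projection, so
      // the sampler can travel along the near-collinear direction.
      for (int j = 0; j < 2; ++j) {
        const double *z = (j == 0) ? &sdi[0] : &hrh[0];
        double g_cur = (j == 0) ? g_sdi : g_hrh;
        double del = norm_rand() * ad_shear[j].scale;
        double d = 0.0;
        for (int s = 0; s < S; ++s) {
          int c = country[s];
          double de = del * (z[s] - proj_a(c, j) - proj_b(c, j) * td[s]);
          d += obs_ll(y[s], n[s], eta[s] + de) - obs_ll(y[s], n[s], eta[s]);
        }
        d += dnorm_l(g_cur + del, 0.0, prior_sd_fixed) -
             dnorm_l(g_cur, 0.0, prior_sd_fixed);
        for (int i = 0; i < n_country; ++i) {
          double a1 = alpha[i] - del * proj_a(i, j);
          double m_i = hierarchical ? (region_hierarchy ? mu_a_reg[region[i]] : mu_a) : 0.0;
          if (hierarchical)
            d += dnorm_l(a1, m_i, sig_a) - dnorm_l(alpha[i], m_i, sig_a);
          else if (intercept_prior == 1)
            d += (a1 - 2.0 * log1pexp_(a1)) - (alpha[i] - 2.0 * log1pexp_(alpha[i]));
          else
            d += dnorm_l(a1, 0.0, prior_sd_fixed) - dnorm_l(alpha[i], 0.0, prior_sd_fixed);
          if (fit_slope) {
            double b1 = beta[i] - del * proj_b(i, j);
            if (hierarchical)
              d += dnorm_l(b1, mu_b, sig_b) - dnorm_l(beta[i], mu_b, sig_b);
            else
              d += dnorm_l(b1, 0.0, prior_sd_fixed) - dnorm_l(beta[i], 0.0, prior_sd_fixed);
          }
        }
        ad_shear[j].tot++;
        if (std::log(unif_rand()) < d) {
          for (int s = 0; s < S; ++s) {
            int c = country[s];
            eta[s] += del * (z[s] - proj_a(c, j) - proj_b(c, j) * td[s]);
          }
          for (int i = 0; i < n_country; ++i) {
            alpha[i] -= del * proj_a(i, j);
            if (fit_slope) beta[i] -= del * proj_b(i, j);
          }
          if (j == 0) g_sdi += del; else g_hrh += del;
          ad_shear[j].acc++;
        }
      }
    }
    if (hierarchical) {
      if (region_hierarchy) {
        // region means: conjugate given alpha, sig_a, mu_a, sig_mu
        for (int r = 0; r < n_region; ++r) {
          int k = reg_members[r].size();
          double sum_a = 0.0;
          for (int j = 0; j < k; ++j) sum_a += alpha[reg_members[r][j]];
          double prec = k / (sig_a * sig_a) + 1.0 / (sig_mu * sig_mu);
          double mean = (sum_a / (sig_a * sig_a) + mu_a / (sig_mu * sig_mu)) / prec;
          mu_a_reg[r] = mean + norm_rand() / std::sqrt(prec);
        }
        // global mean over region means
        double prec = n_region / (sig_mu * sig_mu) + 1.0 / pf2;
        double sum_m = 0.0;
        for (int r = 0; r < n_region; ++r) sum_m += mu_a_reg[r];
        mu_a = sum_m / (sig_mu * sig_mu) / prec + norm_rand() / std::sqrt(prec);
        // SD of region means: random walk on log scale
        double lp0 = lp_sd(sig_mu, sd_family, sd_scale) + std::log(sig_mu);
        for (int r = 0; r < n_region; ++r) lp0 += dnorm_l(mu_a_reg[r], mu_a, sig_mu);
        double prop = sig_mu * std::exp(norm_rand() * ad_sm.scale);
        double lp1 = lp_sd(prop, sd_family, sd_scale) + std::log(prop);
        for (int r = 0; r < n_region; ++r) lp1 += dnorm_l(mu_a_reg[r], mu_a, prop);
        ad_sm.tot++;
        if (std::log(unif_rand()) < lp1 - lp0) { sig_mu = prop; ad_sm.acc++; }
      } else {
        double prec = n_country / (sig_a * sig_a) + 1.0 / pf2;
        double sum_a = 0.0;
        for (int i = 0; i < n_country; ++i) sum_a += alpha[i];
        mu_a = sum_a / (sig_a * sig_a) / prec + norm_rand() / std::sqrt(prec);
      }
      if (fit_slope) {
        double prec = n_country / (sig_b * sig_b) + 1.0 / pf2;
        double sum_b = 0.0;
        for (int i = 0; i < n_country; ++i) sum_b += beta[i];
        mu_b = sum_b / (sig_b * sig_b) / prec + norm_rand() / std::sqrt(prec);
      }
      // hierarchical SDs: random walk on the log scale, Jacobian log(s)
      {
        double lp0 = lp_sd(sig_a, sd_family, sd_scale) + std::log(sig_a);
        for (int i = 0; i < n_country; ++i) {
          double m_i = region_hierarchy ? mu_a_reg[region[i]] : mu_a;
          lp0 += dnorm_l(alpha[i], m_i, sig_a);
        }
        double prop = sig_a * std::exp(norm_rand() * ad_sa.scale);
        double lp1 = lp_sd(prop, sd_family, sd_scale) + std::log(prop);
        for (int i = 0; i < n_country; ++i) {
          double m_i = region_hierarchy ? mu_a_reg[region[i]] : mu_a;
          lp1 += dnorm_l(alpha[i], m_i, prop);
        }
        ad_sa.tot++;
        if (std::log(unif_rand()) < lp1 - lp0) { sig_a = prop; ad_sa.acc++; }
      }
      if (fit_slope) {
        double lp0 = lp_sd(sig_b, sd_family, sd_scale) + std::log(sig_b);
        for (int i = 0; i < n_country; ++i) lp0 += dnorm_l(beta[i], mu_b, sig_b);
        double prop = sig_b * std::exp(norm_rand() * ad_sb.scale);
        double lp1 = lp_sd(prop, sd_family, sd_scale) + std::log(prop);
        for (int i = 0; i < n_country; ++i) lp1 += dnorm_l(beta[i], mu_b, prop);
        ad_sb.tot++;
        if (std::log(unif_rand()) < lp1 - lp0) { sig_b = prop; ad_sb.acc++; }
      }
    }
    // adapt proposal scales during burn-in only; frozen afterwards
    if (it <= burn_in && it % 50 == 0) {
      for (int i = 0; i < n_country; ++i) { ad_a[i].tune(); ad_b[i].tune(); }
      ad_gs.tune(); ad_gh.tune(); ad_sa.tune(); ad_sb.tune(); ad_sm.tune();
      ad_shear[0].tune(); ad_shear[1].tune();
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int i = 0; i < n_country; ++i) draws(kept, c++) = alpha[i];
      for (int i = 0; i < n_country; ++i) draws(kept, c++) = beta[i];
      draws(kept, c++) = g_sdi;
      draws(kept, c++) = g_hrh;
      draws(kept, c++) = mu_a;
      draws(kept, c++) = mu_b;
      draws(kept, c++) = sig_a;
      draws(kept, c++) = sig_b;
      for (int r = 0; r < n_region; ++r) draws(kept, c++) = mu_a_reg[r];
      draws(kept, c++) = sig_mu;
      kept++;
    }
  }

  NumericVector acc_a(n_country), acc_b(n_country);
  for (int i = 0; i < n_country; ++i) {
    acc_a[i] = ad_a[i].tot ? (double)ad_a[i].acc / ad_a[i].tot : NA_REAL;
    acc_b[i] = ad_b[i].tot ? (double)ad_b[i].acc / ad_b[i].tot : NA_REAL;
  }
  return List::create(_["draws"] = draws,
                      _["accept_alpha"] = acc_a, _["accept_beta"] = acc_b,
                      _["accept_gamma"] = NumericVector::create(
                        ad_gs.tot ? (double)ad_gs.acc / ad_gs.tot : NA_REAL,
                        ad_gh.tot ? (double)ad_gh.acc / ad_gh.tot : NA_REAL),
                      _["accept_sigma"] = NumericVector::create(
                        ad_sa.tot ? (double)ad_sa.acc / ad_sa.tot : NA_REAL,
                        ad_sb.tot ? (double)ad_sb.acc / ad_sb.tot : NA_REAL));
}

// One MCMC chain for the random-intercept logistic determinants model.
// logit P(y_r = 1) = b0 + x_r' b + u[c(r)],  u_i ~ N(0, sigma_u^2).
// Dummy columns are passed as row-index lists (0-based) because the design
// matrix is sparse 0/1; only affected rows are touched per update.
// [[Rcpp::export(.determ_chain_cpp)]]
List determ_chain_cpp(IntegerVector y, List col_rows, IntegerVector country,
                      int n_country, NumericVector beta_init,
                      bool random_intercept,
                      double prior_sd_fixed, int sd_family, double sd_scale,
                      int n_iter, int burn_in, int thin) {
  const int N = y.size();
  const int P = col_rows.size(); // non-intercept columns
  std::vector< std::vector<int> > cols(P);
  for (int j = 0; j < P; ++j) {
    IntegerVector r = col_rows[j];
    cols[j] = std::vector<int>(r.begin(), r.end());
  }
  std::vector< std::vector<int> > crows(n_country);
  for (int r = 0; r < N; ++r) crows[country[r]].push_back(r);

  double b0 = beta_init[0];
  std::vector<double> b(P);
  for (int j = 0; j < P; ++j) b[j] = beta_init[j + 1];
  std::vector<double> u(n_country, 0.0);
  double sig_u = 0.5;

  std::vector<double> eta(N, b0);
  for (int j = 0; j < P; ++j)
    for (size_t k = 0; k < cols[j].size(); ++k) eta[cols[j][k]] += b[j];
  // cached per-row log(1+exp(eta))
  std::vector<double> ce(N);
  for (int r = 0; r < N; ++r) ce[r] = log1pexp_(eta[r]);

  Adapt ad_b0(0.05);
  std::vector<Adapt> ad_b(P, Adapt(0.1)), ad_u(n_country, Adapt(0.15));
  Adapt ad_su(0.4), ad_sh(0.2);

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, 1 + P + n_country + 1);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept (dense)
    {
      double del = norm_rand() * ad_b0.scale;
      double d = dnorm_l(b0 + del, 0.0, prior_sd_fixed) - dnorm_l(b0, 0.0, prior_sd_fixed);
      for (int r = 0; r < N; ++r)
        d += y[r] * del - log1pexp_(eta[r] + del) + ce[r];
      ad_b0.tot++;
      if (std::log(unif_rand()) < d) {
        for (int r = 0; r < N; ++r) { eta[r] += del; ce[r] = log1pexp_(eta[r]); }
        b0 += del; ad_b0.acc++;
      }
    }
    // sparse dummy coefficients
    for (int j = 0; j < P; ++j) {
      double del = norm_rand() * ad_b[j].scale;
      double d = dnorm_l(b[j] + del, 0.0, prior_sd_fixed) - dnorm_l(b[j], 0.0, prior_sd_fixed);
      for (size_t k = 0; k < cols[j].size(); ++k) {
        int r = cols[j][k];
        d += y[r] * del - log1pexp_(eta[r] + del) + ce[r];
      }
      ad_b[j].tot++;
      if (std::log(unif_rand()) < d) {
        for (size_t k = 0; k < cols[j].size(); ++k) {
          int r = cols[j][k];
          eta[r] += del; ce[r] = log1pexp_(eta[r]);
        }
        b[j] += del; ad_b[j].acc++;
      }
    }
    if (random_intercept) {
      for (int i = 0; i < n_country; ++i) {
        double del = norm_rand() * ad_u[i].scale;
        double d = dnorm_l(u[i] + del, 0.0, sig_u) - dnorm_l(u[i], 0.0, sig_u);
        for (size_t k = 0; k < crows[i].size(); ++k) {
          int r = crows[i][k];
          d += y[r] * del - log1pexp_(eta[r] + del) + ce[r];
        }
        ad_u[i].tot++;
        if (std::log(unif_rand()) < d) {
          for (size_t k = 0; k < crows[i].size(); ++k) {
            int r = crows[i][k];
            eta[r] += del; ce[r] = log1pexp_(eta[r]);
          }
          u[i] += del; ad_u[i].acc++;
        }
      }
      // shear: shift the intercept against all group effects; the
      // likelihood is invariant, so acceptance depends on the priors only
      {
        double del = norm_rand() * ad_sh.scale;
        double d = dnorm_l(b0 + del, 0.0, prior_sd_fixed) -
                   dnorm_l(b0, 0.0, prior_sd_fixed);
        for (int i = 0; i < n_country; ++i)
          d += dnorm_l(u[i] - del, 0.0, sig_u) - dnorm_l(u[i], 0.0, sig_u);
        ad_sh.tot++;
        if (std::log(unif_rand()) < d) {
          b0 += del;
          for (int i = 0; i < n_country; ++i) u[i] -= del;
          ad_sh.acc++;
        }
      }
      double lp0 = lp_sd(sig_u, sd_family, sd_scale) + std::log(sig_u);
      for (int i = 0; i < n_country; ++i) lp0 += dnorm_l(u[i], 0.0, sig_u);
      double prop = sig_u * std::exp(norm_rand() * ad_su.scale);
      double lp1 = lp_sd(prop, sd_family, sd_scale) + std::log(prop);
      for (int i = 0; i < n_country; ++i) lp1 += dnorm_l(u[i], 0.0, prop);
      ad_su.tot++;
      if (std::log(unif_rand()) < lp1 - lp0) { sig_u = prop; ad_su.acc++; }
    }
    if (it <= burn_in && it % 50 == 0) {
      ad_b0.tune(); ad_su.tune(); ad_sh.tune();
      for (int j = 0; j < P; ++j) ad_b[j].tune();
      for (int i = 0; i < n_country; ++i) ad_u[i].tune();
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      int c = 0;
      draws(kept, c++) = b0;
      for (int j = 0; j < P; ++j) draws(kept, c++) = b[j];
      for (int i = 0; i < n_country; ++i) draws(kept, c++) = u[i];
      draws(kept, c++) = sig_u * sig_u;
      kept++;
    }
  }

  NumericVector acc(P + 1);
  acc[0] = ad_b0.tot ? (double)ad_b0.acc / ad_b0.tot : NA_REAL;
  for (int j = 0; j < P; ++j) acc[j + 1] = ad_b[j].tot ? (double)ad_b[j].acc / ad_b[j].tot : NA_REAL;
  return List::create(_["draws"] = draws, _["accept_fixed"] = acc);
}
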