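#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Two-group hierarchical model for the five-parameter asymmetric RL model.
//
// Unconstrained subject-level parameters z[j][p] are drawn from
//   z[j][p] ~ Normal(mu[p] + s_j * delta[p] / 2, sigma[p])
// where s_j = +1 for group A and -1 for group B, and are mapped to the
// model's bounds by a logistic transform (beta scaled to (0, beta_max)).
// Priors: mu ~ N(0,1), delta ~ N(0,0.5), sigma ~ half-N(0.5).
//
// Sampler: per sweep, conjugate Gibbs draw of (mu[p], delta[p]) jointly,
// random-walk MH on log sigma[p], and component-wise adaptive random-walk
// MH on each z[j][p] against the subject's choice likelihood. Proposal
// scales adapt toward 0.44 acceptance during warmup only.

static const double PROB_FLOOR = 1e-9;
static const int NPAR = 5;

inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct SubjData {
  std::vector<int> choice, outcome, session;
};

static double asym_loglik(const SubjData &d, const double *th) {
  // th: alpha_pos, alpha_neg, gamma_pos, gamma_neg, beta
  double V1 = 0, V2 = 0, ll = 0;
  int cur = -1;
  size_t n = d.choice.size();
  for (size_t t = 0; t < n; ++t) {
    if (d.session[t] != cur) { cur = d.session[t]; V1 = 0; V2 = 0; }
    double m = std::max(V1, V2) * th[4];
    double e1 = std::exp(V1 * th[4] - m), e2 = std::exp(V2 * th[4] - m);
    double p1 = e1 / (e1 + e2);
    double p = (d.choice[t] == 1) ? p1 : 1.0 - p1;
    ll += std::log(std::max(p, PROB_FLOOR));
    double *Vc = (d.choice[t] == 1) ? &V1 : &V2;
    double *Vu = (d.choice[t] == 1) ? &V2 : &V1;
    if (d.outcome[t] == 1) { *Vc += th[0] * (1.0 - *Vc); *Vu *= th[2]; }
    else                   { *Vc += th[1] * (0.0 - *Vc); *Vu *= th[3]; }
  }
  return ll;
}

static void transform_z(const double *z, double beta_max, double *th) {
  th[0] = inv_logit(z[0]);
  th[1] = inv_logit(z[1]);
  th[2] = inv_logit(z[2]);
  th[3] = inv_logit(z[3]);
  th[4] = beta_max * inv_logit(z[4]);
}

// [[Rcpp::export]]
List cpp_hier_mcmc(IntegerVector choice, IntegerVector outcome,
                   IntegerVector session, IntegerVector subject,
                   IntegerVector group_sign, int n_warmup, int n_draws,
                   double beta_max, int seed) {
  int J = group_sign.size();
  int n = choice.size();
  std::vector<SubjData> dat(J);
  for (int t = 0; t < n; ++t) {
    int j = subject[t];
    if (j < 0 || j >= J) stop("subject index out of range");
    dat[j].choice.push_back(choice[t]);
    dat[j].outcome.push_back(outcome[t]);
    dat[j].session.push_back(session[t]);
  }
  for (int j = 0; j < J; ++j)
    if (dat[j].choice.empty()) stop("subject with no trials");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  // state
  std::vector<double> mu(NPAR, 0.0), delta(NPAR, 0.0), sigma(NPAR, 0.5);
  std::vector<std::vector<double>> z(J, std::vector<double>(NPAR, 0.0));
  std::vector<double> ll(J);
  double th[NPAR];
  for (int j = 0; j < J; ++j) {
    for (int p = 0; p < NPAR; ++p) z[j][p] = 0.2 * rnorm01(rng);
    transform_z(z[j].data(), beta_max, th);
    ll[j] = asym_loglik(dat[j], th);
  }

  // adaptive proposal scales
  std::vector<std::vector<double>> step_z(J, std::vector<double>(NPAR, 0.3));
  std::vector<double> step_s(NPAR, 0.3);

  // prior variances on the unconstrained scale
  const double var_mu = 1.0, var_delta = 0.25, sd_sigma_prior = 0.5;

  int total = n_warmup + n_draws;
  NumericMatrix draws_mu(n_draws, NPAR), draws_delta(n_draws, NPAR),
                draws_sigma(n_draws, NPAR);
  NumericMatrix subj_mean(J, NPAR);  // running posterior mean on natural scale
  long n_acc_z = 0, n_prop_z = 0;

  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    double adapt = warm ? std::pow(it + 1.0, -0.6) : 0.0;

    for (int p = 0; p < NPAR; ++p) {
      // --- conjugate Gibbs for (mu, delta): z_j = mu + (s_j/2) delta + e
      double s2 = sigma[p] * sigma[p];
      double a11 = J / s2 + 1.0 / var_mu;            // X'X/s2 + prior prec
      double a22 = 0.0, a12 = 0.0, b1 = 0.0, b2 = 0.0;
      for (int j = 0; j < J; ++j) {
        double x = group_sign[j] / 2.0;
        a22 += x * x; a12 += x;
        b1 += z[j][p]; b2 += x * z[j][p];
      }
      a22 = a22 / s2 + 1.0 / var_delta;
      a12 /= s2; b1 /= s2; b2 /= s2;
      // 2x2 Cholesky of precision A, then sample N(A^-1 b, A^-1)
      double L11 = std::sqrt(a11);
      double L21 = a12 / L11;
      double L22 = std::sqrt(a22 - L21 * L21);
      // mean: solve A m = b
      double y1 = b1 / L11, y2 = (b2 - L21 * y1) / L22;
      double m2 = y2 / L22, m1 = (y1 - L21 * m2) / L11;
      // sample: m + L^-T eps
      double e1 = rnorm01(rng), e2 = rnorm01(rng);
      double x2 = e2 / L22, x1 = (e1 - L21 * x2) / L11;
      mu[p] = m1 + x1;
      delta[p] = m2 + x2;

      // --- MH on log sigma
      double lsig = std::log(sigma[p]);
      double lsig_new = lsig + step_s[p] * rnorm01(rng);
      double sig_new = std::exp(lsig_new);
      double lp_old = 0.0, lp_new = 0.0;
      for (int j = 0; j < J; ++j) {
        double mj = mu[p] + group_sign[j] * delta[p] / 2.0;
        double r = z[j][p] - mj;
        lp_old += -std::log(sigma[p]) - 0.5 * r * r / (sigma[p] * sigma[p]);
        lp_new += -std::log(sig_new) - 0.5 * r * r / (sig_new * sig_new);
      }
      // half-normal prior + log-scale Jacobian
      lp_old += -0.5 * sigma[p] * sigma[p] / (sd_sigma_prior * sd_sigma_prior) + lsig;
      lp_new += -0.5 * sig_new * sig_new / (sd_sigma_prior * sd_sigma_prior) + lsig_new;
      double acc_s = (std::log(runif01(rng)) < lp_new - lp_old) ? 1.0 : 0.0;
      if (acc_s > 0.5) sigma[p] = sig_new;
      if (warm) step_s[p] = std::exp(std::log(step_s[p]) + adapt * (acc_s - 0.44));
    }

    // --- subject-level z updates
    for (int j = 0; j < J; ++j) {
      for (int p = 0; p < NPAR; ++p) {
        double z_old = z[j][p];
        double mj = mu[p] + group_sign[j] * delta[p] / 2.0;
        double z_new = z_old + step_z[j][p] * rnorm01(rng);
        z[j][p] = z_new;
        transform_z(z[j].data(), beta_max, th);
        double ll_new = asym_loglik(dat[j], th);
        double r_old = z_old - mj, r_new = z_new - mj;
        double logr = (ll_new - ll[j])
          - 0.5 * (r_new * r_new - r_old * r_old) / (sigma[p] * sigma[p]);
        double acc = 0.0;
        if (std::log(runif01(rng)) < logr) { ll[j] = ll_new; acc = 1.0; }
        else z[j][p] = z_old;
        if (warm)
          step_z[j][p] = std::exp(std::log(step_z[j][p]) + adapt * (acc - 0.44));
        else { n_prop_z++; n_acc_z += (acc > 0.5); }
      }
    }

    if (!warm) {
      int k = it - n_warmup;
      for (int p = 0; p < NPAR; ++p) {
        draws_mu(k, p) = mu[p];
        draws_delta(k, p) = delta[p];
        draws_sigma(k, p) = sigma[p];
      }
      for (int j = 0; j < J; ++j) {
        transform_z(z[j].data(), beta_max, th);
        for (int p = 0; p < NPAR; ++p)
          subj_mean(j, p) += (th[p] - subj_mean(j, p)) / (k + 1.0);
      }
    }
  }

  return List::create(
    _["mu"] = draws_mu, _["delta"] = draws_delta, _["sigma"] = draws_sigma,
    _["subject_mean"] = subj_mean,
    _["accept_rate_z"] = n_prop_z ? (double)n_acc_z / n_prop_z : NA_REAL);
}
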