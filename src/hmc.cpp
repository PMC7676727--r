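// Hamiltonian Monte Carlo for the Bernoulli-logit strategy models.
//
// The likelihood of a model depends on an observation only through its
// participant and conditioning state (the basis row and the
// missing-information flag), so observations are aggregated into binomial
// cells (count n, cooperation count ysum) before sampling; with the OPA
// design that is at most 4 cells per participant plus one shared
// no-information cell, an order-of-magnitude fewer logistic evaluations
// than per-observation computation with identical results.
//
// Parameter layouts (unconstrained space):
//   multilevel (pooling = 0): mu[B], s[B] (log sigma), z[B*K] (b-major,
//     participant inner), then v if the model has a no-information term.
//   nonpool (pooling = 1): coef[B*K] (b-major), then v.
//   pool (pooling = 2): coef[B], then v.
// Multilevel coefficients are non-centered: coef_{b,k} = mu_b + z_{b,k} exp(s_b);
// sampling s = log(sigma) adds the log-Jacobian s_b to the target.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ModelData {
  NumericMatrix X;      // C x B basis matrix, one row per cell
  IntegerVector pid;    // 1..K participant index per cell
  LogicalVector miss;   // conditioning info missing -> predictor is v
  NumericVector n;      // observations in the cell
  NumericVector ysum;   // cooperative decisions in the cell
  int C, B, K;
  int pooling;          // 0 multilevel, 1 nonpool, 2 pool
  bool has_v;
  double mu_sd, sigma_sd, v_sd, coef_sd;
  int P;                // free-parameter count
};

inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

int param_dim(const ModelData& d) {
  int p;
  if (d.pooling == 0) p = 2 * d.B + d.B * d.K;
  else if (d.pooling == 1) p = d.B * d.K;
  else p = d.B;
  return p + (d.has_v ? 1 : 0);
}

inline double cell_eta(const ModelData& d, const std::vector<double>& th,
                       const std::vector<double>& sigma, int c, int v_idx) {
  if (d.has_v && d.miss[c]) return th[v_idx];
  double eta = 0.0;
  const int k = d.pid[c] - 1;
  for (int b = 0; b < d.B; ++b) {
    const double x = d.X(c, b);
    if (x == 0.0) continue;
    double coef;
    if (d.pooling == 0) coef = th[b] + th[2 * d.B + b * d.K + k] * sigma[b];
    else if (d.pooling == 1) coef = th[b * d.K + k];
    else coef = th[b];
    eta += x * coef;
  }
  return eta;
}

// Log posterior density (up to a constant) and its gradient.
double logp_grad(const ModelData& d, const std::vector<double>& th,
                 std::vector<double>& g) {
  std::fill(g.begin(), g.end(), 0.0);
  const int B = d.B, K = d.K;
  double lp = 0.0;
  const int v_idx = d.P - 1;  // valid only when has_v
  std::vector<double> sigma(B);
  if (d.pooling == 0) {
    for (int b = 0; b < B; ++b) sigma[b] = std::exp(th[B + b]);
  }
  for (int c = 0; c < d.C; ++c) {
    const double eta = cell_eta(d, th, sigma, c, v_idx);
    lp += d.ysum[c] * eta - d.n[c] * softplus(eta);
    const double p = 1.0 / (1.0 + std::exp(-eta));
    const double r = d.ysum[c] - d.n[c] * p;
    if (d.has_v && d.miss[c]) {
      g[v_idx] += r;
    } else {
      const int k = d.pid[c] - 1;
      for (int b = 0; b < B; ++b) {
        const double x = d.X(c, b);
        if (x == 0.0) continue;
        if (d.pooling == 0) {
          g[b] += r * x;
          g[2 * B + b * K + k] += r * x * sigma[b];
          g[B + b] += r * x * th[2 * B + b * K + k] * sigma[b];
        } else if (d.pooling == 1) {
          g[b * K + k] += r * x;
        } else {
          g[b] += r * x;
        }
      }
    }
  }
  // Priors
  if (d.pooling == 0) {
    const double mv = d.mu_sd * d.mu_sd, sv = d.sigma_sd * d.sigma_sd;
    for (int b = 0; b < B; ++b) {
      lp += -0.5 * th[b] * th[b] / mv;
      g[b] += -th[b] / mv;
      // half-normal on sigma plus Jacobian of sigma = exp(s)
      lp += -0.5 * sigma[b] * sigma[b] / sv + th[B + b];
      g[B + b] += -sigma[b] * sigma[b] / sv + 1.0;
      for (int k = 0; k < K; ++k) {
        const int i = 2 * B + b * K + k;
        lp += -0.5 * th[i] * th[i];
        g[i] += -th[i];
      }
    }
  } else {
    const double cv = d.coef_sd * d.coef_sd;
    const int ncoef = (d.pooling == 1) ? B * K : B;
    for (int i = 0; i < ncoef; ++i) {
      lp += -0.5 * th[i] * th[i] / cv;
      g[i] += -th[i] / cv;
    }
  }
  if (d.has_v) {
    const double vv = d.v_sd * d.v_sd;
    lp += -0.5 * th[v_idx] * th[v_idx] / vv;
    g[v_idx] += -th[v_idx] / vv;
  }
  return lp;
}

double kinetic(const std::vector<double>& p, const std::vector<double>& minv) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += minv[i] * p[i] * p[i];
  return 0.5 * k;
}

}  // namespace

// One HMC chain over binomial cells. Returns retained draws
// (iter - warmup rows) on the unconstrained scale, the divergence count
// and the adapted step size.
// [[Rcpp::export]]
List hmc_chain(NumericMatrix X, IntegerVector pid, LogicalVector miss,
               NumericVector n, NumericVector ysum, int K, int pooling,
               bool has_v, double mu_sd, double sigma_sd, double v_sd,
               double coef_sd, int iter, int warmup, double sim_time = 1.2,
               double target_accept = 0.8, double init_scale = 0.1) {
  ModelData d{X, pid, miss, n, ysum, (int)X.nrow(), (int)X.ncol(), K,
              pooling, has_v, mu_sd, sigma_sd, v_sd, coef_sd, 0};
  d.P = param_dim(d);
  const int P = d.P;
  if (iter <= warmup) stop("iter must exceed warmup");

  std::vector<double> th(P), g(P), minv(P, 1.0);
  for (int i = 0; i < P; ++i) th[i] = init_scale * norm_rand();
  double lp = logp_grad(d, th, g);

  // Crude initial step size: scale until one-step acceptance crosses 1/2.
  double eps = 0.1;
  {
    std::vector<double> p0(P), th1(P), g1(P), p1(P);
    for (int i = 0; i < P; ++i) p0[i] = norm_rand();
    const double H0 = -lp + kinetic(p0, minv);
    auto one_step = [&](double e) {
      th1 = th; g1 = g; p1 = p0;
      for (int i = 0; i < P; ++i) p1[i] += 0.5 * e * g1[i];
      for (int i = 0; i < P; ++i) th1[i] += e * minv[i] * p1[i];
      double lp1 = logp_grad(d, th1, g1);
      for (int i = 0; i < P; ++i) p1[i] += 0.5 * e * g1[i];
      return H0 - (-lp1 + kinetic(p1, minv));
    };
    double dH = one_step(eps);
    const int dir = (std::isfinite(dH) && dH > std::log(0.5)) ? 1 : -1;
    for (int tries = 0; tries < 40; ++tries) {
      eps *= (dir == 1) ? 2.0 : 0.5;
      dH = one_step(eps);
      const bool ok = std::isfinite(dH) && dH > std::log(0.5);
      if ((dir == 1 && !ok) || (dir == -1 && ok)) break;
      if (eps < 1e-7 || eps > 1e2) break;
    }
    eps = std::min(std::max(eps, 1e-6), 10.0);
  }

  // Dual averaging (Hoffman & Gelman 2014 defaults)
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  double mu_da = std::log(10.0 * eps), log_eps = std::log(eps),
         log_eps_bar = 0.0, Hbar = 0.0;
  int da_count = 0;

  // Mass-matrix adaptation window inside warmup
  const int mass_lo = (int)(0.25 * warmup), mass_hi = (int)(0.75 * warmup);
  std::vector<double> msum(P, 0.0), msq(P, 0.0);
  int mcount = 0;

  const int S = iter - warmup;
  NumericMatrix draws(S, P);
  int divergences = 0;
  long accept_n = 0;
  double accept_sum = 0.0;

  std::vector<double> p(P), th_prop(P), g_prop(P);
  for (int it = 0; it < iter; ++it) {
    const bool in_warmup = it < warmup;
    double eps_it = std::exp(in_warmup ? log_eps : log_eps_bar);
    eps_it *= 0.9 + 0.2 * unif_rand();
    int L = (int)std::lround(sim_time / eps_it);
    if (L < 1) L = 1;
    if (L > 1024) L = 1024;

    for (int i = 0; i < P; ++i) p[i] = norm_rand() / std::sqrt(minv[i]);
    const double H0 = -lp + kinetic(p, minv);
    th_prop = th; g_prop = g;
    double lp_prop = lp;
    for (int i = 0; i < P; ++i) p[i] += 0.5 * eps_it * g_prop[i];
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < P; ++i) th_prop[i] += eps_it * minv[i] * p[i];
      lp_prop = logp_grad(d, th_prop, g_prop);
      const double w = (l == L - 1) ? 0.5 : 1.0;
      for (int i = 0; i < P; ++i) p[i] += w * eps_it * g_prop[i];
      if (!std::isfinite(lp_prop)) break;
    }
    const double H1 = -lp_prop + kinetic(p, minv);
    const double dH = H0 - H1;
    const bool divergent = !std::isfinite(dH) || dH < -1000.0;
    const double a = divergent ? 0.0 : std::min(1.0, std::exp(dH));
    if (!divergent && unif_rand() < a) {
      th = th_prop; g = g_prop; lp = lp_prop;
    }
    if (divergent && !in_warmup) ++divergences;
    if (!in_warmup) { accept_sum += a; ++accept_n; }

    if (in_warmup) {
      // dual averaging on the acceptance statistic
      ++da_count;
      const double eta_t = 1.0 / (da_count + t0);
      Hbar = (1.0 - eta_t) * Hbar + eta_t * (target_accept - a);
      log_eps = mu_da - std::sqrt((double)da_count) / gamma * Hbar;
      const double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      if (it >= mass_lo && it < mass_hi) {
        for (int i = 0; i < P; ++i) { msum[i] += th[i]; msq[i] += th[i] * th[i]; }
        ++mcount;
      }
      if (it == mass_hi - 1 && mcount > 10) {
        for (int i = 0; i < P; ++i) {
          const double m = msum[i] / mcount;
          double v = (msq[i] - mcount * m * m) / (mcount - 1);
          // regularize toward unit scale as Stan does
          v = (mcount * v + 5.0) / (mcount + 5.0);
          minv[i] = std::max(v, 1e-4);
        }
        // restart step-size adaptation under the new metric
        mu_da = std::log(10.0 * std::exp(log_eps));
        Hbar = 0.0; log_eps_bar = 0.0; da_count = 0;
      }
    } else {
      draws(it - warmup, _) = NumericVector(th.begin(), th.end());
    }
  }

  return List::create(
    _["draws"] = draws,
    _["divergences"] = divergences,
    _["step_size"] = std::exp(log_eps_bar),
    _["accept_rate"] = accept_n > 0 ? accept_sum / accept_n : NA_REAL
  );
}

// Pointwise log-likelihood matrix (S draws x N observations) from draws on
// the constrained scale (multilevel columns: mu[B], sigma[B], z[B*K], v).
// Cell predictors are evaluated once per draw and expanded to observations
// through obs_cell (1-based cell index per observation).
// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(NumericMatrix draws, NumericMatrix X,
                                IntegerVector pid, LogicalVector miss,
                                IntegerVector obs_cell, IntegerVector y,
                                int K, int pooling, bool has_v) {
  const int S = draws.nrow(), C = X.nrow(), B = X.ncol();
  const int N = obs_cell.size();
  const int v_idx = draws.ncol() - 1;
  NumericMatrix out(S, N);
  std::vector<double> ll1(C), ll0(C);
  for (int s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      double eta;
      if (has_v && miss[c]) {
        eta = draws(s, v_idx);
      } else {
        eta = 0.0;
        const int k = pid[c] - 1;
        for (int b = 0; b < B; ++b) {
          const double x = X(c, b);
          if (x == 0.0) continue;
          double coef;
          if (pooling == 0)
            coef = draws(s, b) + draws(s, 2 * B + b * K + k) * draws(s, B + b);
          else if (pooling == 1)
            coef = draws(s, b * K + k);
          else
            coef = draws(s, b);
          eta += x * coef;
        }
      }
      const double sp = softplus(eta);
      ll1[c] = eta - sp;   // log p
      ll0[c] = -sp;        // log(1 - p)
    }
    for (int nn = 0; nn < N; ++nn) {
      const int c = obs_cell[nn] - 1;
      out(s, nn) = y[nn] == 1 ? ll1[c] : ll0[c];
    }
  }
  return out;
}
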