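// Hierarchical Rescorla-Wagner models for trial-level SCR data.
//
// Three model variants share one likelihood kernel:
//   1 = acquisition  : per-participant lr, a_cr, b_cr, a_crur, b_crur, log sigma
//   2 = extinction   : per-participant lr, a_cr, b_cr, log sigma (no reinforced trials)
//   3 = emotional    : lr_shared, state bias, a_cr, b_cr, a_crur, b_crur, log sigma
//
// Hierarchy (non-centered): theta_ij = mu_j + sd_j * z_ij with mu_j ~ N(0,1),
// sd_j ~ half-Cauchy(0,1) (sampled as log sd with Jacobian), z_ij ~ N(0,1).
// Links: learning rates inverse-logit, state bias tanh, sigma exp, rest identity.
//
// Observed SCR on trial t is Normal(m_t, sigma) with branch mean
//   m_t = a_cr + b_cr * EV_t   (unreinforced)  or  a_crur + b_crur * EV_t (reinforced)
// plus a soft non-negativity penalty  -kappa * min(0, m_t)^2  on the log density.
// EV evolves by EV <- EV + alpha * (US - EV); for the emotional-state model
// alpha = lr_shared * (1 + phase * bias), clipped into [0,1].
//
// Gradients are exact (forward sensitivity recursion for dEV/dalpha-parameters),
// enabling Hamiltonian Monte Carlo with dual-averaging step-size and diagonal
// mass-matrix adaptation.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct RwData {
  int model;            // 1, 2, 3
  int n_part;           // N
  int n_ind;            // J individual-level parameters
  double kappa;         // soft-constraint weight
  std::vector<int> us;          // per trial
  std::vector<double> amp;      // per trial
  std::vector<int> phase;       // per trial, +1/-1 (model 3)
  std::vector<int> str_start;   // per stream, 0-based offset
  std::vector<int> str_len;     // per stream
  std::vector<int> str_part;    // per stream, 0-based participant
  std::vector<double> str_ev0;  // per stream
};

int n_ind_params(int model) {
  if (model == 1) return 6;
  if (model == 2) return 4;
  return 7;
}

RwData unpack(const List& dat, int model, double kappa) {
  RwData d;
  d.model = model;
  d.kappa = kappa;
  d.n_part = as<int>(dat["n_participants"]);
  d.n_ind = n_ind_params(model);
  d.us = as<std::vector<int> >(dat["us"]);
  d.amp = as<std::vector<double> >(dat["amp"]);
  d.phase = as<std::vector<int> >(dat["phase"]);
  d.str_start = as<std::vector<int> >(dat["stream_start"]);
  d.str_len = as<std::vector<int> >(dat["stream_len"]);
  d.str_part = as<std::vector<int> >(dat["stream_participant"]);
  d.str_ev0 = as<std::vector<double> >(dat["stream_ev0"]);
  return d;
}

inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Log posterior and gradient over the unconstrained vector
// q = [mu (J), log_sd (J), z (N*J, participant-major within parameter)].
double log_post_grad(const std::vector<double>& q, std::vector<double>& grad,
                     const RwData& d) {
  const int J = d.n_ind, N = d.n_part;
  const int dim = 2 * J + N * J;
  std::fill(grad.begin(), grad.end(), 0.0);
  double lp = 0.0;

  std::vector<double> mu(J), lsd(J), sd(J);
  for (int j = 0; j < J; ++j) {
    mu[j] = q[j];
    lsd[j] = q[J + j];
    sd[j] = std::exp(lsd[j]);
    // mu ~ N(0,1)
    lp += -0.5 * mu[j] * mu[j];
    grad[j] += -mu[j];
    // sd ~ half-Cauchy(0,1), Jacobian of log-transform: + log sd
    lp += lsd[j] - std::log1p(sd[j] * sd[j]);
    grad[J + j] += 1.0 - 2.0 * sd[j] * sd[j] / (1.0 + sd[j] * sd[j]);
  }

  // constrained individual parameters and likelihood-gradient accumulators
  std::vector<double> theta(N * J), con(N * J), gcon(N * J, 0.0);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < J; ++j) {
      double z = q[2 * J + j * N + i];
      lp += -0.5 * z * z;
      theta[i * J + j] = mu[j] + sd[j] * z;
    }
  }
  for (int i = 0; i < N; ++i) {
    double* th = &theta[i * J];
    double* cn = &con[i * J];
    if (d.model == 3) {
      cn[0] = inv_logit(th[0]);            // lr_shared
      cn[1] = std::tanh(th[1]);            // state bias
      for (int j = 2; j < 6; ++j) cn[j] = th[j];
      cn[6] = std::exp(th[6]);             // sigma
    } else {
      cn[0] = inv_logit(th[0]);            // lr
      for (int j = 1; j < J - 1; ++j) cn[j] = th[j];
      cn[J - 1] = std::exp(th[J - 1]);     // sigma
    }
  }

  const double LOG_SQRT_2PI = 0.9189385332046727;
  const int n_stream = (int)d.str_start.size();
  for (int s = 0; s < n_stream; ++s) {
    const int i = d.str_part[s];
    const double* cn = &con[i * J];
    double* gc = &gcon[i * J];
    double lr = cn[0];
    double bias = (d.model == 3) ? cn[1] : 0.0;
    int o_a, o_sig;                         // offsets of a_cr and log-sigma slot
    if (d.model == 3) { o_a = 2; o_sig = 6; }
    else { o_a = 1; o_sig = J - 1; }
    const double sig = cn[o_sig];
    const double inv_s2 = 1.0 / (sig * sig);
    const double lsig = std::log(sig);

    double ev = d.str_ev0[s];
    double sA = 0.0, sB = 0.0;              // dEV/dlr(_shared), dEV/dbias
    const int off = d.str_start[s], len = d.str_len[s];
    for (int t = 0; t < len; ++t) {
      const int us = d.us[off + t];
      const double amp = d.amp[off + t];
      // branch mean
      int ia, ib;
      if (us == 1 && d.model != 2) { ia = o_a + 2; ib = o_a + 3; }
      else { ia = o_a; ib = o_a + 1; }
      const double m = cn[ia] + cn[ib] * ev;
      const double r = amp - m;
      lp += -0.5 * r * r * inv_s2 - lsig - LOG_SQRT_2PI;
      double dldm = r * inv_s2;
      if (m < 0.0) { lp -= d.kappa * m * m; dldm -= 2.0 * d.kappa * m; }
      gc[ia] += dldm;
      gc[ib] += dldm * ev;
      const double dldev = dldm * cn[ib];
      gc[0] += dldev * sA;
      if (d.model == 3) gc[1] += dldev * sB;
      gc[o_sig] += (r * r * inv_s2 - 1.0) / sig;   // d/d sigma

      // RW update with sensitivities
      double alpha, dA, dB = 0.0;
      if (d.model == 3) {
        const double p = (double)d.phase[off + t];
        double araw = lr * (1.0 + p * bias);
        if (araw <= 0.0) { alpha = 0.0; dA = 0.0; dB = 0.0; }
        else if (araw >= 1.0) { alpha = 1.0; dA = 0.0; dB = 0.0; }
        else { alpha = araw; dA = 1.0 + p * bias; dB = lr * p; }
      } else {
        alpha = lr; dA = 1.0;
      }
      const double pe = (double)us - ev;
      sA = sA * (1.0 - alpha) + dA * pe;
      if (d.model == 3) sB = sB * (1.0 - alpha) + dB * pe;
      ev += alpha * pe;
    }
  }

  // chain through links, then through the non-centered hierarchy
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < J; ++j) {
      double g = gcon[i * J + j];
      const double cv = con[i * J + j];
      if (d.model == 3) {
        if (j == 0) g *= cv * (1.0 - cv);
        else if (j == 1) g *= (1.0 - cv * cv);
        else if (j == 6) g *= cv;
      } else {
        if (j == 0) g *= cv * (1.0 - cv);
        else if (j == J - 1) g *= cv;
      }
      const double z = q[2 * J + j * N + i];
      grad[j] += g;                         // d theta / d mu = 1
      grad[J + j] += g * sd[j] * z;         // d theta / d log sd
      grad[2 * J + j * N + i] += g * sd[j] - z;
    }
  }
  (void)dim;
  return lp;
}

struct LeapfrogResult { double H; bool divergent; };

double kinetic(const std::vector<double>& p, const std::vector<double>& m_inv) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += 0.5 * p[i] * p[i] * m_inv[i];
  return k;
}

// One full trajectory of n_step leapfrog steps; q/grad updated in place.
LeapfrogResult leapfrog(std::vector<double>& q, std::vector<double>& p,
                        std::vector<double>& grad, double& lp,
                        double eps, int n_step,
                        const std::vector<double>& m_inv, const RwData& d) {
  const size_t n = q.size();
  LeapfrogResult res; res.divergent = false;
  for (int s = 0; s < n_step; ++s) {
    for (size_t i = 0; i < n; ++i) p[i] += 0.5 * eps * grad[i];
    for (size_t i = 0; i < n; ++i) q[i] += eps * m_inv[i] * p[i];
    lp = log_post_grad(q, grad, d);
    for (size_t i = 0; i < n; ++i) p[i] += 0.5 * eps * grad[i];
    if (!std::isfinite(lp)) { res.divergent = true; break; }
  }
  res.H = -lp + kinetic(p, m_inv);
  return res;
}

} // namespace

// [[Rcpp::export(name = ".rw_log_post")]]
List rw_log_post(NumericVector q, List data, int model, double kappa) {
  RwData d = unpack(data, model, kappa);
  std::vector<double> qv = as<std::vector<double> >(q);
  std::vector<double> grad(qv.size(), 0.0);
  double lp = log_post_grad(qv, grad, d);
  return List::create(_["lp"] = lp, _["grad"] = wrap(grad));
}

// [[Rcpp::export(name = ".rw_hmc")]]
List rw_hmc(List data, int model, int n_chains, int warmup, int iter,
            double kappa, double target_accept, double t_sim, int max_leapfrog) {
  RwData d = unpack(data, model, kappa);
  const int J = d.n_ind, N = d.n_part;
  const int dim = 2 * J + N * J;
  RNGScope scope;

  List chains(n_chains);
  NumericVector step_sizes(n_chains), accept_rates(n_chains);
  IntegerVector divergences(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    std::vector<double> q(dim), grad(dim), m_inv(dim, 1.0);
    for (int j = 0; j < J; ++j) {
      q[j] = 0.5 * norm_rand();
      q[J + j] = std::log(0.3) + 0.3 * norm_rand();
    }
    for (int k = 2 * J; k < dim; ++k) q[k] = 0.3 * norm_rand();
    double lp = log_post_grad(q, grad, d);

    // crude reasonable-step-size search (single-step acceptance near 0.5)
    double eps = 0.1;
    {
      std::vector<double> p0(dim);
      for (int k = 0; k < dim; ++k) p0[k] = norm_rand();
      double H0 = -lp + kinetic(p0, m_inv);
      std::vector<double> qt = q, pt = p0, gt = grad;
      double lpt = lp;
      LeapfrogResult r = leapfrog(qt, pt, gt, lpt, eps, 1, m_inv, d);
      double a = std::exp(H0 - r.H);
      int dir = (std::isfinite(a) && a > 0.5) ? 1 : -1;
      for (int rep = 0; rep < 40; ++rep) {
        eps *= (dir == 1) ? 2.0 : 0.5;
        qt = q; pt = p0; gt = grad; lpt = lp;
        r = leapfrog(qt, pt, gt, lpt, eps, 1, m_inv, d);
        a = std::isfinite(r.H) ? std::exp(H0 - r.H) : 0.0;
        if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break;
      }
    }

    // dual averaging state
    double mu_da = std::log(10.0 * eps), log_eps_bar = std::log(eps),
           h_bar = 0.0;
    const double gamma = 0.05, t0 = 10.0, kap_da = 0.75;
    int da_count = 0;
    // two mass-adaptation windows within warmup
    const int w1 = (int)(0.15 * warmup), w2 = (int)(0.45 * warmup),
              w3 = (int)(0.90 * warmup);
    std::vector<double> msum(dim, 0.0), msq(dim, 0.0);
    int mn = 0;

    NumericMatrix draws(iter, dim);
    int n_acc = 0, n_div = 0;
    const int total = warmup + iter;
    for (int it = 0; it < total; ++it) {
      std::vector<double> p(dim);
      for (int k = 0; k < dim; ++k) p[k] = norm_rand() / std::sqrt(m_inv[k]);
      const double H0 = -lp + kinetic(p, m_inv);
      int L = (int)std::lround(t_sim / eps);
      if (L < 1) L = 1;
      if (L > max_leapfrog) L = max_leapfrog;
      // mild trajectory-length jitter to avoid periodicity
      int Lu = (int)std::ceil(L * (0.85 + 0.15 * unif_rand()));
      if (Lu < 1) Lu = 1;
      std::vector<double> qn = q, gn = grad;
      double lpn = lp;
      LeapfrogResult r = leapfrog(qn, p, gn, lpn, eps, Lu, m_inv, d);
      double a;
      if (r.divergent || !std::isfinite(r.H) || (r.H - H0) > 1000.0) {
        a = 0.0; ++n_div;
      } else {
        a = std::exp(H0 - r.H);
        if (a > 1.0) a = 1.0;
      }
      if (unif_rand() < a) { q = qn; grad = gn; lp = lpn; if (it >= warmup) ++n_acc; }
      else if (it >= warmup) { /* rejected */ }

      if (it < warmup) {
        ++da_count;
        h_bar = (1.0 - 1.0 / (da_count + t0)) * h_bar +
                (target_accept - a) / (da_count + t0);
        double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
        double w = std::pow((double)da_count, -kap_da);
        log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
        eps = std::exp(log_eps);
        if (it >= w1) {
          for (int k = 0; k < dim; ++k) { msum[k] += q[k]; msq[k] += q[k] * q[k]; }
          ++mn;
        }
        if ((it == w2 - 1 || it == w3 - 1) && mn > 10) {
          for (int k = 0; k < dim; ++k) {
            double mean = msum[k] / mn;
            double var = (msq[k] / mn - mean * mean) * mn / (mn - 1.0);
            // regularize toward unit scale as in adaptive windowed samplers
            m_inv[k] = (mn * var + 5.0e-3 * 5.0) / (mn + 5.0);
            if (m_inv[k] < 1e-8) m_inv[k] = 1e-8;
            msum[k] = 0.0; msq[k] = 0.0;
          }
          mn = 0;
          // restart step-size adaptation around current eps
          mu_da = std::log(10.0 * eps);
          h_bar = 0.0; log_eps_bar = std::log(eps); da_count = 0;
        }
      } else {
        if (it == warmup) eps = std::exp(log_eps_bar > 0.0 || log_eps_bar < 0.0 ?
                                         log_eps_bar : std::log(eps));
        for (int k = 0; k < dim; ++k) draws(it - warmup, k) = q[k];
      }
    }
    chains[c] = draws;
    step_sizes[c] = eps;
    accept_rates[c] = iter > 0 ? (double)n_acc / iter : NA_REAL;
    divergences[c] = n_div;
  }
  return List::create(_["chains"] = chains, _["step_size"] = step_sizes,
                      _["accept_rate"] = accept_rates,
                      _["divergences"] = divergences, _["dim"] = dim);
}
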