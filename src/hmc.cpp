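// Hierarchical rank-dependent-utility model: joint log density with
// analytic gradients, and a static Hamiltonian Monte Carlo sampler with
// dual-averaging step-size adaptation and diagonal mass-matrix estimation.
//
// Parameter vector layout (unconstrained scale), K group-level types:
//   z[0..K-1]        group means mu_k            (prior N(prior_mean, prior_sd))
//   z[K..2K-1]       group log-SDs lambda_k      (prior N(0, 3), i.e. the
//                    lognormal(0,3) prior on sigma after change of variables)
//   z[2K..2K+nK-1]   subject raws eta_{i,k}      (prior N(0, 1))
// Non-centered hierarchy: z_ik = mu_k + exp(lambda_k) * eta_ik, mapped to the
// bounded supports by exp / Phi transforms; composed per-condition parameters
// are floored at a small positive value (sub-gradient zero when floored).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double POS_FLOOR = 1e-6;

struct Model {
  int K, n_sub, n_trial, family; // family: 0 linear, 1 KT, 2 Prelec-1
  // per type
  std::vector<double> lower, upper, prior_mean, prior_sd;
  std::vector<int> target; // 0 r, 1 gamma, 2 tau
  std::vector<int> condk;  // 0 baseline, 1 right-delta, 2 left-delta
  // per trial
  std::vector<int> sub, cond, y; // cond: 0 sham, 1 right, 2 left; y: 1 = A
  std::vector<double> sgn;       // +1 gain, -1 loss
  std::vector<double> lp_, lq_;  // log(p_best), log(1 - p_best), clamped
  std::vector<int> pflag;        // 0 interior, 1 p==0, 2 p==1
  // outcome magnitudes: sign and log|x| for xA_best, xA_worst, xB_best, xB_worst
  std::vector<double> xs[4], xl[4];
};

static Model build_model(const List& m) {
  Model M;
  M.K = as<int>(m["K"]);
  M.n_sub = as<int>(m["n_sub"]);
  M.family = as<int>(m["family"]);
  M.lower = as<std::vector<double>>(m["lower"]);
  M.upper = as<std::vector<double>>(m["upper"]);
  M.prior_mean = as<std::vector<double>>(m["prior_mean"]);
  M.prior_sd = as<std::vector<double>>(m["prior_sd"]);
  M.target = as<std::vector<int>>(m["target"]);
  M.condk = as<std::vector<int>>(m["condk"]);
  M.sub = as<std::vector<int>>(m["sub"]);
  M.cond = as<std::vector<int>>(m["cond"]);
  M.y = as<std::vector<int>>(m["y"]);
  M.sgn = as<std::vector<double>>(m["sgn"]);
  std::vector<double> p = as<std::vector<double>>(m["p_best"]);
  NumericMatrix X = m["outcomes"]; // n_trial x 4
  M.n_trial = (int)p.size();
  M.lp_.resize(M.n_trial); M.lq_.resize(M.n_trial); M.pflag.resize(M.n_trial);
  for (int j = 0; j < 4; ++j) { M.xs[j].resize(M.n_trial); M.xl[j].resize(M.n_trial); }
  const double eps = 1e-12;
  for (int t = 0; t < M.n_trial; ++t) {
    double pb = p[t];
    if (pb <= 0.0) M.pflag[t] = 1;
    else if (pb >= 1.0) M.pflag[t] = 2;
    else {
      M.pflag[t] = 0;
      double pc = std::min(std::max(pb, eps), 1.0 - eps);
      M.lp_[t] = std::log(pc);
      M.lq_[t] = std::log(1.0 - pc);
    }
    for (int j = 0; j < 4; ++j) {
      double x = X(t, j);
      M.xs[j][t] = (x > 0) - (x < 0);
      M.xl[j][t] = (x == 0.0) ? 0.0 : std::log(std::fabs(x));
    }
  }
  return M;
}

static inline double softplus(double x) {
  return (x > 0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// joint log density; fills grad (size dim) if non-null, pointwise
// log-likelihood (size n_trial) if non-null. Returns -Inf on failure.
static double logpost(const Model& M, const double* z, double* grad,
                      double* pointwise) {
  const int K = M.K, n = M.n_sub, dim = 2 * K + n * K;
  if (grad) std::fill(grad, grad + dim, 0.0);
  double lp = 0.0;
  const double* mu = z;
  const double* lam = z + K;
  const double* eta = z + 2 * K;

  // priors
  for (int k = 0; k < K; ++k) {
    double d = (mu[k] - M.prior_mean[k]) / M.prior_sd[k];
    lp += -0.5 * d * d - std::log(M.prior_sd[k]) - 0.5 * std::log(2.0 * M_PI);
    if (grad) grad[k] += -d / M.prior_sd[k];
    double dl = lam[k] / 3.0;
    lp += -0.5 * dl * dl - std::log(3.0) - 0.5 * std::log(2.0 * M_PI);
    if (grad) grad[K + k] += -lam[k] / 9.0;
  }
  for (int i = 0; i < n * K; ++i) {
    lp += -0.5 * eta[i] * eta[i] - 0.5 * std::log(2.0 * M_PI);
    if (grad) grad[2 * K + i] += -eta[i];
  }

  // constrained subject-level components
  std::vector<double> sig(K);
  for (int k = 0; k < K; ++k) sig[k] = std::exp(lam[k]);
  std::vector<double> cval(n * K), dcdz(n * K);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      double zz = mu[k] + sig[k] * eta[i * K + k];
      double c, d;
      if (!std::isfinite(zz)) return R_NegInf;
      if (!std::isfinite(M.upper[k])) {
        c = std::exp(zz); d = c;
      } else {
        double w = M.upper[k] - M.lower[k];
        c = M.lower[k] + w * R::pnorm(zz, 0.0, 1.0, 1, 0);
        d = w * R::dnorm(zz, 0.0, 1.0, 0);
      }
      cval[i * K + k] = c; dcdz[i * K + k] = d;
    }
  }

  // composed (r, gamma, tau) per subject x condition, with positive floor
  std::vector<double> par(n * 9), floored(n * 9, 0.0);
  for (int i = 0; i < n; ++i) {
    double base[3] = {0.0, 1.0, 0.0}; // gamma defaults to 1 for linear family
    double del[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}}; // [target][cond]
    for (int k = 0; k < K; ++k) {
      int tg = M.target[k];
      if (M.condk[k] == 0) base[tg] = cval[i * K + k];
      else del[tg][M.condk[k]] = cval[i * K + k];
    }
    for (int c = 0; c < 3; ++c)
      for (int tg = 0; tg < 3; ++tg) {
        double v = base[tg] + del[tg][c];
        if (v < POS_FLOOR) { v = POS_FLOOR; floored[(i * 3 + c) * 3 + tg] = 1.0; }
        par[(i * 3 + c) * 3 + tg] = v;
      }
  }

  // likelihood
  std::vector<double> gacc;
  if (grad) gacc.assign(n * 9, 0.0);
  for (int t = 0; t < M.n_trial; ++t) {
    int i = M.sub[t], c = M.cond[t];
    const double* pc = &par[(i * 3 + c) * 3];
    double r = pc[0], g = pc[1], tau = pc[2];

    double w, dw; // weight of the best outcome and d w / d gamma
    if (M.pflag[t] == 1) { w = 0.0; dw = 0.0; }
    else if (M.pflag[t] == 2) { w = 1.0; dw = 0.0; }
    else if (M.family == 0) { w = std::exp(M.lp_[t]); dw = 0.0; }
    else if (M.family == 1) {
      double pg = std::exp(g * M.lp_[t]), qg = std::exp(g * M.lq_[t]);
      double D = pg + qg, lnD = std::log(D);
      w = std::exp(g * M.lp_[t] - lnD / g);
      dw = w * (M.lp_[t] + lnD / (g * g) -
                (pg * M.lp_[t] + qg * M.lq_[t]) / (g * D));
    } else {
      double tt = -M.lp_[t];
      double a = std::pow(tt, g);
      w = std::exp(-a);
      dw = -w * a * std::log(tt);
    }

    double u[4], du[4];
    for (int j = 0; j < 4; ++j) {
      if (M.xs[j][t] == 0.0) { u[j] = 0.0; du[j] = 0.0; }
      else {
        u[j] = M.xs[j][t] * std::exp(r * M.xl[j][t]);
        du[j] = u[j] * M.xl[j][t];
      }
    }
    double euA = w * u[0] + (1.0 - w) * u[1];
    double euB = w * u[2] + (1.0 - w) * u[3];
    if (!std::isfinite(euA) || !std::isfinite(euB) || euA * euB <= 0.0)
      return R_NegInf;
    double L = std::log(std::fabs(euA)) - std::log(std::fabs(euB));
    double h = M.sgn[t] * tau * L / r;
    double ll = M.y[t] ? -softplus(-h) : -softplus(h);
    lp += ll;
    if (pointwise) pointwise[t] = ll;
    if (grad) {
      double P = 1.0 / (1.0 + std::exp(-h));
      double gh = (double)M.y[t] - P;
      double deuA_r = w * du[0] + (1.0 - w) * du[1];
      double deuB_r = w * du[2] + (1.0 - w) * du[3];
      double dL_r = deuA_r / euA - deuB_r / euB;
      double dh_r = M.sgn[t] * (tau / r) * dL_r - M.sgn[t] * tau * L / (r * r);
      double dh_tau = M.sgn[t] * L / r;
      double* ga = &gacc[(i * 3 + c) * 3];
      ga[0] += gh * dh_r;
      ga[2] += gh * dh_tau;
      if (M.family != 0) {
        double dL_g = (u[0] - u[1]) * dw / euA - (u[2] - u[3]) * dw / euB;
        ga[1] += gh * M.sgn[t] * (tau / r) * dL_g;
      }
    }
  }

  if (grad) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) {
        int tg = M.target[k], ck = M.condk[k];
        double d = 0.0;
        if (ck == 0) {
          for (int c = 0; c < 3; ++c)
            if (!floored[(i * 3 + c) * 3 + tg]) d += gacc[(i * 3 + c) * 3 + tg];
        } else if (!floored[(i * 3 + ck) * 3 + tg]) {
          d = gacc[(i * 3 + ck) * 3 + tg];
        }
        double dz = d * dcdz[i * K + k];
        grad[k] += dz;
        grad[K + k] += dz * sig[k] * eta[i * K + k];
        grad[2 * K + i * K + k] += dz * sig[k];
      }
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_log_density(NumericVector z, List model) {
  Model M = build_model(model);
  return logpost(M, z.begin(), nullptr, nullptr);
}

// [[Rcpp::export]]
List cpp_log_density_grad(NumericVector z, List model) {
  Model M = build_model(model);
  NumericVector grad(z.size());
  double lp = logpost(M, z.begin(), grad.begin(), nullptr);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik_one(NumericVector z, List model) {
  Model M = build_model(model);
  NumericVector ll(M.n_trial);
  logpost(M, z.begin(), nullptr, ll.begin());
  return ll;
}

// [[Rcpp::export]]
NumericMatrix cpp_pointwise_loglik(NumericMatrix draws, List model) {
  Model M = build_model(model);
  NumericMatrix out(draws.nrow(), M.n_trial);
  std::vector<double> z(draws.ncol()), ll(M.n_trial);
  for (int s = 0; s < draws.nrow(); ++s) {
    for (int j = 0; j < draws.ncol(); ++j) z[j] = draws(s, j);
    logpost(M, z.data(), nullptr, ll.data());
    for (int t = 0; t < M.n_trial; ++t) out(s, t) = ll[t];
  }
  return out;
}

struct HMCWork {
  const Model* M;
  int dim;
  std::vector<double> minv; // diagonal inverse mass (positions scale)
};

static double hamiltonian(HMCWork& W, const std::vector<double>& z,
                          const std::vector<double>& p, double& lp) {
  lp = logpost(*W.M, z.data(), nullptr, nullptr);
  double kin = 0.0;
  for (int d = 0; d < W.dim; ++d) kin += 0.5 * p[d] * p[d] * W.minv[d];
  return -lp + kin;
}

// one trajectory; returns accept probability, updates z in place if accepted
static double hmc_step(HMCWork& W, std::vector<double>& z, double eps, int L,
                       double& lp_cur, bool& divergent) {
  const int dim = W.dim;
  std::vector<double> p(dim), zq(z), grad(dim);
  for (int d = 0; d < dim; ++d) p[d] = norm_rand() / std::sqrt(W.minv[d]);
  double kin0 = 0.0;
  for (int d = 0; d < dim; ++d) kin0 += 0.5 * p[d] * p[d] * W.minv[d];
  double H0 = -lp_cur + kin0;

  double lp = logpost(*W.M, zq.data(), grad.data(), nullptr);
  if (!std::isfinite(lp)) { divergent = true; return 0.0; }
  bool bad = false;
  for (int s = 0; s < L; ++s) {
    for (int d = 0; d < dim; ++d) p[d] += 0.5 * eps * grad[d];
    for (int d = 0; d < dim; ++d) zq[d] += eps * W.minv[d] * p[d];
    lp = logpost(*W.M, zq.data(), grad.data(), nullptr);
    if (!std::isfinite(lp)) { bad = true; break; }
    for (int d = 0; d < dim; ++d) p[d] += 0.5 * eps * grad[d];
  }
  double alpha = 0.0;
  if (!bad) {
    double kin = 0.0;
    for (int d = 0; d < dim; ++d) kin += 0.5 * p[d] * p[d] * W.minv[d];
    double H1 = -lp + kin;
    double dH = H0 - H1;
    if (std::isfinite(dH)) {
      alpha = std::min(1.0, std::exp(dH));
      if (-dH > 1000.0) divergent = true;
    } else divergent = true;
  } else divergent = true;
  if (alpha > 0.0 && unif_rand() < alpha) { z = zq; lp_cur = lp; }
  return alpha;
}

// [[Rcpp::export]]
List cpp_hmc_chain(List model, NumericVector z_init, int n_warmup, int n_keep,
                   int max_leapfrog, double adapt_delta) {
  Model M = build_model(model);
  const int dim = 2 * M.K + M.n_sub * M.K;
  HMCWork W{&M, dim, std::vector<double>(dim, 1.0)};
  RNGScope rng;

  std::vector<double> z(z_init.begin(), z_init.end());
  double lp_cur = logpost(M, z.data(), nullptr, nullptr);
  if (!std::isfinite(lp_cur)) stop("initial point has zero posterior density");

  // heuristic initial step size: aim for accept prob near 0.5
  double eps = 0.1;
  {
    std::vector<double> zt = z;
    double lpt = lp_cur; bool dv = false;
    double a = hmc_step(W, zt, eps, 1, lpt, dv);
    double dir = (a > 0.5) ? 2.0 : 0.5;
    for (int it = 0; it < 30; ++it) {
      eps *= dir;
      zt = z; lpt = lp_cur; dv = false;
      a = hmc_step(W, zt, eps, 1, lpt, dv);
      if ((dir > 1.0 && a < 0.5) || (dir < 1.0 && a > 0.5)) break;
    }
  }

  // dual averaging (Nesterov) targeting adapt_delta
  double mu_da = std::log(10.0 * eps), log_ebar = std::log(eps), hbar = 0.0;
  const double gam = 0.05, t0 = 10.0, kap = 0.75;
  int da_iter = 0;
  auto da_update = [&](double alpha) {
    da_iter++;
    double frac = 1.0 / (da_iter + t0);
    hbar = (1.0 - frac) * hbar + frac * (adapt_delta - alpha);
    double log_eps = mu_da - std::sqrt((double)da_iter) / gam * hbar;
    double w = std::pow((double)da_iter, -kap);
    log_ebar = w * log_eps + (1.0 - w) * log_ebar;
    eps = std::exp(log_eps);
  };

  // mass-adaptation window inside warmup
  int wlo = (int)(0.25 * n_warmup), whi = (int)(0.75 * n_warmup);
  std::vector<double> msum(dim, 0.0), msq(dim, 0.0);
  int mcount = 0;

  NumericMatrix draws(n_keep, dim);
  NumericVector lp_keep(n_keep);
  int divergences = 0;
  double acc_sum = 0.0; int acc_n = 0;

  int total = n_warmup + n_keep;
  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    int L = 1 + (int)(unif_rand() * max_leapfrog);
    if (L > max_leapfrog) L = max_leapfrog;
    bool dv = false;
    double alpha = hmc_step(W, z, warm ? eps : std::exp(log_ebar), L, lp_cur, dv);
    if (dv && !warm) divergences++;
    if (warm) {
      da_update(alpha);
      if (it >= wlo && it < whi) {
        mcount++;
        for (int d = 0; d < dim; ++d) { msum[d] += z[d]; msq[d] += z[d] * z[d]; }
        if (it == whi - 1 && mcount > 10) {
          for (int d = 0; d < dim; ++d) {
            double m = msum[d] / mcount;
            double v = msq[d] / mcount - m * m;
            if (v < 0) v = 0;
            W.minv[d] = (mcount / (mcount + 5.0)) * v + 1e-3 * (5.0 / (mcount + 5.0));
          }
          // restart step-size adaptation for the new metric
          mu_da = std::log(10.0 * eps);
          log_ebar = std::log(eps); hbar = 0.0; da_iter = 0;
        }
      }
    } else {
      acc_sum += alpha; acc_n++;
      int row = it - n_warmup;
      for (int d = 0; d < dim; ++d) draws(row, d) = z[d];
      lp_keep[row] = lp_cur;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws, _["lp"] = lp_keep,
    _["step_size"] = std::exp(log_ebar),
    _["accept_rate"] = acc_n ? acc_sum / acc_n : NA_REAL,
    _["divergences"] = divergences,
    _["inv_mass"] = NumericVector(W.minv.begin(), W.minv.end()));
}
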