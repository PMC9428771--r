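// Hamiltonian Monte Carlo sampler for first-difference (random-walk)
// Poisson/binomial incidence models.
//
// Parameterization is non-centered: eta_1 = m0 + s0 * e1raw and
// eta_t = eta_{t-1} + (diag(tau) L z_t), with e1raw, z ~ N(0,1) and
// tau = exp(lt) carrying the half-normal prior plus log Jacobian.
// L is the Cholesky factor of the group correlation matrix (identity
// unless `joint`); it is updated by a random-walk Metropolis step in
// the unconstrained tanh/canonical-partial-correlation space with an
// LKJ prior, interleaved with the HMC updates of (e1raw, z, lt).
//
// Step size is tuned by dual averaging toward a configurable target
// acceptance rate and a diagonal mass matrix is estimated from warmup
// windows.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const int FAM_POISSON = 0;
const int FAM_BINOMIAL = 1;

struct Model {
  int n;       // periods
  int k;       // groups sharing the correlation structure
  int family;
  std::vector<double> y;  // n*k, column-major [t + n*g]
  std::vector<double> P;
  double m0, s0;    // prior on eta_1
  double tau_sd;    // half-normal scale for tau
  int dim() const { return k * (n + 1); }
  // layout: q[g] = e1raw_g, q[k+g] = log tau_g,
  //         q[2k + (t-1)*k + g] = z increment for period t (t = 1..n-1, 0-based)
};

inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

inline double log1pexp(double x) {
  if (x > 0.0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// eta and the cumulative scaled increments c (eta = eta1 + tau * c)
void compute_eta(const Model& M, const std::vector<double>& q,
                 const std::vector<double>& L, std::vector<double>& eta,
                 std::vector<double>& c) {
  const int n = M.n, k = M.k;
  for (int g = 0; g < k; ++g) {
    c[0 + n * g] = 0.0;
    eta[0 + n * g] = M.m0 + M.s0 * q[g];
  }
  for (int t = 1; t < n; ++t) {
    const double* zt = &q[2 * k + (t - 1) * k];
    for (int g = 0; g < k; ++g) {
      double lz = 0.0;
      for (int j = 0; j <= g; ++j) lz += L[g + k * j] * zt[j];
      c[t + n * g] = c[(t - 1) + n * g] + lz;
    }
  }
  for (int g = 0; g < k; ++g) {
    const double tau = std::exp(q[k + g]);
    const double eta1 = eta[0 + n * g];
    for (int t = 1; t < n; ++t) eta[t + n * g] = eta1 + tau * c[t + n * g];
  }
}

double log_lik(const Model& M, const std::vector<double>& eta) {
  double ll = 0.0;
  const int n = M.n, k = M.k;
  for (int g = 0; g < k; ++g) {
    for (int t = 0; t < n; ++t) {
      const double e = eta[t + n * g];
      const double yy = M.y[t + n * g], pp = M.P[t + n * g];
      if (M.family == FAM_POISSON) {
        if (e > 500.0) return -std::numeric_limits<double>::infinity();
        ll += yy * e - pp * std::exp(e);
      } else {
        ll += yy * e - pp * log1pexp(e);
      }
    }
  }
  return ll;
}

// log posterior (up to constants) and its gradient; L held fixed.
double logp_grad(const Model& M, const std::vector<double>& q,
                 const std::vector<double>& L, std::vector<double>& grad,
                 std::vector<double>& eta, std::vector<double>& c,
                 std::vector<double>& glik) {
  const int n = M.n, k = M.k;
  compute_eta(M, q, L, eta, c);

  double lp = 0.0;
  for (int g = 0; g < k; ++g) {
    for (int t = 0; t < n; ++t) {
      const double e = eta[t + n * g];
      const double yy = M.y[t + n * g], pp = M.P[t + n * g];
      if (M.family == FAM_POISSON) {
        if (e > 500.0) {
          lp = -std::numeric_limits<double>::infinity();
          glik[t + n * g] = 0.0;
          continue;
        }
        const double mu = pp * std::exp(e);
        lp += yy * e - mu;
        glik[t + n * g] = yy - mu;
      } else {
        lp += yy * e - pp * log1pexp(e);
        glik[t + n * g] = yy - pp * invlogit(e);
      }
    }
  }
  // priors (standard normal on e1raw and z; half-normal + Jacobian on tau)
  for (int g = 0; g < k; ++g) {
    const double tau = std::exp(q[k + g]);
    lp += -0.5 * q[g] * q[g];
    lp += q[k + g] - 0.5 * (tau / M.tau_sd) * (tau / M.tau_sd);
  }
  for (int i = 2 * k; i < M.dim(); ++i) lp += -0.5 * q[i] * q[i];

  if (!std::isfinite(lp)) {
    std::fill(grad.begin(), grad.end(), 0.0);
    return lp;
  }

  // suffix sums G[t,g] = sum_{t' >= t} glik[t',g]
  std::vector<double> G(n * k);
  for (int g = 0; g < k; ++g) {
    double acc = 0.0;
    for (int t = n - 1; t >= 0; --t) {
      acc += glik[t + n * g];
      G[t + n * g] = acc;
    }
  }
  for (int g = 0; g < k; ++g) {
    const double tau = std::exp(q[k + g]);
    grad[g] = M.s0 * G[0 + n * g] - q[g];
    double acc = 0.0;
    for (int t = 1; t < n; ++t) acc += glik[t + n * g] * c[t + n * g];
    grad[k + g] = tau * acc + 1.0 - (tau / M.tau_sd) * (tau / M.tau_sd);
  }
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double acc = 0.0;
      for (int g = j; g < k; ++g)
        acc += std::exp(q[k + g]) * L[g + k * j] * G[t + n * g];
      const int idx = 2 * k + (t - 1) * k + j;
      grad[idx] = acc - q[idx];
    }
  }
  return lp;
}

// Cholesky factor of a correlation matrix from unconstrained u (tanh CPCs);
// returns log |Jacobian| of the u -> L map.
double build_chol(int k, const std::vector<double>& u, std::vector<double>& L) {
  std::fill(L.begin(), L.end(), 0.0);
  L[0] = 1.0;
  double jac = 0.0;
  int idx = 0;
  for (int i = 1; i < k; ++i) {
    double sum_sqs = 0.0;
    for (int j = 0; j < i; ++j) {
      const double z = std::tanh(u[idx++]);
      jac += std::log1p(-z * z);               // tanh Jacobian
      if (j > 0) jac += 0.5 * std::log1p(-sum_sqs);
      L[i + k * j] = z * std::sqrt(1.0 - sum_sqs);
      sum_sqs += L[i + k * j] * L[i + k * j];
    }
    L[i + k * i] = std::sqrt(1.0 - sum_sqs);
  }
  return jac;
}

// LKJ log density of the correlation matrix in Cholesky form (up to constant)
double lkj_chol_lpdf(int k, double shape, const std::vector<double>& L) {
  double lp = 0.0;
  for (int i = 1; i < k; ++i)
    lp += (k - (i + 1) + 2.0 * shape - 2.0) * std::log(L[i + k * i]);
  return lp;
}

struct DualAvg {
  double mu, logeps, logepsbar, hbar;
  double delta = 0.9;  // target acceptance rate
  int count;
  void reset(double eps) {
    mu = std::log(10.0 * eps);
    logeps = std::log(eps);
    logepsbar = 0.0;
    hbar = 0.0;
    count = 0;
  }
  void update(double accept_prob) {
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    ++count;
    hbar += (delta - accept_prob - hbar) / (count + t0);
    logeps = mu - std::sqrt((double)count) / gamma * hbar;
    const double w = std::pow((double)count, -kappa);
    logepsbar = w * logeps + (1.0 - w) * logepsbar;
  }
};

struct ChainResult {
  std::vector<double> eta_draws;   // retained * n * k
  std::vector<double> tau_draws;   // retained * k
  std::vector<double> corr_draws;  // retained * k * k (joint only)
  int divergent = 0;
  double accept_sum = 0.0;
  double eps_final = 0.0;
};

void run_chain(const Model& M, bool joint, double lkj_shape, int draws,
               int warmup, double target_accept, int seed, int series_id,
               int chain, ChainResult& out) {
  const int d = M.dim(), n = M.n, k = M.k;
  const int retained = draws - warmup;
  const int q_corr = joint ? k * (k - 1) / 2 : 0;

  std::seed_seq ss{seed, series_id, chain, 20260926};
  std::mt19937_64 rng(ss);
  std::normal_distribution<double> rnorm01;
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  std::vector<double> q(d, 0.0), grad(d), eta(n * k), c(n * k), glik(n * k);
  std::vector<double> L(k * k, 0.0);
  for (int g = 0; g < k; ++g) L[g + k * g] = 1.0;
  std::vector<double> u(q_corr, 0.0);
  double jac = 0.0;
  if (joint) jac = build_chol(k, u, L);

  // initialize near the pooled empirical rate, jittered per chain
  for (int g = 0; g < k; ++g) {
    double ys = 0.0, ps = 0.0;
    for (int t = 0; t < n; ++t) {
      ys += M.y[t + n * g];
      ps += M.P[t + n * g];
    }
    double e0;
    if (M.family == FAM_POISSON) {
      e0 = std::log((ys + 0.5) / ps);
    } else {
      const double pr = (ys + 0.5) / (ps + 1.0);
      e0 = std::log(pr / (1.0 - pr));
    }
    double raw = (e0 - M.m0) / M.s0;
    if (raw > 4.0) raw = 4.0;
    if (raw < -4.0) raw = -4.0;
    q[g] = raw + 0.1 * rnorm01(rng);
    q[k + g] = std::log(0.1) + 0.1 * rnorm01(rng);
  }
  for (int i = 2 * k; i < d; ++i) q[i] = 0.1 * rnorm01(rng);

  std::vector<double> invmass(d, 1.0);

  // crude initial step size: shrink until one leapfrog step keeps the
  // Hamiltonian error moderate
  double eps = 0.1;
  {
    std::vector<double> q0 = q, g0(d), p0(d);
    double lp0 = logp_grad(M, q0, L, g0, eta, c, glik);
    for (int i = 0; i < d; ++i) p0[i] = rnorm01(rng);
    for (int tries = 0; tries < 30; ++tries) {
      std::vector<double> qq = q0, gg = g0, pp = p0;
      for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gg[i];
      for (int i = 0; i < d; ++i) qq[i] += eps * pp[i];
      double lp1 = logp_grad(M, qq, L, gg, eta, c, glik);
      for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gg[i];
      double h0 = -lp0, h1 = -lp1;
      for (int i = 0; i < d; ++i) {
        h0 += 0.5 * p0[i] * p0[i];
        h1 += 0.5 * pp[i] * pp[i];
      }
      if (std::isfinite(h1) && h1 - h0 < 1.0) break;
      eps *= 0.5;
    }
  }

  DualAvg da;
  da.delta = target_accept;
  da.reset(eps);
  double log_sdu = std::log(0.5);  // Metropolis scale for correlation update

  // mass-adaptation windows
  const bool adapt_mass = warmup >= 60;
  const int w_init = adapt_mass ? std::max(50, warmup / 5) : warmup;
  const int w_mid = adapt_mass ? (int)(0.45 * warmup) : warmup;
  const int w_late = adapt_mass ? (int)(0.85 * warmup) : warmup;
  std::vector<double> wsum(d, 0.0), wsum2(d, 0.0);
  int wcount = 0;
  auto window_reset = [&]() {
    std::fill(wsum.begin(), wsum.end(), 0.0);
    std::fill(wsum2.begin(), wsum2.end(), 0.0);
    wcount = 0;
  };
  auto window_apply = [&]() {
    if (wcount < 10) return;
    for (int i = 0; i < d; ++i) {
      const double m = wsum[i] / wcount;
      double v = wsum2[i] / wcount - m * m;
      if (v < 0.0) v = 0.0;
      v = (wcount / (wcount + 5.0)) * v + 1e-3 * (5.0 / (wcount + 5.0));
      invmass[i] = v;
    }
  };

  std::vector<double> p(d), qprop(d), gprop(d);
  const double lambda = 6.0;  // nominal integration time

  double lp_cur;
  for (int iter = 0; iter < draws; ++iter) {
    lp_cur = logp_grad(M, q, L, grad, eta, c, glik);

    // --- HMC update of q given L ---
    for (int i = 0; i < d; ++i) p[i] = rnorm01(rng) / std::sqrt(invmass[i]);
    double h0 = -lp_cur;
    for (int i = 0; i < d; ++i) h0 += 0.5 * p[i] * p[i] * invmass[i];

    int nsteps = (int)std::round(lambda / eps);
    if (nsteps < 1) nsteps = 1;
    if (nsteps > 100) nsteps = 100;
    // jitter +-30%
    {
      const int lo = std::max(1, (int)std::floor(0.7 * nsteps));
      const int hi = std::max(lo, (int)std::ceil(1.3 * nsteps));
      nsteps = lo + (int)(runif01(rng) * (hi - lo + 1));
      if (nsteps > hi) nsteps = hi;
    }

    qprop = q;
    gprop = grad;
    std::vector<double> pp = p;
    bool bad = false;
    double lp_prop = lp_cur;
    for (int s = 0; s < nsteps; ++s) {
      for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gprop[i];
      for (int i = 0; i < d; ++i) qprop[i] += eps * invmass[i] * pp[i];
      lp_prop = logp_grad(M, qprop, L, gprop, eta, c, glik);
      if (!std::isfinite(lp_prop)) {
        bad = true;
        break;
      }
      for (int i = 0; i < d; ++i) pp[i] += 0.5 * eps * gprop[i];
    }
    double accept_prob = 0.0;
    bool divergent_now = false;
    if (!bad) {
      double h1 = -lp_prop;
      for (int i = 0; i < d; ++i) h1 += 0.5 * pp[i] * pp[i] * invmass[i];
      const double dh = h0 - h1;  // log acceptance ratio
      if (!std::isfinite(dh) || dh < -1000.0) {
        divergent_now = true;
      } else {
        accept_prob = dh > 0.0 ? 1.0 : std::exp(dh);
        if (std::log(runif01(rng)) < dh) {
          q = qprop;
          lp_cur = lp_prop;
        }
      }
    } else {
      divergent_now = true;
    }

    if (iter < warmup) {
      da.update(accept_prob);
      eps = std::exp(da.logeps);
      if (adapt_mass && iter >= w_init && iter < w_late) {
        // collect variances (current q)
        for (int i = 0; i < d; ++i) {
          wsum[i] += q[i];
          wsum2[i] += q[i] * q[i];
        }
        ++wcount;
        if (iter + 1 == w_mid || iter + 1 == w_late) {
          window_apply();
          window_reset();
          da.reset(std::exp(da.logeps));
        }
      }
      if (iter + 1 == warmup) {
        eps = std::exp(da.logepsbar);
        out.eps_final = eps;
      }
    } else {
      out.accept_sum += accept_prob;
      if (divergent_now) ++out.divergent;
    }

    // --- Metropolis update of the correlation Cholesky (joint) ---
    if (joint) {
      compute_eta(M, q, L, eta, c);
      const double ll_cur = log_lik(M, eta);
      const double tgt_cur = ll_cur + lkj_chol_lpdf(k, lkj_shape, L) + jac;
      std::vector<double> uprop(q_corr), Lprop(k * k);
      const double sdu = std::exp(log_sdu);
      for (int i = 0; i < q_corr; ++i) uprop[i] = u[i] + sdu * rnorm01(rng);
      const double jac_prop = build_chol(k, uprop, Lprop);
      compute_eta(M, q, Lprop, eta, c);
      const double ll_prop = log_lik(M, eta);
      const double tgt_prop =
          ll_prop + lkj_chol_lpdf(k, lkj_shape, Lprop) + jac_prop;
      const double a = tgt_prop - tgt_cur;
      const double alpha = a > 0.0 ? 1.0 : std::exp(a);
      if (std::log(runif01(rng)) < a) {
        u = uprop;
        L = Lprop;
        jac = jac_prop;
      }
      if (iter < warmup)
        log_sdu += (alpha - 0.35) / std::pow(iter + 1.0, 0.6);
    }

    // --- store retained draw ---
    if (iter >= warmup) {
      const int r = iter - warmup;
      compute_eta(M, q, L, eta, c);
      for (int g = 0; g < k; ++g)
        for (int t = 0; t < n; ++t)
          out.eta_draws[r + retained * (t + n * g)] = eta[t + n * g];
      for (int g = 0; g < k; ++g)
        out.tau_draws[r + retained * g] = std::exp(q[k + g]);
      if (joint) {
        // C = L L'
        for (int i = 0; i < k; ++i)
          for (int j = 0; j < k; ++j) {
            double s = 0.0;
            for (int l = 0; l <= std::min(i, j); ++l)
              s += L[i + k * l] * L[j + k * l];
            out.corr_draws[r + retained * (i + k * j)] = s;
          }
      }
    }
  }
  if (out.eps_final == 0.0) out.eps_final = eps;
}

}  // namespace

// [[Rcpp::export]]
List rw_sampler_cpp(NumericMatrix y, NumericMatrix P, std::string family,
                    double m0, double s0, double tau_sd, bool joint,
                    double lkj_shape, int chains, int draws, int warmup,
                    double target_accept, int seed, int series_id) {
  Model M;
  M.n = y.nrow();
  M.k = y.ncol();
  M.family = (family == "binomial") ? FAM_BINOMIAL : FAM_POISSON;
  M.y.assign(y.begin(), y.end());
  M.P.assign(P.begin(), P.end());
  M.m0 = m0;
  M.s0 = s0;
  M.tau_sd = tau_sd;

  const int retained = draws - warmup;
  const int n = M.n, k = M.k;

  NumericVector eta_out(Dimension(retained, n * k, chains));
  NumericVector tau_out(Dimension(retained, k, chains));
  NumericVector corr_out(joint ? retained * k * k * chains : 0);
  IntegerVector divergent(chains);
  NumericVector accept(chains), eps(chains);

  for (int ch = 0; ch < chains; ++ch) {
    ChainResult res;
    res.eta_draws.resize((size_t)retained * n * k);
    res.tau_draws.resize((size_t)retained * k);
    if (joint) res.corr_draws.resize((size_t)retained * k * k);
    run_chain(M, joint, lkj_shape, draws, warmup, target_accept, seed,
              series_id, ch + 1, res);
    std::copy(res.eta_draws.begin(), res.eta_draws.end(),
              eta_out.begin() + (size_t)ch * retained * n * k);
    std::copy(res.tau_draws.begin(), res.tau_draws.end(),
              tau_out.begin() + (size_t)ch * retained * k);
    if (joint)
      std::copy(res.corr_draws.begin(), res.corr_draws.end(),
                corr_out.begin() + (size_t)ch * retained * k * k);
    divergent[ch] = res.divergent;
    accept[ch] = retained > 0 ? res.accept_sum / retained : 0.0;
    eps[ch] = res.eps_final;
  }
  if (joint) corr_out.attr("dim") = Dimension(retained, k * k, chains);

  return List::create(
      Named("eta") = eta_out, Named("tau") = tau_out, Named("corr") = corr_out,
      Named("divergent") = divergent, Named("accept") = accept,
      Named("stepsize") = eps, Named("retained") = retained);
}
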