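#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Poisson sampler on R's uniform stream: inversion for small means,
// Hormann's PTRS transformed rejection for large means. Cheaper than
// R::rpois here because the mean differs on every call, defeating rpois'
// internal caching.
static double rpois_fast(double lambda) {
  if (lambda <= 0.0) return 0.0;
  if (lambda < 12.0) {
    double L = std::exp(-lambda), p = 1.0;
    double k = -1.0;
    do { ++k; p *= R::unif_rand(); } while (p > L);
    return k;
  }
  if (lambda > 1e8) {
    // normal limit; relative error is negligible at this scale
    double v = R::norm_rand();
    double x = std::floor(lambda + std::sqrt(lambda) * v + 0.5);
    return x < 0.0 ? 0.0 : x;
  }
  const double b = 0.931 + 2.53 * std::sqrt(lambda);
  const double a = -0.059 + 0.02483 * b;
  const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
  const double vr = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    double u = R::unif_rand() - 0.5;
    double v = R::unif_rand();
    double us = 0.5 - std::fabs(u);
    double k = std::floor((2.0 * a / us + b) * u + lambda + 0.43);
    if (us >= 0.07 && v <= vr) return k;
    if (k < 0.0 || (us < 0.013 && v > us)) continue;
    if (std::log(v) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
        k * std::log(lambda) - lambda - std::lgamma(k + 1.0)) {
      return k;
    }
  }
}

// Sparse view of the network: per-reaction reactant indices/multiplicities
// and nonzero stoichiometry entries. Built once per simulation call.
struct SparseNet {
  int ns, nr;
  std::vector<std::vector<int>> re_idx;    // reactant species per reaction
  std::vector<std::vector<int>> re_mult;   // multiplicities
  std::vector<std::vector<int>> st_idx;    // species with nonzero stoich
  std::vector<std::vector<int>> st_val;    // stoichiometric change
  std::vector<double> g;                   // tau-selection order factor
  std::vector<double> rates;

  SparseNet(const IntegerMatrix& stoich, const IntegerMatrix& reactant_mat,
            const NumericVector& rate_vec) {
    ns = stoich.nrow(); nr = stoich.ncol();
    re_idx.resize(nr); re_mult.resize(nr);
    st_idx.resize(nr); st_val.resize(nr);
    g.assign(ns, 1.0);
    rates.assign(rate_vec.begin(), rate_vec.end());
    for (int j = 0; j < nr; ++j) {
      int order = 0;
      for (int i = 0; i < ns; ++i) {
        int m = reactant_mat(i, j);
        if (m > 0) {
          re_idx[j].push_back(i); re_mult[j].push_back(m); order += m;
        }
        int v = stoich(i, j);
        if (v != 0) { st_idx[j].push_back(i); st_val[j].push_back(v); }
      }
      for (size_t k = 0; k < re_idx[j].size(); ++k)
        if (order > g[re_idx[j][k]]) g[re_idx[j][k]] = order;
    }
  }

  inline double propensity(int j, const std::vector<double>& x) const {
    double a = rates[j];
    const std::vector<int>& ri = re_idx[j];
    const std::vector<int>& rm = re_mult[j];
    for (size_t k = 0; k < ri.size(); ++k) {
      double xi = x[ri[k]];
      for (int m = 0; m < rm[k]; ++m) a *= (xi - m);
    }
    return a > 0.0 ? a : 0.0;
  }

  void propensities(const std::vector<double>& x, std::vector<double>& a,
                    double& a0) const {
    a0 = 0.0;
    for (int j = 0; j < nr; ++j) { a[j] = propensity(j, x); a0 += a[j]; }
  }

  inline void apply(int j, std::vector<double>& x) const {
    const std::vector<int>& si = st_idx[j];
    const std::vector<int>& sv = st_val[j];
    for (size_t k = 0; k < si.size(); ++k) x[si[k]] += sv[k];
  }

  // species-based tau selection (bounded relative propensity change)
  double select_tau(const std::vector<double>& x,
                    const std::vector<double>& a, double eps,
                    std::vector<double>& mu, std::vector<double>& s2,
                    double tau_max) const {
    std::fill(mu.begin(), mu.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int j = 0; j < nr; ++j) {
      if (a[j] <= 0.0) continue;
      const std::vector<int>& si = st_idx[j];
      const std::vector<int>& sv = st_val[j];
      for (size_t k = 0; k < si.size(); ++k) {
        mu[si[k]] += sv[k] * a[j];
        s2[si[k]] += (double)sv[k] * sv[k] * a[j];
      }
    }
    double tau = tau_max;
    for (int i = 0; i < ns; ++i) {
      if (s2[i] <= 0.0) continue;
      double bnd = eps * x[i] / g[i];
      if (bnd < 1.0) bnd = 1.0;
      double am = std::fabs(mu[i]);
      if (am > 0.0) { double t1 = bnd / am; if (t1 < tau) tau = t1; }
      double t2 = bnd * bnd / s2[i];
      if (t2 < tau) tau = t2;
    }
    return tau;
  }

  // one exact SSA event; returns false when the horizon is reached or no
  // reaction can fire (t is then advanced to t_end)
  bool ssa_event(std::vector<double>& x, std::vector<double>& a,
                 double& t, double t_end) {
    double a0;
    propensities(x, a, a0);
    if (a0 <= 0.0) { t = t_end; return false; }
    double dt = R::exp_rand() / a0;
    if (t + dt > t_end) { t = t_end; return false; }
    t += dt;
    double u = R::unif_rand() * a0, c = 0.0;
    int j = nr - 1;
    for (int k = 0; k < nr; ++k) { c += a[k]; if (u <= c) { j = k; break; } }
    apply(j, x);
    return true;
  }

  // one tau-leap (or batch of exact fallback events); advances t
  void leap_step(std::vector<double>& x, std::vector<double>& a,
                 std::vector<double>& mu, std::vector<double>& s2,
                 std::vector<double>& kf, double& t, double t_end,
                 double eps, double ssa_factor, double& steps) {
    double a0;
    propensities(x, a, a0);
    if (a0 <= 0.0) { t = t_end; return; }
    double tau = select_tau(x, a, eps, mu, s2, t_end - t);
    if (tau < ssa_factor / a0) {
      for (int ev = 0; ev < 50; ++ev) {
        if (!ssa_event(x, a, t, t_end)) return;
        ++steps;
        if (t >= t_end) return;
      }
      return;
    }
    if (t + tau > t_end) tau = t_end - t;
    for (int attempt = 0; ; ++attempt) {
      for (int j = 0; j < nr; ++j)
        kf[j] = a[j] > 0.0 ? rpois_fast(a[j] * tau) : 0.0;
      // apply provisionally, verify nonnegativity, roll back on failure
      for (int j = 0; j < nr; ++j) {
        if (kf[j] == 0.0) continue;
        const std::vector<int>& si = st_idx[j];
        const std::vector<int>& sv = st_val[j];
        for (size_t k = 0; k < si.size(); ++k) x[si[k]] += sv[k] * kf[j];
      }
      bool neg = false;
      for (int i = 0; i < ns; ++i) if (x[i] < 0.0) { neg = true; break; }
      if (!neg) break;
      for (int j = 0; j < nr; ++j) {
        if (kf[j] == 0.0) continue;
        const std::vector<int>& si = st_idx[j];
        const std::vector<int>& sv = st_val[j];
        for (size_t k = 0; k < si.size(); ++k) x[si[k]] -= sv[k] * kf[j];
      }
      tau *= 0.5;
      if (attempt > 60) {  // degenerate: take one exact event instead
        ssa_event(x, a, t, t_end);
        ++steps;
        return;
      }
    }
    t += tau;
    ++steps;
  }
};

// [[Rcpp::export]]
NumericVector propensities_cpp(IntegerMatrix reactant_mat, NumericVector rates,
                               NumericVector state, bool stochastic) {
  const int nr = reactant_mat.ncol(), ns = reactant_mat.nrow();
  NumericVector a(nr);
  for (int j = 0; j < nr; ++j) {
    double aj = rates[j];
    for (int i = 0; i < ns; ++i) {
      int m = reactant_mat(i, j);
      if (m == 0) continue;
      if (stochastic) {
        for (int k = 0; k < m; ++k) aj *= (state[i] - k);
      } else {
        aj *= std::pow(state[i], m);
      }
    }
    a[j] = (stochastic && aj < 0.0) ? 0.0 : aj;
  }
  return a;
}

static List make_result(const std::vector<double>& times,
                        const std::vector<double>& states,
                        int ns, bool truncated, double nsteps) {
  const int nt = times.size();
  NumericMatrix M(nt, ns);
  for (int t = 0; t < nt; ++t)
    for (int i = 0; i < ns; ++i) M(t, i) = states[(size_t)t * ns + i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = M, _["truncated"] = truncated,
                      _["nsteps"] = nsteps);
}

// Exact Gillespie direct method, recording at fixed intervals.
// [[Rcpp::export]]
List ssa_cpp(IntegerMatrix stoich, IntegerMatrix reactant_mat,
             NumericVector rates, IntegerVector init,
             double t_end, double record_interval, double max_steps) {
  SparseNet net(stoich, reactant_mat, rates);
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(net.nr);
  std::vector<double> times, states;
  double t = 0.0, next_rec = 0.0, steps = 0.0;
  bool truncated = false;
  RNGScope scope;
  for (;;) {
    while (next_rec <= t + 1e-12 && next_rec <= t_end + 1e-12) {
      times.push_back(next_rec);
      for (int i = 0; i < net.ns; ++i) states.push_back(x[i]);
      next_rec += record_interval;
    }
    if (t >= t_end) break;
    if (net.ssa_event(x, a, t, t_end)) {
      if (++steps >= max_steps) { truncated = true; break; }
    }
  }
  return make_result(times, states, net.ns, truncated, steps);
}

// Tau-leaping with species-based tau selection (Cao-Gillespie-Petzold),
// SSA fallback for small leaps and rejection of negative-count leaps.
// [[Rcpp::export]]
List tau_leap_cpp(IntegerMatrix stoich, IntegerMatrix reactant_mat,
                  NumericVector rates, IntegerVector init,
                  double t_end, double record_interval, double epsilon,
                  double max_steps, double ssa_factor) {
  SparseNet net(stoich, reactant_mat, rates);
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(net.nr), mu(net.ns), s2(net.ns), kf(net.nr);
  std::vector<double> times, states;
  double t = 0.0, next_rec = 0.0, steps = 0.0;
  bool truncated = false;
  RNGScope scope;
  for (;;) {
    while (next_rec <= t + 1e-9 && next_rec <= t_end + 1e-9) {
      times.push_back(next_rec);
      for (int i = 0; i < net.ns; ++i) states.push_back(x[i]);
      next_rec += record_interval;
    }
    if (t >= t_end) break;
    // never leap across a recording point
    double t_stop = next_rec < t_end ? next_rec : t_end;
    net.leap_step(x, a, mu, s2, kf, t, t_stop, epsilon, ssa_factor, steps);
    if (steps >= max_steps) { truncated = true; break; }
  }
  return make_result(times, states, net.ns, truncated, steps);
}

// First-passage sampler: tau-leap simulation with an online linear basin
// classifier h = dot(w, x) - b evaluated every check_interval; reports the
// first time h changes sign and stays flipped for >= dwell.
// [[Rcpp::export]]
List first_passage_cpp(IntegerMatrix stoich, IntegerMatrix reactant_mat,
                       NumericVector rates, IntegerVector init,
                       double t_end, double check_interval, double epsilon,
                       double max_steps, double ssa_factor,
                       NumericVector w, double b, double dwell) {
  SparseNet net(stoich, reactant_mat, rates);
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(net.nr), mu(net.ns), s2(net.ns), kf(net.nr);
  std::vector<double> wv(w.begin(), w.end());
  double h0 = -b;
  for (int i = 0; i < net.ns; ++i) h0 += wv[i] * x[i];
  const bool start_side = h0 >= 0.0;
  double t = 0.0, steps = 0.0, next_check = check_interval;
  double flip_time = -1.0;
  bool truncated = false;
  RNGScope scope;
  while (t < t_end) {
    double t_stop = next_check < t_end ? next_check : t_end;
    net.leap_step(x, a, mu, s2, kf, t, t_stop, epsilon, ssa_factor, steps);
    if (t >= next_check - 1e-9) {
      double h = -b;
      for (int i = 0; i < net.ns; ++i) h += wv[i] * x[i];
      bool side = h >= 0.0;
      if (side != start_side) {
        if (flip_time < 0.0) flip_time = t;
        else if (t - flip_time >= dwell)
          return List::create(_["first_passage"] = flip_time,
                              _["transitioned"] = true,
                              _["truncated"] = false, _["nsteps"] = steps);
      } else {
        flip_time = -1.0;
      }
      next_check = t + check_interval;
    }
    if (steps >= max_steps) { truncated = true; break; }
  }
  return List::create(_["first_passage"] = NA_REAL,
                      _["transitioned"] = false,
                      _["truncated"] = truncated, _["nsteps"] = steps);
}

// Endpoint sampler for the landscape module: run short tau-leap simulations
// from each supplied initial state and return the final state of each.
// [[Rcpp::export]]
NumericMatrix endpoints_cpp(IntegerMatrix stoich, IntegerMatrix reactant_mat,
                            NumericVector rates, IntegerMatrix inits,
                            double t_end, double epsilon, double max_steps,
                            double ssa_factor) {
  SparseNet net(stoich, reactant_mat, rates);
  const int nsim = inits.nrow();
  NumericMatrix out(nsim, net.ns);
  std::vector<double> a(net.nr), mu(net.ns), s2(net.ns), kf(net.nr);
  RNGScope scope;
  for (int s = 0; s < nsim; ++s) {
    std::vector<double> x(net.ns);
    for (int i = 0; i < net.ns; ++i) x[i] = inits(s, i);
    double t = 0.0, steps = 0.0;
    while (t < t_end && steps < max_steps) {
      net.leap_step(x, a, mu, s2, kf, t, t_end, epsilon, ssa_factor, steps);
      double a0 = 0.0;
      for (int j = 0; j < net.nr; ++j) a0 += a[j];
      if (a0 <= 0.0) break;
    }
    for (int i = 0; i < net.ns; ++i) out(s, i) = x[i];
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
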