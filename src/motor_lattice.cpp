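#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Mean-field rate equations for the minus-end-loading exclusion process.
// Sites are numbered 1..N from the minus end. Site 1 receives both the
// dedicated loading rate r_in and the lattice landing rate a (= k_on * c_free);
// k_off acts on sites 1..N-1; the plus-end site N detaches only at k_out.
static void mf_residual(const std::vector<double> &rho,
                        double r_in, double a, double k_off,
                        double k_step, double k_out,
                        std::vector<double> &F) {
  const int n = rho.size();
  if (n == 1) {
    F[0] = (r_in + a) * (1.0 - rho[0]) - k_out * rho[0];
    return;
  }
  F[0] = (r_in + a) * (1.0 - rho[0]) - k_off * rho[0]
         - k_step * rho[0] * (1.0 - rho[1]);
  for (int i = 1; i < n - 1; ++i) {
    F[i] = a * (1.0 - rho[i]) + k_step * rho[i - 1] * (1.0 - rho[i])
           - k_off * rho[i] - k_step * rho[i] * (1.0 - rho[i + 1]);
  }
  F[n - 1] = a * (1.0 - rho[n - 1]) + k_step * rho[n - 2] * (1.0 - rho[n - 1])
             - k_out * rho[n - 1];
}

static double max_abs(const std::vector<double> &x) {
  double m = 0.0;
  for (double v : x) m = std::max(m, std::fabs(v));
  return m;
}

// Damped (pseudo-transient) Newton step: solve (I/dt - J) * delta = F with
// the Thomas algorithm; rho + delta is the implicit-Euler update of
// d rho / dt = F, which approaches the pure Newton step as dt -> Inf.
// Returns false on a (near-)singular pivot.
static bool mf_ptc_delta(const std::vector<double> &rho,
                         const std::vector<double> &F, double inv_dt,
                         double r_in, double a, double k_off,
                         double k_step, double k_out,
                         std::vector<double> &delta) {
  const int n = rho.size();
  std::vector<double> lo(n, 0.0), di(n, 0.0), up(n, 0.0);
  if (n == 1) {
    di[0] = -(r_in + a) - k_out;
  } else {
    di[0] = -(r_in + a) - k_off - k_step * (1.0 - rho[1]);
    up[0] = k_step * rho[0];
    for (int i = 1; i < n - 1; ++i) {
      lo[i] = k_step * (1.0 - rho[i]);
      di[i] = -a - k_step * rho[i - 1] - k_off - k_step * (1.0 - rho[i + 1]);
      up[i] = k_step * rho[i];
    }
    lo[n - 1] = k_step * (1.0 - rho[n - 1]);
    di[n - 1] = -a - k_step * rho[n - 2] - k_out;
  }
  // system matrix I/dt - J (J is the tridiagonal above, entries negated)
  for (int i = 0; i < n; ++i) { di[i] = inv_dt - di[i]; }
  std::vector<double> cp(n), dp(n);
  double piv = di[0];
  if (std::fabs(piv) < 1e-300) return false;
  cp[0] = -up[0] / piv;
  dp[0] = F[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = di[i] - (-lo[i]) * cp[i - 1];
    if (std::fabs(piv) < 1e-300) return false;
    cp[i] = -up[i] / piv;
    dp[i] = (F[i] - (-lo[i]) * dp[i - 1]) / piv;
  }
  delta[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) delta[i] = dp[i] - cp[i] * delta[i + 1];
  return true;
}

// Solve the mean-field fixed point at a fixed free concentration.
// Pseudo-transient continuation from a uniform low-density guess (or a
// warm start): implicit-Euler steps on d rho/dt = F with a growing
// pseudo-timestep, giving relaxation-like global behavior and quadratic
// Newton convergence near the fixed point.
static bool mf_solve_fixed(int n, double r_in, double a, double k_off,
                           double k_step, double k_out, double tol,
                           std::vector<double> &rho, bool warm) {
  rho.resize(n);
  if (r_in <= 0.0 && a <= 0.0) {           // no entry pathway: empty lattice
    std::fill(rho.begin(), rho.end(), 0.0);
    return true;
  }
  if (k_step <= 0.0) {                     // immobile motors: Langmuir balance
    for (int i = 0; i < n; ++i) {
      double gain = a, loss = k_off;
      if (i == 0) gain = r_in + a;
      if (i == n - 1) loss = k_out;
      if (n == 1) { gain = r_in + a; loss = k_out; }
      rho[i] = (gain + loss > 0.0) ? gain / (gain + loss) : 0.0;
    }
    return true;
  }
  if (!warm) std::fill(rho.begin(), rho.end(), 0.1);
  std::vector<double> F(n), delta(n), cand(n), Fc(n);
  double scale = r_in + a + k_off + k_step + k_out;
  // a warm start is near the fixed point: begin in the Newton regime
  double dt = (warm ? 1e6 : 1.0) / scale;
  mf_residual(rho, r_in, a, k_off, k_step, k_out, F);
  double res = max_abs(F);
  for (int iter = 0; iter < 5000; ++iter) {
    if (res <= tol) return true;
    if (!mf_ptc_delta(rho, F, 1.0 / dt, r_in, a, k_off, k_step, k_out,
                      delta))
      return false;
    for (int i = 0; i < n; ++i) {
      double v = rho[i] + delta[i];
      cand[i] = std::min(1.0, std::max(0.0, v));
    }
    mf_residual(cand, r_in, a, k_off, k_step, k_out, Fc);
    double res_new = max_abs(Fc);
    // residual fronts move through the lattice, so the max-norm need not
    // fall monotonically: accept any step that does not blow up
    if (res_new <= 3.0 * res || dt <= 1e-9 / scale) {
      rho = cand; F = Fc; res = res_new;
      dt = std::min(dt * 2.0, 1e14);
    } else {
      dt *= 0.25;
    }
  }
  return res <= tol;
}

// [[Rcpp::export(name = ".mf_solve_cpp")]]
List mf_solve_cpp(int n_sites, double k_in, double k_on, double k_off,
                  double k_step, double k_out, double c_total,
                  double copies_per_nM, int n_filaments, bool closed,
                  double tol,
                  Nullable<NumericVector> warm_rho = R_NilValue,
                  double warm_c = -1.0) {
  std::vector<double> rho;
  bool ok = false;
  double c_free = c_total;
  bool have_warm = false;
  if (warm_rho.isNotNull()) {
    NumericVector w(warm_rho);
    if (w.size() == n_sites) {
      rho.assign(w.begin(), w.end());
      have_warm = true;
    }
  }
  if (!closed) {
    ok = mf_solve_fixed(n_sites, k_in * c_free, k_on * c_free, k_off,
                        k_step, k_out, tol, rho, have_warm);
  } else {
    // conservation fixed point on the free concentration,
    // c <- c_total - n_filaments * sum(rho(c)) / copies_per_nM,
    // damped on oscillation, with a bisection fallback on the monotone
    // excess g(c) = c + n_filaments * sum(rho(c)) / copies_per_nM - c_total
    double c = c_total, lo = 0.0, hi = c_total;
    bool warm = have_warm, done = false;
    double damp = 1.0;
    if (have_warm && warm_c > 0.0 && warm_c <= c_total) c = warm_c;
    for (int it = 0; it < 200; ++it) {
      ok = mf_solve_fixed(n_sites, k_in * c, k_on * c, k_off,
                          k_step, k_out, tol, rho, warm);
      if (!ok) break;
      warm = true;
      double bound = 0.0;
      for (double v : rho) bound += v;
      double g = c + n_filaments * bound / copies_per_nM - c_total;
      if (g > 0.0) hi = c; else lo = std::max(lo, c);
      if (std::fabs(g) < 1e-11 * std::max(1.0, c_total)) {
        c_free = c; done = true; break;
      }
      double c_next = c - damp * g;
      if (c_next <= lo || c_next >= hi) {     // fall back to bisection step
        c_next = 0.5 * (lo + hi);
        damp *= 0.5;
      }
      c = c_next;
      c_free = c;
    }
    if (ok && !done) {
      ok = mf_solve_fixed(n_sites, k_in * c_free, k_on * c_free, k_off,
                          k_step, k_out, tol, rho, true);
    }
  }
  NumericVector occ(rho.begin(), rho.end());
  double flux = (n_sites >= 1 && ok) ? k_out * rho[n_sites - 1] : NA_REAL;
  return List::create(_["occupancy"] = occ, _["converged"] = ok,
                      _["c_free"] = c_free, _["flux"] = flux);
}

// Exact stochastic simulation of the lattice model, optionally with a
// growing plus end (Poisson site addition at growth_rate) and a closed
// finite reservoir holding an integer number of motor copies.
// Event codes: 1 minus-end entry, 2 lattice landing, 3 lattice detachment,
// 4 forward step, 5 plus-end exit, 6 lattice growth.
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(int n_init, double k_in, double k_on, double k_off,
                   double k_step, double k_out, double c_total,
                   double copies_per_nM, bool closed, double growth_rate,
                   double duration, double max_events) {
  std::vector<int> occ(n_init, 0);
  int n = n_init;
  long total_copies = closed ? (long)std::floor(c_total * copies_per_nM + 0.5)
                             : 0L;
  long free_copies = total_copies;
  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_site, ev_n;
  double t = 0.0;
  bool quiescent = false;
  RNGScope scope;

  while (true) {
    if (ev_t.size() >= (size_t)max_events)
      stop("gillespie: event budget exceeded (%d events)", (int)max_events);
    double c_free = closed ? (double)free_copies / copies_per_nM : c_total;
    double a = k_on * c_free;
    double r_in = k_in * c_free;
    // category propensities
    double A_entry = occ[0] ? 0.0 : (r_in + a);
    double A_land = 0.0;
    int n_free_tail = 0;
    for (int i = 1; i < n; ++i) if (!occ[i]) ++n_free_tail;
    A_land = a * n_free_tail;
    int n_occ_body = 0;                      // sites 1..N-1 (k_off applies)
    for (int i = 0; i < n - 1; ++i) if (occ[i]) ++n_occ_body;
    double A_off = k_off * n_occ_body;
    int n_steppable = 0;
    for (int i = 0; i < n - 1; ++i) if (occ[i] && !occ[i + 1]) ++n_steppable;
    double A_step = k_step * n_steppable;
    double A_exit = occ[n - 1] ? k_out : 0.0;
    double A_grow = growth_rate;
    double A = A_entry + A_land + A_off + A_step + A_exit + A_grow;
    if (A <= 0.0) { quiescent = true; break; }
    t += R::rexp(1.0 / A);
    if (t > duration) break;
    double u = R::unif_rand() * A;
    int type = 0, site = 0;
    if (u < A_entry) {
      type = 1; site = 1; occ[0] = 1; if (closed) --free_copies;
    } else if (u < A_entry + A_land) {
      int k = (int)std::floor((u - A_entry) / (k_on * c_free));
      if (k >= n_free_tail) k = n_free_tail - 1;
      int seen = -1, idx = -1;
      for (int i = 1; i < n; ++i) {
        if (!occ[i]) { ++seen; if (seen == k) { idx = i; break; } }
      }
      type = 2; site = idx + 1; occ[idx] = 1; if (closed) --free_copies;
    } else if (u < A_entry + A_land + A_off) {
      int k = (int)std::floor((u - A_entry - A_land) / k_off);
      if (k >= n_occ_body) k = n_occ_body - 1;
      int seen = -1, idx = -1;
      for (int i = 0; i < n - 1; ++i) {
        if (occ[i]) { ++seen; if (seen == k) { idx = i; break; } }
      }
      type = 3; site = idx + 1; occ[idx] = 0; if (closed) ++free_copies;
    } else if (u < A_entry + A_land + A_off + A_step) {
      int k = (int)std::floor((u - A_entry - A_land - A_off) / k_step);
      if (k >= n_steppable) k = n_steppable - 1;
      int seen = -1, idx = -1;
      for (int i = 0; i < n - 1; ++i) {
        if (occ[i] && !occ[i + 1]) { ++seen; if (seen == k) { idx = i; break; } }
      }
      type = 4; site = idx + 1; occ[idx] = 0; occ[idx + 1] = 1;
    } else if (u < A_entry + A_land + A_off + A_step + A_exit) {
      type = 5; site = n; occ[n - 1] = 0; if (closed) ++free_copies;
    } else {
      type = 6; site = n + 1; occ.push_back(0); ++n;
    }
    ev_t.push_back(t);
    ev_type.push_back(type);
    ev_site.push_back(site);
    ev_n.push_back(n);
  }
  IntegerVector fin(occ.begin(), occ.end());
  return List::create(
      _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["type"] = IntegerVector(ev_type.begin(), ev_type.end()),
      _["site"] = IntegerVector(ev_site.begin(), ev_site.end()),
      _["n_sites"] = IntegerVector(ev_n.begin(), ev_n.end()),
      _["final_state"] = fin, _["n_final"] = n,
      _["quiescent"] = quiescent, _["free_copies"] = (double)free_copies,
      _["total_copies"] = (double)total_copies);
}

// Replay an event list and accumulate per-site occupancy time after burn_in.
// [[Rcpp::export(name = ".time_average_cpp")]]
NumericVector time_average_cpp(NumericVector time, IntegerVector type,
                               IntegerVector site, int n_init,
                               double duration, double burn_in) {
  int n_final = n_init;
  for (int e = 0; e < type.size(); ++e) if (type[e] == 6) ++n_final;
  std::vector<double> tocc(n_final, 0.0);
  std::vector<int> occ(n_final, 0);
  int n = n_init;
  double prev = 0.0;
  auto accumulate = [&](double upto) {
    double lo = std::max(prev, burn_in), hi = std::min(upto, duration);
    if (hi > lo) for (int i = 0; i < n; ++i) if (occ[i]) tocc[i] += hi - lo;
  };
  for (int e = 0; e < time.size(); ++e) {
    accumulate(time[e]);
    int s = site[e] - 1;
    switch (type[e]) {
      case 1: occ[0] = 1; break;
      case 2: occ[s] = 1; break;
      case 3: occ[s] = 0; break;
      case 4: occ[s] = 0; occ[s + 1] = 1; break;
      case 5: occ[s] = 0; break;
      case 6: ++n; break;
    }
    prev = time[e];
  }
  accumulate(duration);
  double window = duration - burn_in;
  NumericVector out(n_final);
  for (int i = 0; i < n_final; ++i) out[i] = tocc[i] / window;
  return out;
}
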