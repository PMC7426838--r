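#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact event-driven simulation of the binary branching process with
// extinction rate eps(t) = s*(p0 - A*sin(nu*t)) by Ogata/Lewis thinning.
//
// Per-particle total event rate: lambda(t) = q2 + eps(t) = s*(1 - A*sin(nu*t)),
// bounded above by s*(1+|A|). Proposals arrive at rate N*s*(1+|A|); a proposal
// at time t is accepted with probability (1 - A*sin(nu*t))/(1+|A|) and is then
// a branching event with probability p2/(1 - A*sin(nu*t)), an extinction
// otherwise. Both factors are exact, so accepted events follow the exact law.
//
// Uses R's RNG stream (unif_rand/exp_rand): set.seed() on the R side gives
// bitwise-reproducible trajectories.

struct SimState {
  std::vector<double> times;
  std::vector<int> kinds;    // 1 = branch, 0 = extinct
  std::vector<int> n_after;
  bool censored;
  bool exploded;
};

static void simulate_one(double s, double p2, double A, double nu,
                         double t0, int n0, double horizon, int max_pop,
                         SimState &st) {
  st.times.clear(); st.kinds.clear(); st.n_after.clear();
  st.censored = false; st.exploded = false;
  const double absA = std::fabs(A);
  const double bound = s * (1.0 + absA);
  double t = t0;
  int n = n0;
  while (n > 0) {
    double w = exp_rand() / (bound * n);
    t += w;
    if (t >= horizon) { st.censored = true; break; }
    double mod = 1.0 - A * std::sin(nu * t); // lambda(t)/s at proposal time
    if (unif_rand() * (1.0 + absA) >= mod) continue; // thinned out
    bool branch = (unif_rand() * mod < p2);
    n += branch ? 1 : -1;
    if (n > max_pop) { st.exploded = true; break; }
    st.times.push_back(t);
    st.kinds.push_back(branch ? 1 : 0);
    st.n_after.push_back(n);
  }
}

// [[Rcpp::export]]
List cpp_simulate_log(double s, double p2, double A, double nu,
                      double t0, int n0, double horizon, int max_pop) {
  SimState st;
  simulate_one(s, p2, A, nu, t0, n0, horizon, max_pop, st);
  if (st.exploded)
    stop("population exploded beyond max_pop = %d; raise `max_pop` or check "
         "parameters (r < 0 is supercritical)", max_pop);
  return List::create(
    _["time"] = NumericVector(st.times.begin(), st.times.end()),
    _["kind"] = IntegerVector(st.kinds.begin(), st.kinds.end()),
    _["n_after"] = IntegerVector(st.n_after.begin(), st.n_after.end()),
    _["censored"] = st.censored);
}

// Evaluation of N(t) at sorted query times from the event log of one
// realisation; right-continuous by default, or left limits N(t-) when
// left_limit is set (used for shape profiles so that tau = 1 sees the last
// particle rather than the post-death value 0).
static void eval_step(const std::vector<double> &times,
                      const std::vector<int> &n_after, int n0,
                      const double *q, int nq, double *out,
                      bool left_limit = false) {
  int j = 0, m = (int)times.size();
  int cur = n0;
  for (int i = 0; i < nq; ++i) {
    if (left_limit) {
      while (j < m && times[j] < q[i]) { cur = n_after[j]; ++j; }
    } else {
      while (j < m && times[j] <= q[i]) { cur = n_after[j]; ++j; }
    }
    out[i] = cur;
  }
}

// One-pass ensemble: per-avalanche records, grid moments/survival, and
// optional collection of profiles for avalanches terminating near shape_T.
// [[Rcpp::export]]
List cpp_run_ensemble(double s, double p2, double A, double nu,
                      double t0, int n0, double horizon, int n_runs,
                      NumericVector grid, int max_pop,
                      double shape_T, double shape_window,
                      NumericVector tau_grid) {
  const bool collect_shape = R_finite(shape_T) && shape_T > 0;
  const int G = grid.size(), K = tau_grid.size();
  NumericVector Tout(n_runs), Sout(n_runs), peak(n_runs);
  LogicalVector cens(n_runs);
  std::vector<double> sumN(G, 0.0), sumN2(G, 0.0), sumN4(G, 0.0);
  std::vector<double> nsurv(G, 0.0);
  std::vector<double> shape_rows;  // row-major K columns
  std::vector<double> shape_Ts;
  std::vector<double> prof(K);
  SimState st;
  for (int run = 0; run < n_runs; ++run) {
    simulate_one(s, p2, A, nu, t0, n0, horizon, max_pop, st);
    if (st.exploded)
      stop("population exploded beyond max_pop = %d at run %d", max_pop,
           run + 1);
    int branches = 0, pk = n0;
    for (size_t i = 0; i < st.kinds.size(); ++i) {
      branches += st.kinds[i];
      if (st.n_after[i] > pk) pk = st.n_after[i];
    }
    double T = st.censored ? NA_REAL : st.times.back() - t0;
    Tout[run] = T;
    Sout[run] = n0 + branches;
    peak[run] = pk;
    cens[run] = st.censored;
    if (G > 0) {
      // grid is absolute time, sorted
      int j = 0, m = (int)st.times.size(), cur = n0;
      for (int i = 0; i < G; ++i) {
        while (j < m && st.times[j] <= grid[i]) { cur = st.n_after[j]; ++j; }
        double v = cur;
        sumN[i] += v; sumN2[i] += v * v; sumN4[i] += v * v * v * v;
        if (v > 0) nsurv[i] += 1.0;
      }
    }
    if (collect_shape && !st.censored &&
        std::fabs(T - shape_T) <= shape_window) {
      std::vector<double> q(K);
      for (int k = 0; k < K; ++k) q[k] = t0 + tau_grid[k] * T;
      eval_step(st.times, st.n_after, n0, q.data(), K, prof.data(), true);
      shape_rows.insert(shape_rows.end(), prof.begin(), prof.end());
      shape_Ts.push_back(T);
    }
    if ((run & 0x3FF) == 0) checkUserInterrupt();
  }
  List out = List::create(
    _["T"] = Tout, _["S"] = Sout, _["peak"] = peak, _["censored"] = cens,
    _["sumN"] = NumericVector(sumN.begin(), sumN.end()),
    _["sumN2"] = NumericVector(sumN2.begin(), sumN2.end()),
    _["sumN4"] = NumericVector(sumN4.begin(), sumN4.end()),
    _["nsurv"] = NumericVector(nsurv.begin(), nsurv.end()));
  if (collect_shape) {
    int nq = (int)shape_Ts.size();
    NumericMatrix M(nq, K);
    for (int i = 0; i < nq; ++i)
      for (int k = 0; k < K; ++k) M(i, k) = shape_rows[(size_t)i * K + k];
    out["shape_profiles"] = M;
    out["shape_T_obs"] = NumericVector(shape_Ts.begin(), shape_Ts.end());
  }
  return out;
}
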