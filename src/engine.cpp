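#include <Rcpp.h>
#include <cstdint>
#include <random>
using namespace Rcpp;

// parameter vector layout; must match params_to_vec() on the R side
enum Par { K0 = 0, B1, B2, B3, B4, B5, LAM, ZN, ZS, KILL, DPIRK, CCACT,
           TOPO, FORM, NPAR };

// species indices (canonical order B, R, N, P, S, A)
enum Sp { iB = 0, iR, iN, iP, iS, iA };

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// 53-bit uniform in [0, 1); avoids std::uniform_real_distribution so the
// stream is identical across standard-library implementations
static inline double runif53(std::mt19937_64 &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

static inline std::mt19937_64 child_rng(double base_seed, int replicate) {
  uint64_t base = (uint64_t)base_seed;
  uint64_t s = splitmix64(base ^ splitmix64((uint64_t)(replicate + 1)));
  return std::mt19937_64(s);
}

// FORM: 0 = competitive (default), 1 = occupancy, 2 = leaky; matches
// params_to_vec() on the R side
static inline double amp_rate(const double *s, const double *p) {
  double N = s[iN], S = s[iS];
  if (p[TOPO] > 0.5) return p[B5] * N / p[ZN];      // Toll: no promoter competition
  double x = N / p[ZN], y = S / p[ZS];
  if (p[FORM] > 1.5) return p[B5] * x / (1.0 + x + y);
  if (p[FORM] > 0.5) return (x + y > 1e-9) ? p[B5] * x / (x + y) : 0.0;
  return (x + y > 1e-9) ? p[B5] * x * x / (x + y) : 0.0;
}

// immune channel order mirrors build_network(); Toll appends Cactus removal
static inline int immune_propensities(const double *s, const double *p,
                                      double *a) {
  a[0] = p[B1] * s[iN];               // R + 1
  a[1] = p[B2] * s[iR] * s[iB];       // N + 1
  a[2] = p[B3] * s[iN];               // P + 1
  a[3] = p[B4] * s[iN];               // S + 1
  a[4] = amp_rate(s, p);              // A + 1
  a[5] = p[DPIRK] * s[iP] * s[iR];    // R - 1
  a[6] = p[LAM] * s[iR];              // R - 1
  a[7] = p[LAM] * s[iN];              // N - 1
  a[8] = p[LAM] * s[iP];              // P - 1
  a[9] = p[LAM] * s[iS];              // S - 1
  a[10] = p[LAM] * s[iA];             // A - 1
  if (p[TOPO] > 0.5) {
    a[11] = p[CCACT] * s[iS] * s[iN]; // N - 1
    return 12;
  }
  return 11;
}

static const int IMM_SPECIES[12] = {iR, iN, iP, iS, iA, iR, iR, iN, iP, iS,
                                    iA, iN};
static const int IMM_SIGN[12] = {+1, +1, +1, +1, +1, -1, -1, -1, -1, -1,
                                 -1, -1};

static inline int pick(const double *a, int n, double tot,
                       std::mt19937_64 &g) {
  double u = runif53(g) * tot;
  double c = 0.0;
  for (int j = 0; j < n; ++j) {
    c += a[j];
    if (u < c) return j;
  }
  return n - 1; // guard against rounding at the upper edge
}

// advance one discrete step: at most one bacterial and one immune reaction,
// both selected from propensities evaluated at the step's starting state and
// applied jointly; bacterial draw consumes RNG first
static inline void one_step(double *s, const double *p, std::mt19937_64 &g) {
  double ab[2];
  ab[0] = p[K0] * s[iB];
  ab[1] = p[KILL] * s[iA] * s[iB];
  double ai[12];
  int ni = immune_propensities(s, p, ai);
  double totb = ab[0] + ab[1];
  double toti = 0.0;
  for (int j = 0; j < ni; ++j) toti += ai[j];
  int jb = (totb > 0.0) ? pick(ab, 2, totb, g) : -1;
  int ji = (toti > 0.0) ? pick(ai, ni, toti, g) : -1;
  if (jb >= 0) s[iB] += (jb == 0) ? 1.0 : -1.0;
  if (ji >= 0) s[IMM_SPECIES[ji]] += IMM_SIGN[ji];
}

static void run_one(const double *p, int T, const LogicalVector &is_event,
                    int inoculum, const double *init, std::mt19937_64 &g,
                    double *traj /* (T+1) x 6, column-major rows=time */,
                    int ld) {
  double s[6];
  for (int k = 0; k < 6; ++k) s[k] = init[k];
  for (int t = 0; t < T; ++t) {
    if (is_event[t]) s[iB] += inoculum;
    for (int k = 0; k < 6; ++k) traj[t + (R_xlen_t)k * ld] = s[k];
    one_step(s, p, g);
  }
  for (int k = 0; k < 6; ++k) traj[T + (R_xlen_t)k * ld] = s[k];
}

// [[Rcpp::export]]
NumericMatrix sim_trajectory_cpp(NumericVector p, int T,
                                 IntegerVector event_times, int inoculum,
                                 NumericVector init, double seed) {
  LogicalVector is_event(T, false);
  for (int i = 0; i < event_times.size(); ++i) {
    int t = event_times[i];
    if (t >= 0 && t < T) is_event[t] = true;
  }
  NumericMatrix traj(T + 1, 6);
  std::mt19937_64 g(splitmix64((uint64_t)seed));
  run_one(REAL(p), T, is_event, inoculum, REAL(init), g, REAL(traj), T + 1);
  return traj;
}

// [[Rcpp::export]]
List sim_ensemble_cpp(NumericVector p, int T, IntegerVector event_times,
                      int inoculum, NumericVector init, int n_reps,
                      double base_seed, int rep_offset, bool keep_bacteria) {
  LogicalVector is_event(T, false);
  for (int i = 0; i < event_times.size(); ++i) {
    int t = event_times[i];
    if (t >= 0 && t < T) is_event[t] = true;
  }
  NumericMatrix amp(n_reps, T + 1);
  NumericMatrix bac(keep_bacteria ? n_reps : 0, keep_bacteria ? (T + 1) : 0);
  std::vector<double> traj((T + 1) * 6);
  for (int r = 0; r < n_reps; ++r) {
    std::mt19937_64 g = child_rng(base_seed, rep_offset + r);
    run_one(REAL(p), T, is_event, inoculum, REAL(init), g, traj.data(), T + 1);
    for (int t = 0; t <= T; ++t) {
      amp(r, t) = traj[t + (R_xlen_t)iA * (T + 1)];
      if (keep_bacteria) bac(r, t) = traj[t + (R_xlen_t)iB * (T + 1)];
    }
  }
  if (keep_bacteria) return List::create(_["amp"] = amp, _["bacteria"] = bac);
  return List::create(_["amp"] = amp, _["bacteria"] = R_NilValue);
}

// repeated independent single-step draws from one frozen state; returns how
// often each channel fired in each set (used for goodness-of-fit checks)
// [[Rcpp::export]]
List step_counts_cpp(NumericVector p, NumericVector state, int n_draws,
                     double seed) {
  std::mt19937_64 g(splitmix64((uint64_t)seed));
  double ab[2];
  double ai[12];
  const double *s = REAL(state);
  const double *pp = REAL(p);
  ab[0] = pp[K0] * s[iB];
  ab[1] = pp[KILL] * s[iA] * s[iB];
  int ni = immune_propensities(s, pp, ai);
  double totb = ab[0] + ab[1];
  double toti = 0.0;
  for (int j = 0; j < ni; ++j) toti += ai[j];
  IntegerVector cb(2), ci(ni);
  for (int d = 0; d < n_draws; ++d) {
    if (totb > 0.0) cb[pick(ab, 2, totb, g)]++;
    if (toti > 0.0) ci[pick(ai, ni, toti, g)]++;
  }
  return List::create(_["bacterial"] = cb, _["immune"] = ci);
}

// [[Rcpp::export]]
List propensities_cpp(NumericVector p, NumericVector state) {
  double ab[2];
  double ai[12];
  const double *s = REAL(state);
  const double *pp = REAL(p);
  ab[0] = pp[K0] * s[iB];
  ab[1] = pp[KILL] * s[iA] * s[iB];
  int ni = immune_propensities(s, pp, ai);
  return List::create(_["bacterial"] = NumericVector(ab, ab + 2),
                      _["immune"] = NumericVector(ai, ai + ni));
}
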