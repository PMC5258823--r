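#include <Rcpp.h>
#include <cstdint>
#include <random>
using namespace Rcpp;

// SplitMix64: mixes (root seed, trajectory index) into an independent
// 64-bit stream seed, so replicate counts can grow without reshuffling
// earlier trajectories.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in (0,1): 53-bit mantissa, offset so 0 is excluded
static inline double runif01(std::mt19937_64 &rng) {
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double rexp1(std::mt19937_64 &rng, double rate) {
  return -std::log(runif01(rng)) / rate;
}

// One Gillespie path of the clonotype birth-death chain from size i0 until
// extinction (or a cap). lambda[i] is the birth rate at size i (index i);
// death rate is mu * i. Per-path summaries are accumulated in place.
struct PathSummary {
  double xmax, tmax, t_ext, t_reach, t_div;
  double nmax, births, events, n_at_reach;
  bool censored, reached;
};

static PathSummary run_path(const NumericVector &lambda, double mu, int i0,
                            std::mt19937_64 &rng, int irho_target,
                            double d_target, double max_time,
                            double max_events) {
  const int cap = lambda.size() - 1;
  PathSummary s;
  s.xmax = i0; s.tmax = 0.0; s.nmax = 0.0; s.births = 0.0; s.events = 0.0;
  s.t_ext = NA_REAL; s.t_reach = NA_REAL; s.t_div = NA_REAL;
  s.n_at_reach = NA_REAL;
  s.censored = false; s.reached = (i0 == irho_target);
  if (s.reached) { s.t_reach = 0.0; s.n_at_reach = 0.0; }

  int i = i0;
  double t = 0.0;
  while (i > 0) {
    double lam = lambda[i], dth = mu * i, tot = lam + dth;
    t += rexp1(rng, tot);
    if (t > max_time || s.events >= max_events) { s.censored = true; break; }
    s.events += 1.0;
    if (runif01(rng) * tot < lam) {
      ++i;
      s.births += 1.0;
      if (s.births == d_target && !(s.t_div == s.t_div)) s.t_div = t;
      if (i > s.xmax) { s.xmax = i; s.tmax = t; s.nmax = s.births; }
      if (i >= cap) { s.censored = true; break; }
    } else {
      --i;
    }
    // first passage works for expansion and contraction targets alike
    if (irho_target > 0 && i == irho_target && !s.reached) {
      s.reached = true; s.t_reach = t; s.n_at_reach = s.births;
    }
  }
  if (i == 0) s.t_ext = t;
  return s;
}

// [[Rcpp::export]]
DataFrame simulate_paths_cpp(NumericVector lambda, double mu, int i0,
                             int n_reps, double seed, int irho_target,
                             double d_target, double max_time,
                             double max_events) {
  NumericVector xmax(n_reps), tmax(n_reps), nmax(n_reps), births(n_reps),
      events(n_reps), t_ext(n_reps), t_reach(n_reps), t_div(n_reps),
      n_at_reach(n_reps);
  LogicalVector censored(n_reps);
  uint64_t root = static_cast<uint64_t>(seed);
  for (int r = 0; r < n_reps; ++r) {
    std::mt19937_64 rng(splitmix64(root ^ splitmix64(r + 1)));
    PathSummary s = run_path(lambda, mu, i0, rng, irho_target, d_target,
                             max_time, max_events);
    xmax[r] = s.xmax; tmax[r] = s.tmax; nmax[r] = s.nmax;
    births[r] = s.births; events[r] = s.events; t_ext[r] = s.t_ext;
    t_reach[r] = s.t_reach; t_div[r] = s.t_div;
    n_at_reach[r] = s.n_at_reach; censored[r] = s.censored;
  }
  return DataFrame::create(
      _["xmax"] = xmax, _["tmax"] = tmax, _["nmax"] = nmax,
      _["births"] = births, _["events"] = events, _["t_extinction"] = t_ext,
      _["t_reach"] = t_reach, _["t_divisions"] = t_div,
      _["n_at_reach"] = n_at_reach, _["censored"] = censored);
}

// [[Rcpp::export]]
List simulate_events_cpp(NumericVector lambda, double mu, int i0,
                         double seed, double max_time, double max_events) {
  const int cap = lambda.size() - 1;
  std::mt19937_64 rng(splitmix64(static_cast<uint64_t>(seed) ^
                                 splitmix64(1)));
  std::vector<double> times;
  std::vector<int> sizes, types; // type: +1 birth, -1 death
  int i = i0;
  double t = 0.0;
  bool cens = false;
  while (i > 0) {
    double lam = lambda[i], dth = mu * i, tot = lam + dth;
    t += rexp1(rng, tot);
    if (t > max_time || times.size() >= (size_t)max_events) { cens = true; break; }
    if (runif01(rng) * tot < lam) { ++i; types.push_back(1); }
    else { --i; types.push_back(-1); }
    times.push_back(t);
    sizes.push_back(i);
    if (i >= cap) { cens = true; break; }
  }
  return List::create(_["time"] = times, _["size"] = sizes,
                      _["type"] = types, _["censored"] = cens);
}
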