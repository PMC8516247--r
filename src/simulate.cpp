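#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained RNG: splitmix64 stream + Marsaglia polar normals.
// One independent stream per (trial, rep) so that candidate evaluations in
// the fitting loop reuse identical noise (common random numbers) and results
// are bit-reproducible across platforms, independent of R's RNG state.
namespace {

inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t state;
  bool have_spare;
  double spare;
  explicit Stream(uint64_t seed) : state(seed), have_spare(false), spare(0.0) {}
  inline double unif() {  // in [0, 1)
    return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
};

inline uint64_t stream_seed(uint64_t base, int trial, int rep) {
  uint64_t s = base;
  s ^= (uint64_t)(trial + 1) * 0xA24BAED4963EE407ULL;
  s ^= (uint64_t)(rep + 1) * 0x9FB21C651E98DF25ULL;
  uint64_t st = s;
  return splitmix64(st);
}

}  // namespace

//' @name cpp_simulate_batch
//' Simulate decisions for a batch of evidence traces.
//'
//' evid: n_trials x n_points matrix of piecewise-constant evidence values,
//'   value j holding from times[j] (inclusive) to times[j+1]; evidence is 0
//'   before times[0]. model: 0 = EAM, 1 = UGM. Decisions are allowed strictly
//'   before `deadline`; otherwise the trial is censored, the choice forced
//'   from the sign of the decision variable and dt set to the deadline.
// [[Rcpp::export]]
List cpp_simulate_batch(NumericMatrix evid, NumericVector times,
                        int model, double nu, double eta, double theta,
                        double s, double dt, double tau, double deadline,
                        int n_reps, double seed) {
  const int n_trials = evid.nrow();
  const int n_pts = evid.ncol();
  const int n_steps = (int)std::floor(deadline / dt + 1e-9);
  const double dts = dt / 1000.0;        // step in seconds (EAM drift/noise unit)
  const double sq_dts = std::sqrt(dts);
  const double a = tau / (tau + dt);     // UGM low-pass coefficients
  const double b = dt / (tau + dt);
  const uint64_t base = (uint64_t)seed;

  const int total = n_trials * n_reps;
  IntegerVector out_trial(total), out_rep(total), out_choice(total),
      out_censored(total);
  NumericVector out_dt(total);

  int idx = 0;
  for (int tr = 0; tr < n_trials; ++tr) {
    for (int rep = 0; rep < n_reps; ++rep, ++idx) {
      Stream rng(stream_seed(base, tr, rep));
      const double v = nu + eta * rng.norm();  // per-trial drift draw
      double x = (model == 0) ? theta / 2.0 : 0.0;
      int j = 0;  // number of evidence points with onset <= t
      int choice = 0, censored = 0;
      double dtime = deadline;
      for (int n = 1; n < n_steps; ++n) {
        const double t = n * dt;
        while (j < n_pts && times[j] <= t + 1e-9) ++j;
        const double e = (j > 0) ? evid(tr, j - 1) : 0.0;
        if (model == 0) {
          x += v * e * dts + s * rng.norm() * sq_dts;
          if (x > theta)      { choice = 1;  dtime = t - dt / 2.0; break; }
          else if (x < 0.0)   { choice = -1; dtime = t - dt / 2.0; break; }
        } else {
          x = a * x + b * (v * e + s * rng.norm());
          const double xu = x * t;
          if (xu > theta)       { choice = 1;  dtime = t - dt / 2.0; break; }
          else if (xu < -theta) { choice = -1; dtime = t - dt / 2.0; break; }
        }
      }
      if (choice == 0) {
        censored = 1;
        const double ref = (model == 0) ? x - theta / 2.0 : x;
        if (ref > 0.0)      choice = 1;
        else if (ref < 0.0) choice = -1;
        else                choice = (rng.unif() < 0.5) ? 1 : -1;
        dtime = deadline;
      }
      out_trial[idx] = tr + 1;
      out_rep[idx] = rep + 1;
      out_choice[idx] = choice;
      out_dt[idx] = dtime;
      out_censored[idx] = censored;
    }
  }
  return List::create(_["trial"] = out_trial, _["rep"] = out_rep,
                      _["choice"] = out_choice, _["dt_ms"] = out_dt,
                      _["censored"] = out_censored);
}
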