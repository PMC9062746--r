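#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained normal deviate stream (splitmix64-seeded xoshiro256++ with
// Box-Muller). Keeps the integrator's noise path bitwise reproducible from a
// single integer seed, independent of R's RNG state.
namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 to fill the state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]
  inline double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
};

struct NormalStream {
  Xoshiro256pp rng;
  double cached;
  bool has_cached;
  explicit NormalStream(uint64_t seed) : rng(seed), cached(0.0), has_cached(false) {}
  inline double next() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }
};

} // namespace

// Stochastic Heun stepping of the coupled two-layer FitzHugh-Nagumo system.
//
//   dV_i/dt = c (V_i - V_i^3/3 - w_i) + D eta_i + K_.E V_i^E - K_.I V_i^I
//   dw_i/dt = (V_i - b w_i + a) / c
//
// Coupling sums are diffusive over the binary matrix M, given here as a
// directed edge list (from -> to, 0-based), split by presynaptic type:
//   V_i^E = sum_{j <= N_E} M_ji (V_j - V_i),  V_i^I analogous for j > N_E.
// Per step the drift is advanced by the two-stage Heun (trapezoidal)
// rule, second-order accurate in the noise-free limit, and the noise adds
// D * eta * dt to V with eta ~ N(0,1) i.i.d. per neuron and step (noise on
// V only). States are recorded every `stride` steps, including the initial
// state.
//
// [[Rcpp::export(name = ".em_integrate")]]
List em_integrate(int N, int N_E,
                  IntegerVector edge_from, IntegerVector edge_to,
                  NumericVector V0, NumericVector w0,
                  double a, double b, double c, double D,
                  double K_EE, double K_EI, double K_IE, double K_II,
                  double dt, int n_steps, int stride,
                  double seed, bool record_w) {
  const int n_edges = edge_from.size();
  std::vector<double> V(V0.begin(), V0.end()), w(w0.begin(), w0.end());
  std::vector<double> sumE(N), sumI(N);
  std::vector<double> k1V(N), k1w(N), k2V(N), k2w(N), Vp(N), wp(N);
  std::vector<double> cntE(N, 0.0), cntI(N, 0.0);
  for (int e = 0; e < n_edges; ++e) {
    if (edge_from[e] < N_E) cntE[edge_to[e]] += 1.0; else cntI[edge_to[e]] += 1.0;
  }
  const int n_rec = n_steps / stride + 1;
  NumericMatrix Vrec(N, n_rec);
  NumericMatrix wrec(record_w ? N : 1, record_w ? n_rec : 1);
  for (int i = 0; i < N; ++i) Vrec(i, 0) = V[i];
  if (record_w) for (int i = 0; i < N; ++i) wrec(i, 0) = w[i];

  NormalStream ns(static_cast<uint64_t>(seed));
  int ri = 0;
  const double inv_c = 1.0 / c;
  // drift evaluation into (outV, outw) from state (sV, sw)
  auto drift = [&](const std::vector<double>& sV, const std::vector<double>& sw,
                   std::vector<double>& outV, std::vector<double>& outw) {
    std::fill(sumE.begin(), sumE.end(), 0.0);
    std::fill(sumI.begin(), sumI.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      const int j = edge_from[e], i = edge_to[e];
      if (j < N_E) sumE[i] += sV[j]; else sumI[i] += sV[j];
    }
    for (int i = 0; i < N; ++i) {
      const double Vi = sV[i];
      const double VE = sumE[i] - cntE[i] * Vi;
      const double VI = sumI[i] - cntI[i] * Vi;
      const double kE = (i < N_E) ? K_EE : K_EI;
      const double kI = (i < N_E) ? K_IE : K_II;
      outV[i] = c * (Vi - Vi * Vi * Vi / 3.0 - sw[i]) + kE * VE - kI * VI;
      outw[i] = (Vi - b * sw[i] + a) * inv_c;
    }
  };
  for (int s = 1; s <= n_steps; ++s) {
    drift(V, w, k1V, k1w);
    for (int i = 0; i < N; ++i) {
      Vp[i] = V[i] + dt * k1V[i];
      wp[i] = w[i] + dt * k1w[i];
    }
    drift(Vp, wp, k2V, k2w);
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      V[i] += 0.5 * dt * (k1V[i] + k2V[i]) + D * dt * ns.next();
      w[i] += 0.5 * dt * (k1w[i] + k2w[i]);
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 1.0e6) bad = true;
    }
    if (bad) {
      stop("integration diverged at step %d (t = %g): non-finite or runaway "
           "state; reduce dt", s, s * dt);
    }
    if (s % stride == 0) {
      ++ri;
      for (int i = 0; i < N; ++i) Vrec(i, ri) = V[i];
      if (record_w) for (int i = 0; i < N; ++i) wrec(i, ri) = w[i];
    }
  }
  return List::create(_["V"] = Vrec,
                      _["w"] = record_w ? SEXP(wrec) : R_NilValue,
                      _["n_recorded"] = ri + 1);
}
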