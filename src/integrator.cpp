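#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64 from (seed, stream). Each
// (seed, stream) pair yields an independent, reproducible noise sequence,
// so grid cells can be simulated in any order. Standard normals come from
// the 128-layer ziggurat of Marsaglia & Tsang.
// ---------------------------------------------------------------------------

struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
const ZigTables zig;

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t x = seed;
    uint64_t a = splitmix(x);
    uint64_t b = splitmix(x);
    x ^= stream * 0xDA942042E4DD58B5ULL + 0x632BE59BD9B4E019ULL;
    s[0] = splitmix(x) ^ a;
    s[1] = splitmix(x) ^ b;
    s[2] = splitmix(x);
    s[3] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // uniform on [0, 1), 53-bit
    return (next() >> 11) * 0x1.0p-53;
  }

  double norm() {
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      const uint32_t iz = (uint32_t)hz & 127u;
      const uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < zig.kn[iz]) return hz * zig.wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double x, y;
        do {
          double u1 = unif(), u2 = unif();
          if (u1 <= 0.0) u1 = 0x1.0p-53;
          if (u2 <= 0.0) u2 = 0x1.0p-53;
          x = -std::log(u1) / r;
          y = -std::log(u2);
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      const double x = hz * zig.wn[iz];
      if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// exp with Cephes-style rational approximation (|x| clamped to 700); a few
// ulp accurate, branch-light so the per-step sigmoid loops vectorize.
// ---------------------------------------------------------------------------
inline double fast_exp(double x) {
  if (x > 700.0) x = 700.0;
  else if (x < -700.0) x = -700.0;
  const double LOG2E = 1.4426950408889634074;
  const double C1 = 6.93145751953125e-1;
  const double C2 = 1.42860682030941723212e-6;
  double px = std::floor(LOG2E * x + 0.5);
  const int k = (int)px;
  x -= px * C1;
  x -= px * C2;
  const double xx = x * x;
  px = x * (1.26177193074810590878e-4 * xx * xx +
            3.02994407707441961300e-2 * xx +
            9.99999999999999999910e-1);
  const double q = 3.00198505138664455042e-6 * xx * xx * xx +
                   2.52448340349684104192e-3 * xx * xx +
                   2.27265548208155028766e-1 * xx + 2.0;
  double res = 1.0 + 2.0 * px / (q - px);
  // scale by 2^k through the exponent bits
  union { double d; uint64_t u; } v;
  v.d = res;
  v.u += (uint64_t)((int64_t)k << 52);
  return v.d;
}

}  // namespace

// ---------------------------------------------------------------------------
// Euler-Maruyama integration of the delay-coupled stochastic Wilson-Cowan
// network. Long-range coupling links excitatory populations only, with
// per-pair delays in integration steps (>= 1). The stimulus enters the
// excitatory sigmoid argument of stim_site during [onset, offset). States
// are clipped to [0, 1] after every step (count reported). Output is plain
// decimation: every out_every-th step, keeping samples with t > discard.
//
// Delayed inputs are gathered blockwise: edges whose delay exceeds the block
// length are resolved for a whole block at once with contiguous reads from
// per-node ring buffers (power-of-two length); the few shorter-delay edges
// are resolved step by step.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List wc_integrate_cpp(NumericMatrix weights, IntegerMatrix delay_steps,
                      double tau, double cEE, double cIE, double cEI,
                      double cII, double aE, double aI, double thE,
                      double thI, double SEmax, double SImax, double cglob,
                      double sigma, double dt, double duration, int stim_site,
                      double stim_amp, double stim_onset, double stim_offset,
                      double init_value, int out_every, double discard,
                      bool record_inh, double seed, double stream) {
  const int n = weights.nrow();
  if (weights.ncol() != n || delay_steps.nrow() != n || delay_steps.ncol() != n)
    stop("weights and delay_steps must be square matrices of equal size");

  const int B = 32;  // block length (steps)

  // edge lists: (target i, source j, weight, delay); long edges (d >= B)
  // gathered blockwise, short edges step by step
  struct Edge { int i, j, d; double w; };
  std::vector<Edge> elong, eshort;
  int max_d = 1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (j != i && weights(i, j) != 0.0) {
        int d = delay_steps(i, j);
        if (d < 1) d = 1;
        if (d > max_d) max_d = d;
        Edge e{i, j, d, weights(i, j)};
        if (d >= B) elong.push_back(e); else eshort.push_back(e);
      }

  int R = 1;
  while (R < max_d + B + 1) R <<= 1;
  const int mask = R - 1;

  const long long total_steps = llround(duration / dt);
  if (out_every < 1) stop("out_every must be >= 1");
  if (total_steps % out_every != 0)
    stop("duration must be an integer number of output intervals");
  const long long K = total_steps / out_every;
  const long long kmin = llround(discard / (out_every * dt));
  const long long n_keep = K - kmin;
  if (n_keep <= 0) stop("discard leaves no samples");

  NumericMatrix Eout(n, (int)n_keep);
  NumericMatrix Iout(record_inh ? n : 1, record_inh ? (int)n_keep : 1);

  std::vector<double> ring((size_t)n * R, init_value);
  std::vector<double> E(n, init_value), I(n, init_value);
  std::vector<double> coupin((size_t)n * B, 0.0);
  std::vector<double> xE(n), xI(n), sE(n), sI(n);

  const double kE = 1.0 / (1.0 + std::exp(aE * thE));
  const double kI = 1.0 / (1.0 + std::exp(aI * thI));
  const double rdt = dt / tau;
  const double noise_fac = (sigma / tau) * std::sqrt(dt);
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);

  long long clipped = 0;
  const double eps_t = 1e-12;
  const long long on_step = llround(stim_onset / dt);
  const long long off_step = llround(stim_offset / dt);

  for (long long s0 = 0; s0 < total_steps; s0 += B) {
    const int nb = (int)std::min<long long>(B, total_steps - s0);

    // blockwise gather of long-delay inputs (all source states predate s0)
    std::fill(coupin.begin(), coupin.begin() + (size_t)n * nb, 0.0);
    for (const Edge& e : elong) {
      const double w = e.w;
      double* acc = &coupin[(size_t)e.i * B];
      const double* src = &ring[(size_t)e.j * R];
      int p = (int)((s0 - e.d) & mask);
      const int run1 = std::min(nb, R - p);
      for (int t = 0; t < run1; ++t) acc[t] += w * src[p + t];
      for (int t = run1; t < nb; ++t) acc[t] += w * src[t - run1];
    }

    for (int tb = 0; tb < nb; ++tb) {
      const long long s = s0 + tb;
      const bool stim_on = stim_site >= 0 && s >= on_step && s < off_step;
      const int slot = (int)(s & mask);
      const int next_slot = (slot + 1) & mask;

      for (int i = 0; i < n; ++i) {
        xE[i] = cEE * E[i] - cIE * I[i] + cglob * coupin[(size_t)i * B + tb];
        xI[i] = cEI * E[i] - cII * I[i];
      }
      for (const Edge& e : eshort) {
        int idx = slot - e.d;
        if (idx < 0) idx += R;
        xE[e.i] += cglob * e.w * ring[(size_t)e.j * R + idx];
      }
      if (stim_on) xE[stim_site] += stim_amp;
      for (int i = 0; i < n; ++i) {  // vectorizable sigmoid pass
        sE[i] = 1.0 / (1.0 + fast_exp(-aE * (xE[i] - thE))) - kE;
        sI[i] = 1.0 / (1.0 + fast_exp(-aI * (xI[i] - thI))) - kI;
      }
      if (sigma > 0.0) {
        for (int i = 0; i < n; ++i) {
          double En = E[i] + rdt * (-E[i] + (SEmax - E[i]) * sE[i]) +
                      noise_fac * rng.norm();
          double In = I[i] + rdt * (-I[i] + (SImax - I[i]) * sI[i]) +
                      noise_fac * rng.norm();
          if (En < 0.0) { En = 0.0; ++clipped; }
          else if (En > 1.0) { En = 1.0; ++clipped; }
          if (In < 0.0) { In = 0.0; ++clipped; }
          else if (In > 1.0) { In = 1.0; ++clipped; }
          E[i] = En;
          I[i] = In;
          ring[(size_t)i * R + next_slot] = En;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double En = E[i] + rdt * (-E[i] + (SEmax - E[i]) * sE[i]);
          double In = I[i] + rdt * (-I[i] + (SImax - I[i]) * sI[i]);
          if (En < 0.0) { En = 0.0; ++clipped; }
          else if (En > 1.0) { En = 1.0; ++clipped; }
          if (In < 0.0) { In = 0.0; ++clipped; }
          else if (In > 1.0) { In = 1.0; ++clipped; }
          E[i] = En;
          I[i] = In;
          ring[(size_t)i * R + next_slot] = En;
        }
      }

      if (!std::isfinite(E[0]) || !std::isfinite(I[0]))
        stop("non-finite state at t = %f; try a smaller dt", s * dt);

      if ((s + 1) % out_every == 0) {
        const long long k = (s + 1) / out_every;
        if (k > kmin) {
          const int col = (int)(k - kmin - 1);
          for (int i = 0; i < n; ++i) Eout(i, col) = E[i];
          if (record_inh)
            for (int i = 0; i < n; ++i) Iout(i, col) = I[i];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // clipping (or an exactly absorbing boundary) keeps states finite; a
  // blow-up would surface as persistent clipping, reported to the caller
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(E[i]) || !std::isfinite(I[i]))
      stop("non-finite terminal state (node %d); try a smaller dt", i + 1);

  List out = List::create(_["excitatory"] = Eout,
                          _["n_clipped"] = (double)clipped,
                          _["first_sample"] = (double)((kmin + 1) * out_every) * dt,
                          _["sample_interval"] = out_every * dt);
  if (record_inh) out["inhibitory"] = Iout;
  return out;
}

// standard normals from the integrator's generator, for statistical tests
// of the noise stream
// [[Rcpp::export]]
NumericVector rng_normals_cpp(int n, double seed, double stream) {
  Xoshiro256 rng((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// exposed for accuracy checks of the integrator's exponential
// [[Rcpp::export]]
NumericVector fast_exp_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = fast_exp(x[i]);
  return out;
}
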