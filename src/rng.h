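#ifndef SENSEDYN_RNG_H
#define SENSEDYN_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG (xoshiro256++ seeded via splitmix64) so that
// per-cell substreams are reproducible across platforms and independent of R's
// global generator. Cell i of a run with master seed s always sees the same stream
// regardless of how many cells are requested.
struct CellRng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  CellRng(uint64_t master, uint64_t stream) : have_spare(false), spare(0.0) {
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // --- ziggurat tables for the standard exponential (Marsaglia & Tsang) ---
  struct ZigTables {
    uint32_t ke[256];
    double we[256], fe[256];
    ZigTables() {
      const double m2 = 4294967296.0;
      double de = 7.697117470131487, te = de, ve = 3.949659822581572e-3;
      double q = ve / std::exp(-de);
      ke[0] = (uint32_t)((de / q) * m2);
      ke[1] = 0;
      we[0] = q / m2;
      we[255] = de / m2;
      fe[0] = 1.0;
      fe[255] = std::exp(-de);
      for (int i = 254; i >= 1; --i) {
        de = -std::log(ve / de + std::exp(-de));
        ke[i + 1] = (uint32_t)((de / te) * m2);
        te = de;
        we[i] = de / m2;
        fe[i] = std::exp(-de);
      }
    }
  };
  static const ZigTables &zig() {
    static ZigTables t;
    return t;
  }

  // standard exponential deviate via the ziggurat (exact; ~1 uniform/draw)
  double rexp1() {
    const ZigTables &t = zig();
    for (;;) {
      uint32_t jz = (uint32_t)(next() >> 32);
      int iz = jz & 255;
      if (jz < t.ke[iz]) return jz * t.we[iz];
      if (iz == 0) {
        double u;
        do { u = unif(); } while (u <= 0.0);
        return 7.697117470131487 - std::log(u);
      }
      double x = jz * t.we[iz];
      if (t.fe[iz] + unif() * (t.fe[iz - 1] - t.fe[iz]) < std::exp(-x))
        return x;
    }
  }

  // exponential with given rate (rate > 0)
  double rexp(double rate) { return rexp1() / rate; }

  double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }

  // Marsaglia-Tsang gamma for shape >= 1, unit rate
  double rgamma_shape(double a) {
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = rnorm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      double x2 = x * x;
      if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
      if (u > 0.0 && std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  // Poisson: Knuth inversion for small mean, Hormann PTRS otherwise
  int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda);
      int kk = 0;
      double p = 1.0;
      do { ++kk; p *= unif(); } while (p > L);
      return kk - 1;
    }
    // PTRS transformed rejection (Hormann 1993)
    double b = 0.931 + 2.53 * std::sqrt(lambda);
    double a = -0.059 + 0.02483 * b;
    double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    double v_r = 0.9277 - 3.6224 / (b - 2.0);
    double loglam = std::log(lambda);
    for (;;) {
      double U = unif() - 0.5;
      double V = unif();
      double us = 0.5 - std::fabs(U);
      double kf = std::floor((2.0 * a / us + b) * U + lambda + 0.43);
      if (us >= 0.07 && V <= v_r) return (int)kf;
      if (kf < 0.0 || (us < 0.013 && V > us)) continue;
      if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          kf * loglam - lambda - std::lgamma(kf + 1.0))
        return (int)kf;
    }
  }
};

#endif
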