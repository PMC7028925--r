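#ifndef HYBRIDGATE_RNG_H
#define HYBRIDGATE_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained xoshiro256++ generator (Blackman & Vigna), seeded through
// splitmix64. The Gibbs samplers draw ~1e9 variates per fit; an inlined
// generator keeps the per-copy update cost at a few ns and makes runs
// reproducible from a single 64-bit seed independently of R's RNG stream.
class Xoshiro {
 public:
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s_[i] = z ^ (z >> 31);
    }
    have_spare_ = false;
    spare_ = 0.0;
  }

  inline uint64_t next_u64() {
    const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform on (0,1); never exactly 0
  inline double unif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via Box-Muller with caching
  inline double norm() {
    if (have_spare_) {
      have_spare_ = false;
      return spare_;
    }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double theta = 6.283185307179586476925286766559 * v;
    spare_ = r * std::sin(theta);
    have_spare_ = true;
    return r * std::cos(theta);
  }

  // Gamma(shape, 1), Marsaglia & Tsang (2000); boost for shape < 1
  double rgamma(double shape) {
    if (shape < 1.0) {
      double u = unif();
      return rgamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    const double d = shape - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = norm();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

 private:
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t s_[4];
  bool have_spare_;
  double spare_;
};

#endif
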