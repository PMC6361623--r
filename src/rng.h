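#ifndef BLGAMMA_RNG_H
#define BLGAMMA_RNG_H

#include <cstdint>
#include <cmath>

// Deterministic, seedable RNG independent of R's global stream.
// xoshiro256+ seeded through splitmix64; per-cell streams are derived from
// (master seed, stream id) so that adding cells does not perturb the noise
// of existing ones.

namespace blg {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0x9E3779B97F4A7C15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0,1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double unif(double a, double b) { return a + (b - a) * unif(); }

  // standard normal, polar Box-Muller with caching
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }

  // Poisson by inversion (small means) / normal approx for large means
  inline int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    double x = lambda + std::sqrt(lambda) * norm();
    return x < 0 ? 0 : (int)(x + 0.5);
  }
};

} // namespace blg

#endif
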