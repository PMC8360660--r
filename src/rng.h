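#ifndef NGFSUM_RNG_H
#define NGFSUM_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256+ with splitmix64 seeding: fast deterministic RNG for the
// particle walkers; seeded explicitly from R so results are reproducible.
struct XRng {
  uint64_t s[4];
  explicit XRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline int unif_int(int n) { return (int)(unif() * n) % n; }
  // Box-Muller with cache
  bool has_cached = false;
  double cached = 0.0;
  inline double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }
};

#endif
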