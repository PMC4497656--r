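#pragma once
#include <cstdint>
#include <cstdlib>
#include <cmath>

// Self-contained xoshiro256++ generator with ziggurat normals
// (Marsaglia & Tsang 2000, 128 strips). Used instead of R's RNG in the
// hot simulation loops so that a run is a pure function of the integer
// seed passed in, independent of the caller's R RNG state, and cheap
// enough for one draw per neuron per 0.1 ms step.

struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;  // 2^31
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

inline const ZigTables& zig_tables() {
  static const ZigTables t;
  return t;
}

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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

  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal, ziggurat method
  inline double norm() {
    const ZigTables& z = zig_tables();
    const double R = 3.442619855899;
    for (;;) {
      const int32_t hz = (int32_t)(uint32_t)next();
      const int iz = hz & 127;
      if ((uint32_t)std::abs((long)hz) < z.kn[iz]) return hz * z.wn[iz];
      if (iz == 0) {  // tail beyond R
        double x, y;
        do {
          x = -std::log(unif()) / R;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? R + x : -(R + x);
      }
      const double x = hz * z.wn[iz];
      if (z.fn[iz] + unif() * (z.fn[iz - 1] - z.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};
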