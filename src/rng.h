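#ifndef ENSMECH_RNG_H
#define ENSMECH_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained deterministic RNG (xorshift64* seeded through splitmix64).
// Used instead of R's RNG so conformer/sequence streams are reproducible
// bit-for-bit given a master seed, independent of R RNG state and platform.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scramble so small consecutive seeds give unrelated streams
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  // integer in [0, n)
  int below(int n) { return (int)(unif() * n) % n; }
  double norm() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

#endif
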