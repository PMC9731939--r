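#ifndef CDEXPLAIN_RNG_H
#define CDEXPLAIN_RNG_H

#include <cstdint>
#include <vector>

// Small deterministic RNG (xoshiro256**) so that seeded results are
// identical across platforms and independent of R's RNG state.
struct CdRng {
  uint64_t s[4];

  explicit CdRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
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

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform integer in [0, n), rejection sampling (no modulo bias)
  int randint(int n) {
    uint64_t bound = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do {
      x = next();
    } while (x >= bound);
    return (int)(x % (uint64_t)n);
  }

  template <typename T>
  void shuffle(std::vector<T>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = randint(i + 1);
      T tmp = v[i];
      v[i] = v[j];
      v[j] = tmp;
    }
  }
};

#endif
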