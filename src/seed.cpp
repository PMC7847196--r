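// Deterministic seed derivation for nested simulation streams
// (root -> study/cell -> replicate -> animal). A bijective 64-bit mixing
// finaliser (splitmix64) keeps derived streams free of the collisions a
// linear scheme would create across nesting levels.

#include <Rcpp.h>
#include <cstdint>

// [[Rcpp::export]]
int derive_seed_cpp(int seed, int index) {
  uint64_t z = (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL +
               (uint64_t)(uint32_t)index * 0xBF58476D1CE4E5B9ULL +
               0x94D049BB133111EBULL;
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return (int)(z % 2147483646ULL) + 1; // in [1, 2^31 - 1], valid for set.seed
}
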