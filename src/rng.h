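#ifndef EIMATCH_RNG_H
#define EIMATCH_RNG_H

#include <cstdint>

// splitmix64: tiny deterministic generator, identical across platforms.
// Used for level assignment, CBOW init and negative sampling so that a
// fixed seed gives bit-identical results independently of R's RNG state.
struct SplitMix64 {
    uint64_t state;
    explicit SplitMix64(uint64_t seed) : state(seed) {}
    uint64_t next() {
        uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    // uniform on the open interval (0, 1): never returns 0 or 1, so
    // log(u) is always finite
    double unif() {
        return (static_cast<double>(next() >> 11) + 0.5) *
               (1.0 / 9007199254740992.0);
    }
};

#endif
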