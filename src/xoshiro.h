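#pragma once
#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding.  Normal deviates by the Marsaglia
// polar method with one cached spare.  Self-contained so that per-step noise
// in the simulator does not go through R's RNG API.
struct SimRng {
    uint64_t s[4];
    double spare;
    bool has_spare;

    explicit SimRng(uint64_t seed) : spare(0.0), has_spare(false) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9E3779B97f4A7C15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
            z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
            s[i] = z ^ (z >> 31);
        }
    }

    static inline uint64_t rotl(uint64_t x, int k) {
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

    // uniform on [0, 1)
    inline double unif() {
        return (next() >> 11) * 0x1.0p-53;
    }

    inline double norm() {
        if (has_spare) {
            has_spare = false;
            return spare;
        }
        double u, v, s2;
        do {
            u = 2.0 * unif() - 1.0;
            v = 2.0 * unif() - 1.0;
            s2 = u * u + v * v;
        } while (s2 >= 1.0 || s2 == 0.0);
        const double f = std::sqrt(-2.0 * std::log(s2) / s2);
        spare = v * f;
        has_spare = true;
        return u * f;
    }
};
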