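// Sequencing-error injection.  Short reads get substitutions only; long
// reads get substitutions, insertions and deletions in a fixed 60/20/20
// split of the total error rate.  A self-contained splitmix64 PRNG keyed by
// (seed, sequence index) keeps results reproducible and order-independent.

#include <Rcpp.h>
#include <string>
#include "dna_utils.h"

using namespace Rcpp;

struct SplitMix {
    uint64_t state;
    explicit SplitMix(uint64_t s) : state(s) {}
    uint64_t next() {
        state += 0x9E3779B97F4A7C15ULL;
        uint64_t z = state;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    int rint(int n) { return (int)(next() % (uint64_t)n); }
};

// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double sub_rate,
                                double ins_rate, double del_rate,
                                double seed) {
    CharacterVector out(seqs.size());
    double total = sub_rate + ins_rate + del_rate;
    if (total <= 0) return clone(seqs);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        SplitMix rng(splitmix64((uint64_t)seed) ^ splitmix64((uint64_t)i + 1));
        std::string m;
        for (const char *p = s; *p; ++p) {
            double u = rng.runif();
            if (u < sub_rate) {
                int b = encode_base(*p);
                int nb = b < 0 ? rng.rint(4) : (b + 1 + rng.rint(3)) % 4;
                m.push_back(decode_base(nb));
            } else if (u < sub_rate + del_rate) {
                // deletion: skip base
            } else if (u < total) {
                m.push_back(*p);
                m.push_back(decode_base(rng.rint(4)));
            } else {
                m.push_back(*p);
            }
        }
        out[i] = m;
    }
    return out;
}
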