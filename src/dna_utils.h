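#ifndef IHAMAG_DNA_UTILS_H
#define IHAMAG_DNA_UTILS_H

#include <cstdint>
#include <string>

// 2-bit DNA encoding: A=0, C=1, G=2, T=3; anything else -1.
inline int encode_base(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

inline char decode_base(int b) {
    static const char tab[4] = {'A', 'C', 'G', 'T'};
    return tab[b & 3];
}

inline std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break; case 'a': c = 'T'; break;
        case 'C': c = 'G'; break; case 'c': c = 'G'; break;
        case 'G': c = 'C'; break; case 'g': c = 'C'; break;
        case 'T': c = 'A'; break; case 't': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

// splitmix64: fast, well-mixed 64-bit hash / PRNG step.
inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// Rolling k-mer scanner over one sequence.  Maintains forward and
// reverse-complement encodings; valid() is false until k consecutive
// ACGT bases have been seen.
struct KmerRoller {
    int k;
    uint64_t mask, fwd, rev;
    int filled;
    explicit KmerRoller(int k_) : k(k_), fwd(0), rev(0), filled(0) {
        mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    }
    void reset() { fwd = rev = 0; filled = 0; }
    // feed one base; returns true if a full valid k-mer is available
    bool push(char c) {
        int b = encode_base(c);
        if (b < 0) { reset(); return false; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
        if (filled < k) ++filled;
        return filled == k;
    }
    uint64_t canon() const { return fwd < rev ? fwd : rev; }
    // +1 if the canonical form equals the forward strand
    int canon_strand() const { return fwd <= rev ? +1 : -1; }
};

inline std::string decode_kmer(uint64_t km, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = decode_base((int)(km & 3ULL));
        km >>= 2;
    }
    return s;
}

#endif
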