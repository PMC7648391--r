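// Bottom-s MinHash sketches of canonical k-mer sets (Mash-style).
// Hashes are masked to 53 bits so they survive the round trip through
// R doubles exactly.

#include <Rcpp.h>
#include <unordered_set>
#include <queue>
#include <vector>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

static const uint64_t HASH53 = (1ULL << 53) - 1ULL;

// [[Rcpp::export]]
NumericVector cpp_minhash_sketch(CharacterVector seqs, int k, int sketch_size) {
    std::priority_queue<uint64_t> heap; // max-heap of the bottom-s hashes
    std::unordered_set<uint64_t> in_heap;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        KmerRoller roll(k);
        for (const char *p = s; *p; ++p) {
            if (!roll.push(*p)) continue;
            uint64_t h = splitmix64(roll.canon()) & HASH53;
            if ((int)heap.size() < sketch_size) {
                if (in_heap.insert(h).second) heap.push(h);
            } else if (h < heap.top()) {
                if (in_heap.insert(h).second) {
                    in_heap.erase(heap.top());
                    heap.pop();
                    heap.push(h);
                }
            }
        }
    }
    std::vector<uint64_t> v;
    v.reserve(heap.size());
    while (!heap.empty()) { v.push_back(heap.top()); heap.pop(); }
    std::sort(v.begin(), v.end());
    NumericVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_kmer_hash_set(CharacterVector seqs, int k) {
    // full hashed canonical k-mer set (exact-Jaccard oracle support)
    std::unordered_set<uint64_t> set;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        KmerRoller roll(k);
        for (const char *p = s; *p; ++p)
            if (roll.push(*p)) set.insert(splitmix64(roll.canon()) & HASH53);
    }
    std::vector<uint64_t> v(set.begin(), set.end());
    std::sort(v.begin(), v.end());
    NumericVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
    return out;
}
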