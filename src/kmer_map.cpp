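// k-mer based read-vs-genome machinery:
//  - cpp_kmer_vote: fraction of a read's k-mers present in a reference set
//    (the built-in short-read recruiter, a bowtie2 stand-in on synthetic data)
//  - cpp_chain_align: exact-anchor seeding + colinear chaining, emitting
//    PAF-semantics records with a k-mer-survival identity estimate
//  - cpp_anchor_hits: raw unique-anchor matches for the reference-based
//    evaluation aligner (chaining and gap scoring happen in R)

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <algorithm>
#include "dna_utils.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_kmer_vote(CharacterVector reads, CharacterVector refs, int k) {
    std::unordered_set<uint64_t> refset;
    for (R_xlen_t i = 0; i < refs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(refs, i));
        KmerRoller roll(k);
        for (const char *p = s; *p; ++p)
            if (roll.push(*p)) refset.insert(roll.canon());
    }
    NumericVector out(reads.size());
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        const char *s = CHAR(STRING_ELT(reads, i));
        KmerRoller roll(k);
        int n = 0, hit = 0;
        for (const char *p = s; *p; ++p)
            if (roll.push(*p)) {
                ++n;
                if (refset.count(roll.canon())) ++hit;
            }
        out[i] = (n > 0) ? (double)hit / n : 0.0;
    }
    return out;
}

struct RefAnchor {
    int32_t t;
    int32_t pos;
    int8_t strand;
};

// [[Rcpp::export]]
DataFrame cpp_chain_align(CharacterVector queries, CharacterVector targets,
                          int k, int max_occ, int min_anchors, int max_gap) {
    // index target k-mers, dropping over-represented ones
    std::unordered_map<uint64_t, std::vector<RefAnchor>> index;
    std::vector<int> tlen(targets.size());
    for (R_xlen_t t = 0; t < targets.size(); ++t) {
        const char *s = CHAR(STRING_ELT(targets, t));
        tlen[t] = (int)strlen(s);
        KmerRoller roll(k);
        for (int i = 0; s[i]; ++i)
            if (roll.push(s[i])) {
                auto &v = index[roll.canon()];
                if ((int)v.size() <= max_occ)
                    v.push_back({(int32_t)t, (int32_t)(i - k + 1),
                                 (int8_t)roll.canon_strand()});
            }
    }
    for (auto it = index.begin(); it != index.end();) {
        if ((int)it->second.size() > max_occ) it = index.erase(it);
        else ++it;
    }

    std::vector<int> o_q, o_t, o_qs, o_qe, o_ts, o_te, o_nm, o_bl, o_na, o_ql, o_tl;
    std::vector<int> o_strand;
    std::vector<double> o_cov;

    struct Hit { int qpos, tpos; };
    for (R_xlen_t q = 0; q < queries.size(); ++q) {
        const char *s = CHAR(STRING_ELT(queries, q));
        int qlen = (int)strlen(s);
        // hits grouped by (target, rel strand)
        std::map<std::pair<int, int>, std::vector<Hit>> groups;
        KmerRoller roll(k);
        for (int i = 0; s[i]; ++i)
            if (roll.push(s[i])) {
                auto it = index.find(roll.canon());
                if (it == index.end()) continue;
                int qpos = i - k + 1;
                for (const RefAnchor &a : it->second) {
                    int rel = roll.canon_strand() * a.strand;
                    groups[{a.t, rel}].push_back({qpos, (int)a.pos});
                }
            }
        for (auto &g : groups) {
            int t = g.first.first, rel = g.first.second;
            std::vector<Hit> &hits = g.second; // already in qpos order
            // greedy colinear chaining; each anchor joins at most one chain
            std::vector<bool> consumed(hits.size(), false);
            for (size_t i = 0; i < hits.size(); ++i) {
                if (consumed[i]) continue;
                std::vector<size_t> chain{i};
                consumed[i] = true;
                double diag0 = (rel > 0) ? (double)hits[i].tpos - hits[i].qpos
                                         : (double)hits[i].tpos + hits[i].qpos;
                size_t j = i + 1, last = i;
                for (; j < hits.size(); ++j) {
                    if (consumed[j]) continue;
                    int dq = hits[j].qpos - hits[last].qpos;
                    if (dq <= 0) continue;
                    if (dq > max_gap) break;
                    double diag = (rel > 0) ? (double)hits[j].tpos - hits[j].qpos
                                            : (double)hits[j].tpos + hits[j].qpos;
                    int dt = (rel > 0) ? hits[j].tpos - hits[last].tpos
                                       : hits[last].tpos - hits[j].tpos;
                    if (dt <= 0) continue;
                    if (std::abs(diag - diag0) > 0.1 * hits[j].qpos + 50) continue;
                    chain.push_back(j);
                    consumed[j] = true;
                    last = j;
                }
                int na = (int)chain.size();
                if (na >= min_anchors) {
                    int qs = hits[chain.front()].qpos;
                    int qe = hits[chain.back()].qpos + k;
                    int ts, te;
                    if (rel > 0) {
                        ts = hits[chain.front()].tpos;
                        te = hits[chain.back()].tpos + k;
                    } else {
                        ts = hits[chain.back()].tpos;
                        te = hits[chain.front()].tpos + k;
                    }
                    int span_kmers = qe - qs - k + 1;
                    double f = std::min(1.0, (double)na / span_kmers);
                    double ident = std::pow(std::max(f, 1e-12), 1.0 / k);
                    int bl = std::max(qe - qs, te - ts);
                    // extend the query span to its ends where the target
                    // continues (homologous extension for coverage)
                    int ext_l = (rel > 0) ? std::min(qs, ts)
                                          : std::min(qs, tlen[t] - te);
                    int ext_r = (rel > 0) ? std::min(qlen - qe, tlen[t] - te)
                                          : std::min(qlen - qe, ts);
                    o_q.push_back((int)q + 1);
                    o_ql.push_back(qlen);
                    o_qs.push_back(qs);
                    o_qe.push_back(qe);
                    o_strand.push_back(rel);
                    o_t.push_back(t + 1);
                    o_tl.push_back(tlen[t]);
                    o_ts.push_back(ts);
                    o_te.push_back(te);
                    o_nm.push_back((int)std::lround(ident * bl));
                    o_bl.push_back(bl);
                    o_na.push_back(na);
                    o_cov.push_back((double)(qe - qs + ext_l + ext_r) / qlen);
                }
                // next unchained hit
                size_t nxt = i + 1;
                std::unordered_set<size_t> inchain(chain.begin(), chain.end());
                while (nxt < hits.size() && inchain.count(nxt)) ++nxt;
                i = nxt;
            }
        }
    }
    return DataFrame::create(
        _["query"] = o_q, _["qlen"] = o_ql, _["qstart"] = o_qs, _["qend"] = o_qe,
        _["strand"] = o_strand, _["target"] = o_t, _["tlen"] = o_tl,
        _["tstart"] = o_ts, _["tend"] = o_te, _["nmatch"] = o_nm,
        _["blocklen"] = o_bl, _["n_anchors"] = o_na,
        _["qcov_ext"] = o_cov);
}

// [[Rcpp::export]]
DataFrame cpp_anchor_hits(std::string query, std::string target, int k) {
    // k-mers unique in the target, matched exactly in the query
    std::unordered_map<uint64_t, RefAnchor> index;
    std::unordered_set<uint64_t> dup;
    {
        KmerRoller roll(k);
        for (size_t i = 0; i < target.size(); ++i)
            if (roll.push(target[i])) {
                uint64_t c = roll.canon();
                if (dup.count(c)) continue;
                if (index.count(c)) { index.erase(c); dup.insert(c); continue; }
                index[c] = {0, (int32_t)(i - k + 1), (int8_t)roll.canon_strand()};
            }
    }
    std::vector<int> qpos, tpos, strand;
    KmerRoller roll(k);
    for (size_t i = 0; i < query.size(); ++i)
        if (roll.push(query[i])) {
            auto it = index.find(roll.canon());
            if (it == index.end()) continue;
            qpos.push_back((int)(i - k + 1));
            tpos.push_back((int)it->second.pos);
            strand.push_back(roll.canon_strand() * it->second.strand);
        }
    return DataFrame::create(_["qpos"] = qpos, _["tpos"] = tpos,
                             _["strand"] = strand);
}
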