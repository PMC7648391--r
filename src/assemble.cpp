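// Built-in hybrid assembler: canonical de Bruijn graph on short-read k-mers,
// unitig extraction, then unitig joining guided by exact k-mer anchors along
// long reads.  Junction sequence always comes from the unitig copies (joins
// require a verified exact suffix/prefix overlap); ambiguous junctions caused
// by repeats are resolved by read-level triple spans (X -> repeat -> Y).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <map>
#include "dna_utils.h"

using namespace Rcpp;

static uint64_t rc_kmer(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return r;
}

typedef std::unordered_map<uint64_t, uint32_t> KmerCounts;

// number of solid successors of the oriented k-mer (f, r); if exactly one,
// also reports it through nf/nr.
static int succ_count(uint64_t f, uint64_t r, int k, uint64_t mask,
                      const KmerCounts &solid,
                      uint64_t *nf_out = nullptr, uint64_t *nr_out = nullptr) {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
        uint64_t nf = ((f << 2) | b) & mask;
        uint64_t nr = (r >> 2) | ((3ULL - b) << (2 * (k - 1)));
        uint64_t canon = nf < nr ? nf : nr;
        if (solid.count(canon)) {
            ++n;
            if (nf_out) { *nf_out = nf; *nr_out = nr; }
        }
    }
    return n;
}

struct Unitig {
    std::string seq;
    double depth;
    bool circ;
};

// anchor: where a solid k-mer lives among the linear unitigs
struct KAnchor {
    int32_t u;
    int32_t pos;
    int8_t strand; // +1 if canonical form == unitig forward strand
};

struct Visit {
    int u;
    int rel;             // +1 read matches unitig forward
    int first_q, last_q;
    int first_up, last_up;
    int n;
    double est_start, est_end; // read coords where the full unitig would sit
};

// unordered end pair key; end = 2*u + side (0 left, 1 right)
static inline uint64_t end_pair_key(int64_t e1, int64_t e2) {
    if (e1 > e2) std::swap(e1, e2);
    return ((uint64_t)e1 << 32) | (uint64_t)e2;
}

struct LinkInfo { int count = 0; double gap_sum = 0; };

struct TripleInfo { int count = 0; double g1_sum = 0, g2_sum = 0; };

struct Join {
    bool present = false;
    int64_t to = -1;       // partner end
    bool via = false;
    int via_u = -1;
    int via_orient = 0;    // +1 insert forward, -1 reverse, travelling out of this end
    double gap1 = 0, gap2 = 0;
};

// exact suffix(left)/prefix(right) overlap closest to -gap_est;
// returns 0 when no acceptable overlap exists.
static int best_overlap(const std::string &left, const std::string &right,
                        double gap_est, int k) {
    int maxo = std::min((int)std::min(left.size(), right.size()), k + 20);
    int best = 0;
    double best_d = 1e18;
    for (int o = 5; o <= maxo; ++o) {
        if (left.compare(left.size() - o, o, right, 0, o) == 0) {
            double d = std::abs((double)o + gap_est);
            if (d < best_d) { best_d = d; best = o; }
        }
    }
    if (best > 0 && best_d <= 60.0) return best;
    return 0;
}

// [[Rcpp::export]]
List cpp_toy_assemble(CharacterVector sr_seqs, CharacterVector lr_seqs,
                      int k, int min_depth, int min_contig_len,
                      int bridge_min_links, double erode_frac) {
    if (k < 15 || k > 31 || k % 2 == 0)
        stop("k must be odd and within [15, 31]");
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;

    // ---- k-mer counting over short reads ----
    KmerCounts counts;
    counts.reserve(1 << 20);
    for (R_xlen_t i = 0; i < sr_seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(sr_seqs, i));
        KmerRoller roll(k);
        for (const char *p = s; *p; ++p)
            if (roll.push(*p)) {
                auto it = counts.find(roll.canon());
                if (it == counts.end()) counts.emplace(roll.canon(), 1);
                else ++(it->second);
            }
    }
    // solid set
    for (auto it = counts.begin(); it != counts.end();) {
        if ((int)it->second < min_depth) it = counts.erase(it);
        else ++it;
    }
    KmerCounts &solid = counts;

    // deterministic seed order
    std::vector<uint64_t> seeds;
    seeds.reserve(solid.size());
    for (auto &kv : solid) seeds.push_back(kv.first);
    std::sort(seeds.begin(), seeds.end());

    // ---- unitig extraction ----
    std::unordered_set<uint64_t> visited;
    visited.reserve(solid.size());
    std::vector<Unitig> units;
    for (uint64_t c : seeds) {
        if (visited.count(c)) continue;
        uint64_t f0 = c, r0 = rc_kmer(c, k);
        std::string seq = decode_kmer(f0, k);
        double dsum = solid.at(c);
        int nk = 1;
        bool circ = false;
        visited.insert(c);
        uint64_t f = f0, r = r0, nf, nr;
        while (true) { // extend right
            if (succ_count(f, r, k, mask, solid, &nf, &nr) != 1) break;
            if (succ_count(nr, nf, k, mask, solid) != 1) break;
            uint64_t nc = nf < nr ? nf : nr;
            if (nc == c && nf == f0) { circ = true; break; }
            if (visited.count(nc)) break;
            visited.insert(nc);
            seq.push_back(decode_base((int)(nf & 3ULL)));
            dsum += solid.at(nc);
            ++nk;
            f = nf; r = nr;
        }
        if (!circ) { // extend left = extend right in rc orientation
            f = r0; r = f0;
            std::string left;
            while (true) {
                if (succ_count(f, r, k, mask, solid, &nf, &nr) != 1) break;
                if (succ_count(nr, nf, k, mask, solid) != 1) break;
                uint64_t nc = nf < nr ? nf : nr;
                if (visited.count(nc)) break;
                visited.insert(nc);
                left.push_back(decode_base((int)(nf & 3ULL)));
                dsum += solid.at(nc);
                ++nk;
                f = nf; r = nr;
            }
            if (!left.empty()) seq = revcomp_str(left) + seq;
        }
        Unitig u;
        u.seq = seq;
        u.depth = dsum / nk;
        u.circ = circ;
        units.push_back(std::move(u));
    }

    // erosion: unitigs barely above the solidity cutoff belong to
    // organisms too rare to assemble this cycle; removing them untangles
    // the shared-element neighbourhoods of the assemblable genomes
    if (erode_frac > 0 && units.size() > 1) {
        double thr = erode_frac * min_depth;
        std::vector<Unitig> kept;
        for (auto &u : units)
            if (u.depth >= thr) kept.push_back(std::move(u));
        if (!kept.empty()) units = std::move(kept);
    }

    int nu = (int)units.size();
    if (std::getenv("IHAMAG_DEBUG_JOINS"))
        for (int u = 0; u < nu; ++u)
            Rcpp::Rcout << "UNIT " << u << " len " << units[u].seq.size()
                        << " depth " << units[u].depth << " head "
                        << units[u].seq.substr((units[u].seq.size() > 25) ? (units[u].seq.size() / 2 - 12) : 0,
                                               std::min<size_t>(25, units[u].seq.size()))
                        << "\n";
    std::vector<std::string> contig_seqs;
    std::vector<bool> contig_circ;
    std::vector<double> contig_depth;

    bool have_lr = lr_seqs.size() > 0;
    std::vector<Join> joins;
    if (have_lr && nu > 0) {
        // ---- anchor index over linear unitigs ----
        std::unordered_map<uint64_t, KAnchor> index;
        index.reserve(solid.size());
        for (int u = 0; u < nu; ++u) {
            if (units[u].circ) continue;
            KmerRoller roll(k);
            const std::string &s = units[u].seq;
            for (size_t i = 0; i < s.size(); ++i)
                if (roll.push(s[i])) {
                    KAnchor a;
                    a.u = u;
                    a.pos = (int32_t)(i - k + 1);
                    a.strand = (int8_t)roll.canon_strand();
                    index[roll.canon()] = a;
                }
        }

        std::unordered_map<uint64_t, LinkInfo> links;
        // triple key: end pair key -> map over (via_u, orient when e1 -> e2)
        std::unordered_map<uint64_t, std::map<std::pair<int, int>, TripleInfo>> triples;

        for (R_xlen_t ri = 0; ri < lr_seqs.size(); ++ri) {
            const char *sp = CHAR(STRING_ELT(lr_seqs, ri));
            std::string s(sp);
            KmerRoller roll(k);
            std::vector<Visit> visits;
            Visit cur; cur.u = -1;
            double prev_diag = 0; int prev_q = 0;
            for (size_t i = 0; i < s.size(); ++i) {
                if (!roll.push(s[i])) continue;
                auto it = index.find(roll.canon());
                if (it == index.end()) continue;
                const KAnchor &a = it->second;
                int qpos = (int)(i - k + 1);
                int rel = roll.canon_strand() * a.strand;
                double diag = (rel > 0) ? (double)qpos - a.pos
                                        : (double)qpos + a.pos;
                bool fresh = (cur.u < 0 || a.u != cur.u || rel != cur.rel ||
                              qpos - prev_q > 3000 ||
                              std::abs(diag - prev_diag) > 50 + 0.05 * (qpos - prev_q));
                if (fresh) {
                    if (cur.u >= 0) visits.push_back(cur);
                    cur.u = a.u; cur.rel = rel;
                    cur.first_q = qpos; cur.first_up = a.pos;
                    cur.n = 0;
                }
                cur.last_q = qpos; cur.last_up = a.pos;
                ++cur.n;
                prev_diag = diag; prev_q = qpos;
            }
            if (cur.u >= 0) visits.push_back(cur);
            // extrapolated read coordinates of each unitig's span
            for (auto &v : visits) {
                int ulen = (int)units[v.u].seq.size();
                if (v.rel > 0) {
                    v.est_start = v.first_q - v.first_up;
                    v.est_end = v.last_q + (ulen - v.last_up);
                } else {
                    v.est_start = v.first_q - (ulen - (v.first_up + k));
                    v.est_end = v.last_q + k + v.last_up;
                }
            }
            // pairwise links
            for (size_t i = 0; i + 1 < visits.size(); ++i) {
                const Visit &a = visits[i], &b = visits[i + 1];
                if (a.u == b.u) continue;
                int64_t ea = 2LL * a.u + (a.rel > 0 ? 1 : 0); // exit end
                int64_t eb = 2LL * b.u + (b.rel > 0 ? 0 : 1); // entry end
                double gap = b.est_start - a.est_end;
                // adjacent unitigs overlap by up to k-1 bases, so a real
                // junction's gap estimate is negative; a positive gap means
                // sequence (a skipped unitig) would be missing
                if (gap > 200) continue;
                LinkInfo &L = links[end_pair_key(ea, eb)];
                ++L.count;
                L.gap_sum += gap;
            }
            // triple spans (repeat resolution)
            for (size_t i = 0; i + 2 < visits.size(); ++i) {
                const Visit &a = visits[i], &m = visits[i + 1], &b = visits[i + 2];
                if (a.u == m.u || m.u == b.u) continue;
                int64_t ea = 2LL * a.u + (a.rel > 0 ? 1 : 0);
                int64_t eb = 2LL * b.u + (b.rel > 0 ? 0 : 1);
                double g1 = m.est_start - a.est_end;
                double g2 = b.est_start - m.est_end;
                if (g1 > 200 || g2 > 200) continue;
                int orient = m.rel;
                double gg1 = g1, gg2 = g2;
                if (ea > eb) { // canonicalise: orientation seen from min end
                    std::swap(ea, eb);
                    orient = -orient;
                    std::swap(gg1, gg2);
                }
                TripleInfo &T = triples[end_pair_key(ea, eb)][{m.u, orient}];
                ++T.count;
                T.g1_sum += gg1;
                T.g2_sum += gg2;
            }
        }

        // partner sets per end
        std::unordered_map<int64_t, std::vector<std::pair<int64_t, const LinkInfo *>>> partners;
        std::vector<std::pair<uint64_t, const LinkInfo *>> link_list;
        auto build_partners = [&]() {
            partners.clear();
            link_list.clear();
            for (auto &kv : links) {
                if (kv.second.count < bridge_min_links) continue;
                int64_t e1 = (int64_t)(kv.first >> 32);
                int64_t e2 = (int64_t)(kv.first & 0xffffffffULL);
                partners[e1].push_back({e2, &kv.second});
                if (e2 != e1) partners[e2].push_back({e1, &kv.second});
                link_list.push_back({kv.first, &kv.second});
            }
        };
        build_partners();
        // transitive reduction: drop a link E-F when some unitig X links
        // E to F through both its ends (reads that skipped X's anchors)
        {
            std::vector<uint64_t> drop;
            for (auto &lk : link_list) {
                int64_t e1 = (int64_t)(lk.first >> 32);
                int64_t e2 = (int64_t)(lk.first & 0xffffffffULL);
                bool red = false;
                for (auto &p : partners[e1]) {
                    int64_t entry = p.first;
                    if (entry == e2 || (entry >> 1) == (e1 >> 1)) continue;
                    int64_t exit = entry ^ 1;
                    if (links.count(end_pair_key(exit, e2))) { red = true; break; }
                }
                if (red) drop.push_back(lk.first);
            }
            for (uint64_t k2 : drop) links.erase(k2);
            if (!drop.empty()) build_partners();
        }
        joins.assign(2 * nu, Join());
        std::vector<bool> consumed(2 * nu, false);
        std::sort(link_list.begin(), link_list.end(),
                  [](const std::pair<uint64_t, const LinkInfo *> &a,
                     const std::pair<uint64_t, const LinkInfo *> &b) {
                      return a.first < b.first;
                  });
        struct TripCand {
            int count; int64_t e1, e2; int via; int orient; double g1, g2;
        };
        std::vector<TripCand> cands;
        for (auto &kv : triples)
            for (auto &mkv : kv.second) {
                if (mkv.second.count < bridge_min_links) continue;
                TripCand t;
                t.count = mkv.second.count;
                t.e1 = (int64_t)(kv.first >> 32);
                t.e2 = (int64_t)(kv.first & 0xffffffffULL);
                t.via = mkv.first.first;
                t.orient = mkv.first.second;
                t.g1 = mkv.second.g1_sum / mkv.second.count;
                t.g2 = mkv.second.g2_sum / mkv.second.count;
                cands.push_back(t);
            }
        std::sort(cands.begin(), cands.end(), [](const TripCand &a, const TripCand &b) {
            if (a.count != b.count) return a.count > b.count;
            if (a.e1 != b.e1) return a.e1 < b.e1;
            if (a.e2 != b.e2) return a.e2 < b.e2;
            return a.via < b.via;
        });
        // resolve junctions to a fixpoint: joins whose both ends have a
        // single unconsumed partner are applied first; remaining
        // (repeat-flanked) junctions are resolved by read-level triple
        // spans, which may unlock further unique joins, and so on
        auto sole_unconsumed = [&](int64_t e) -> int64_t {
            int64_t sole = -1;
            int n = 0;
            for (auto &p : partners[e])
                if (!consumed[p.first]) { ++n; sole = p.first; }
            return n == 1 ? sole : -1;
        };
        // one sweep applies unambiguous joins and justified via
        // insertions; the outer loop adds a weight-majority fallback for
        // ends left ambiguous by junctions of genomes too poorly covered
        // to resolve their own side
        bool changed = true;
        bool outer = true;
        while (outer) {
        while (changed) {
            changed = false;
            for (auto &lk : link_list) {
                int64_t e1 = (int64_t)(lk.first >> 32);
                int64_t e2 = (int64_t)(lk.first & 0xffffffffULL);
                if (consumed[e1] || consumed[e2]) continue;
                if (sole_unconsumed(e1) != e2 || sole_unconsumed(e2) != e1)
                    continue;
                double gap = lk.second->gap_sum / lk.second->count;
                // adjacent unitigs overlap by up to k-1 bases, so a real
                // junction's mean gap estimate is negative but bounded
                if (gap > 10 || gap < -(double)(k + 30)) continue;
                joins[e1].present = true; joins[e1].to = e2; joins[e1].gap1 = gap;
                joins[e2].present = true; joins[e2].to = e1; joins[e2].gap1 = gap;
                consumed[e1] = consumed[e2] = true;
                changed = true;
                if (std::getenv("IHAMAG_DEBUG_JOINS"))
                    Rcpp::Rcout << "JOIN simple " << (e1 >> 1)
                                << ((e1 & 1) ? "R" : "L") << " (len "
                                << units[e1 >> 1].seq.size() << ") -- "
                                << (e2 >> 1) << ((e2 & 1) ? "R" : "L")
                                << " (len " << units[e2 >> 1].seq.size()
                                << ") gap " << gap << " n=" << lk.second->count << "\n";
            }
            auto end_pending_unique = [&](int64_t e) {
                return !consumed[e] && sole_unconsumed(e) >= 0;
            };
            for (auto &t : cands) {
                if (consumed[t.e1] || consumed[t.e2]) continue;
                if (t.via == (int)(t.e1 >> 1) || t.via == (int)(t.e2 >> 1))
                    continue;
                if (t.g1 > 10 || t.g2 > 10) continue;
                if (t.g1 < -(double)(k + 30) || t.g2 < -(double)(k + 30))
                    continue;
                // inserting a via duplicates its sequence, which is only
                // justified for a collapsed multi-copy element; such a
                // unitig shows multiple link partners on at least one of
                // its own ends, while a unique segment links only to its
                // two true neighbours
                if (partners[2LL * t.via].size() < 2 &&
                    partners[2LL * t.via + 1].size() < 2) continue;
                joins[t.e1].present = true; joins[t.e1].to = t.e2;
                joins[t.e1].via = true; joins[t.e1].via_u = t.via;
                joins[t.e1].via_orient = t.orient;
                joins[t.e1].gap1 = t.g1; joins[t.e1].gap2 = t.g2;
                joins[t.e2].present = true; joins[t.e2].to = t.e1;
                joins[t.e2].via = true; joins[t.e2].via_u = t.via;
                joins[t.e2].via_orient = -t.orient;
                joins[t.e2].gap1 = t.g2; joins[t.e2].gap2 = t.g1;
                consumed[t.e1] = consumed[t.e2] = true;
                changed = true;
                if (std::getenv("IHAMAG_DEBUG_JOINS"))
                    Rcpp::Rcout << "JOIN via " << (t.e1 >> 1)
                                << ((t.e1 & 1) ? "R" : "L") << " (len "
                                << units[t.e1 >> 1].seq.size() << ") -["
                                << t.via << " len "
                                << units[t.via].seq.size() << "]- "
                                << (t.e2 >> 1) << ((t.e2 & 1) ? "R" : "L")
                                << " (len " << units[t.e2 >> 1].seq.size()
                                << ") n=" << t.count << "\n";
            }
        }

        // weight-majority fallback: an unresolved candidate may be applied
        // when its read support dominates every competing candidate at
        // both of its ends (factor 3); one application per round, then the
        // unambiguous sweep runs again
        {
            struct FallCand { int count; int64_t e1, e2; int via; int orient;
                              double g1, g2; bool is_via; uint64_t key; };
            std::vector<FallCand> fc;
            for (auto &lk : link_list) {
                int64_t e1 = (int64_t)(lk.first >> 32);
                int64_t e2 = (int64_t)(lk.first & 0xffffffffULL);
                if (consumed[e1] || consumed[e2]) continue;
                double gap = lk.second->gap_sum / lk.second->count;
                if (gap > 10 || gap < -(double)(k + 30)) continue;
                fc.push_back({lk.second->count, e1, e2, -1, 0, gap, 0,
                              false, lk.first});
            }
            for (auto &t : cands) {
                if (consumed[t.e1] || consumed[t.e2]) continue;
                if (t.via == (int)(t.e1 >> 1) || t.via == (int)(t.e2 >> 1))
                    continue;
                if (t.g1 > 10 || t.g2 > 10) continue;
                if (t.g1 < -(double)(k + 30) || t.g2 < -(double)(k + 30))
                    continue;
                if (partners[2LL * t.via].size() < 2 &&
                    partners[2LL * t.via + 1].size() < 2) continue;
                fc.push_back({t.count, t.e1, t.e2, t.via, t.orient,
                              t.g1, t.g2, true, 0});
            }
            // per-end best and second-best counts
            std::unordered_map<int64_t, std::pair<int, int>> top2;
            auto feed = [&](int64_t e, int n) {
                auto &p = top2[e];
                if (n > p.first) { p.second = p.first; p.first = n; }
                else if (n > p.second) p.second = n;
            };
            for (auto &c : fc) { feed(c.e1, c.count); feed(c.e2, c.count); }
            std::sort(fc.begin(), fc.end(), [](const FallCand &a, const FallCand &b) {
                if (a.count != b.count) return a.count > b.count;
                if (a.e1 != b.e1) return a.e1 < b.e1;
                return a.e2 < b.e2;
            });
            bool applied = false;
            for (auto &c : fc) {
                auto d1 = top2[c.e1], d2 = top2[c.e2];
                bool dom1 = (d1.first == c.count) &&
                    (d1.second == 0 || c.count >= 2 * d1.second);
                bool dom2 = (d2.first == c.count) &&
                    (d2.second == 0 || c.count >= 2 * d2.second);
                if (!dom1 || !dom2) continue;
                if (!c.is_via) {
                    joins[c.e1].present = true; joins[c.e1].to = c.e2;
                    joins[c.e1].gap1 = c.g1;
                    joins[c.e2].present = true; joins[c.e2].to = c.e1;
                    joins[c.e2].gap1 = c.g1;
                } else {
                    joins[c.e1].present = true; joins[c.e1].to = c.e2;
                    joins[c.e1].via = true; joins[c.e1].via_u = c.via;
                    joins[c.e1].via_orient = c.orient;
                    joins[c.e1].gap1 = c.g1; joins[c.e1].gap2 = c.g2;
                    joins[c.e2].present = true; joins[c.e2].to = c.e1;
                    joins[c.e2].via = true; joins[c.e2].via_u = c.via;
                    joins[c.e2].via_orient = -c.orient;
                    joins[c.e2].gap1 = c.g2; joins[c.e2].gap2 = c.g1;
                }
                consumed[c.e1] = consumed[c.e2] = true;
                applied = true;
                if (std::getenv("IHAMAG_DEBUG_JOINS"))
                    Rcpp::Rcout << "JOIN fallback " << (c.e1 >> 1)
                                << ((c.e1 & 1) ? "R" : "L") << " -- "
                                << (c.e2 >> 1) << ((c.e2 & 1) ? "R" : "L")
                                << " via=" << c.via << " n=" << c.count << "\n";
                break;
            }
            if (applied) changed = true;
            else outer = false;
        }
        }
    }

    // ---- path traversal and sequence emission ----
    std::vector<bool> used(nu, false);
    std::vector<int> inserted(nu, 0);
    std::vector<int> order(nu);
    for (int i = 0; i < nu; ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
        if (units[a].seq.size() != units[b].seq.size())
            return units[a].seq.size() > units[b].seq.size();
        return a < b;
    });

    struct Elem { int u; int orient; double gap_before; bool is_via; };

    std::vector<std::vector<Elem>> paths;
    std::vector<bool> path_circ;

    for (int seed : order) {
        if (units[seed].circ || used[seed]) continue;
        used[seed] = true;
        std::vector<Elem> path;
        path.push_back({seed, +1, 0, false});
        bool circ = false;
        // walk right, then (if not circular) flip and walk right again
        for (int phase = 0; phase < 2 && !circ; ++phase) {
            if (phase == 1) {
                std::reverse(path.begin(), path.end());
                for (size_t i = 0; i < path.size(); ++i) path[i].orient = -path[i].orient;
                // a junction's gap now belongs to the element after it
                for (size_t j = path.size(); j-- > 1;)
                    path[j].gap_before = path[j - 1].gap_before;
                path[0].gap_before = 0;
            }
            while (!joins.empty()) {
                Elem &tail = path.back();
                int64_t e = 2LL * tail.u + (tail.orient > 0 ? 1 : 0);
                if (!joins[(size_t)e].present) break;
                const Join &J = joins[(size_t)e];
                int vu = (int)(J.to >> 1);
                int vside = (int)(J.to & 1); // entry side: 0 left -> forward
                int vorient = (vside == 0) ? +1 : -1;
                int start_u = path.front().u;
                int64_t start_in_end = 2LL * start_u + (path.front().orient > 0 ? 0 : 1);
                if (vu == start_u && J.to == start_in_end && path.size() > 1) {
                    if (J.via) path.push_back({J.via_u, J.via_orient, J.gap1, true});
                    circ = true;
                    break;
                }
                if (used[vu]) break;
                if (J.via)
                    path.push_back({J.via_u, J.via_orient, J.gap1, true});
                path.push_back({vu, vorient, J.via ? J.gap2 : J.gap1, false});
                used[vu] = true;
            }
        }
        for (auto &el : path) if (el.is_via) inserted[el.u]++;
        if (std::getenv("IHAMAG_DEBUG_JOINS")) {
            Rcpp::Rcout << "PATH" << (circ ? " circ:" : ":");
            for (auto &el : path)
                Rcpp::Rcout << " " << (el.is_via ? "v" : "") << el.u
                            << (el.orient > 0 ? "+" : "-");
            Rcpp::Rcout << "\n";
        }
        paths.push_back(std::move(path));
        path_circ.push_back(circ);
    }

    // emit sequences, splitting where an overlap cannot be verified
    for (size_t pi = 0; pi < paths.size(); ++pi) {
        const std::vector<Elem> &path = paths[pi];
        bool circ = path_circ[pi];
        if (path.size() == 1 && !circ && inserted[path[0].u] > 0 &&
            !joins.empty()) {
            // repeat copy already placed inside another contig
            continue;
        }
        std::string seq;
        bool first = true;
        // per-piece element (depth, length) records; contig depth is the
        // length-weighted median, robust to collapsed-repeat inserts
        std::vector<std::pair<double, double>> elems;
        std::vector<std::pair<std::string, std::vector<std::pair<double, double>>>> pieces;
        for (const Elem &el : path) {
            std::string s = (el.orient > 0) ? units[el.u].seq
                                            : revcomp_str(units[el.u].seq);
            if (first) {
                seq = s;
                elems.clear();
                elems.push_back({units[el.u].depth, (double)s.size()});
                first = false;
                continue;
            }
            int ov = best_overlap(seq, s, el.gap_before, k);
            if (ov == 0 && std::getenv("IHAMAG_DEBUG_OVERLAP")) {
                int mo = std::min((int)std::min(seq.size(), s.size()), k + 20);
                int bo = 0;
                for (int o = 1; o <= mo; ++o)
                    if (seq.compare(seq.size() - o, o, s, 0, o) == 0) bo = o;
                Rcpp::Rcout << "overlap fail: gap_est=" << el.gap_before
                            << " via=" << el.is_via
                            << " best_any=" << bo
                            << " tail=" << seq.substr(seq.size() - 35)
                            << " head=" << s.substr(0, 35) << "\n";
            }
            if (ov == 0) {
                pieces.push_back({seq, elems});
                seq = s;
                elems.clear();
                elems.push_back({units[el.u].depth, (double)s.size()});
                circ = false; // a break voids circular closure
                continue;
            }
            seq += s.substr(ov);
            elems.push_back({units[el.u].depth, (double)(s.size() - ov)});
        }
        if (circ && seq.size() > (size_t)(k + 5)) {
            // close the circle: trim terminal overlap against the head
            int ov = best_overlap(seq, seq.substr(0, k + 20), -(double)(k - 1), k);
            if (ov > 0) seq.resize(seq.size() - ov);
            else circ = false;
        }
        pieces.push_back({seq, elems});
        auto wmedian = [](std::vector<std::pair<double, double>> v) {
            if (v.empty()) return 0.0;
            std::sort(v.begin(), v.end());
            double tot = 0;
            for (auto &p : v) tot += p.second;
            double acc = 0;
            for (auto &p : v) {
                acc += p.second;
                if (acc >= tot / 2) return p.first;
            }
            return v.back().first;
        };
        for (size_t i = 0; i < pieces.size(); ++i) {
            bool this_circ = circ && pieces.size() == 1;
            std::string &ps = pieces[i].first;
            if (!this_circ && ps.size() > (size_t)(2 * k) &&
                ps.compare(0, k - 1, ps, ps.size() - (k - 1), k - 1) == 0) {
                // terminal (k-1)-mers coincide: circular by sequence
                ps.resize(ps.size() - (k - 1));
                this_circ = true;
            }
            contig_seqs.push_back(ps);
            contig_circ.push_back(this_circ);
            contig_depth.push_back(wmedian(pieces[i].second));
        }
    }
    // circular unitigs are finished replicons
    for (int u = 0; u < nu; ++u) {
        if (!units[u].circ) continue;
        std::string s = units[u].seq;
        if ((int)s.size() > k - 1) s.resize(s.size() - (k - 1));
        contig_seqs.push_back(s);
        contig_circ.push_back(true);
        contig_depth.push_back(units[u].depth);
    }

    // length filter + deterministic output order
    std::vector<int> keep;
    for (size_t i = 0; i < contig_seqs.size(); ++i)
        if ((int)contig_seqs[i].size() >= min_contig_len) keep.push_back((int)i);
    std::sort(keep.begin(), keep.end(), [&](int a, int b) {
        if (contig_seqs[a].size() != contig_seqs[b].size())
            return contig_seqs[a].size() > contig_seqs[b].size();
        return contig_seqs[a] < contig_seqs[b];
    });
    CharacterVector out_seq(keep.size());
    LogicalVector out_circ(keep.size());
    NumericVector out_depth(keep.size());
    for (size_t i = 0; i < keep.size(); ++i) {
        out_seq[i] = contig_seqs[keep[i]];
        out_circ[i] = contig_circ[keep[i]];
        out_depth[i] = contig_depth[keep[i]];
    }
    return List::create(_["seq"] = out_seq, _["circular"] = out_circ,
                        _["depth"] = out_depth);
}
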