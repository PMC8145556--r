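#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <set>
#include "kmer_common.h"

using namespace Rcpp;

// Bottom-s MinHash sketch over the distinct canonical k-mers of a sequence set.
// Returned as sorted doubles of the top 53 bits of the splitmix64 hash, so the
// values survive R's numeric type exactly.
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector seqs, int k, int s) {
  std::set<uint64_t> bottom;  // ordered; largest element is cheap to find
  for (int i = 0; i < seqs.size(); ++i) {
    std::string sq = as<std::string>(seqs[i]);
    for_each_kmer(sq, k, [&](long, uint64_t, uint64_t canon) {
      uint64_t h = splitmix64(canon) >> 11;
      if ((int)bottom.size() < s) {
        bottom.insert(h);
      } else if (h < *bottom.rbegin()) {
        bottom.insert(h);
        if ((int)bottom.size() > s) bottom.erase(std::prev(bottom.end()));
      }
    });
  }
  NumericVector out(bottom.size());
  int j = 0;
  for (uint64_t h : bottom) out[j++] = (double)h;
  return out;
}

// LCA-collapsed k-mer index. Genomes carry 0-based species codes; species map to
// 0-based genus codes. Node coding in the output: [0, S) species, [S, S+G) genus.
// K-mers shared across genera are uninformative and dropped. k <= 26 so the packed
// canonical k-mer fits a double exactly.
// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, IntegerVector species,
                     IntegerVector genus_of_species, int k) {
  int S = genus_of_species.size();
  std::unordered_map<uint64_t, int> node;
  node.reserve(1 << 20);
  for (int i = 0; i < seqs.size(); ++i) {
    int sp = species[i];
    int ge = genus_of_species[sp];
    std::string sq = as<std::string>(seqs[i]);
    for_each_kmer(sq, k, [&](long, uint64_t, uint64_t canon) {
      auto it = node.find(canon);
      if (it == node.end()) {
        node[canon] = sp;
      } else {
        int cur = it->second;
        if (cur == -1 || cur == sp) return;
        int cur_ge = (cur < S) ? genus_of_species[cur] : (cur - S);
        if (cur_ge == ge) it->second = S + ge;   // same genus, different species
        else it->second = -1;                    // cross-genus: uninformative
      }
    });
  }
  size_t n = 0;
  for (auto& kv : node) if (kv.second >= 0) ++n;
  std::vector<std::pair<uint64_t, int>> recs;
  recs.reserve(n);
  for (auto& kv : node) if (kv.second >= 0) recs.push_back(kv);
  std::sort(recs.begin(), recs.end());
  NumericVector keys(n);
  IntegerVector nd(n);
  for (size_t i = 0; i < n; ++i) {
    keys[i] = (double)recs[i].first;
    nd[i] = recs[i].second;
  }
  return List::create(_["key"] = keys, _["node"] = nd);
}

// Classify sequence units (reads or contigs) against a built index by k-mer vote.
// Returns an n x 3 integer matrix: species code (-1 if unresolved at species rank),
// genus code (-1 if unresolved), and total informative k-mer hits.
// [[Rcpp::export]]
IntegerMatrix cpp_classify(CharacterVector units, NumericVector key,
                           IntegerVector node, IntegerVector genus_of_species,
                           int n_genus, int k) {
  int S = genus_of_species.size();
  int n = units.size();
  IntegerMatrix out(n, 3);
  const double* kp = REAL(key);
  int nk = key.size();
  std::vector<int> sp_hits(S), ge_hits(n_genus);
  for (int u = 0; u < n; ++u) {
    std::fill(sp_hits.begin(), sp_hits.end(), 0);
    std::fill(ge_hits.begin(), ge_hits.end(), 0);
    int tot = 0;
    std::string sq = as<std::string>(units[u]);
    for_each_kmer(sq, k, [&](long, uint64_t, uint64_t canon) {
      double v = (double)canon;
      const double* lo = std::lower_bound(kp, kp + nk, v);
      if (lo != kp + nk && *lo == v) {
        int nd = node[lo - kp];
        ++tot;
        if (nd < S) { ++sp_hits[nd]; ++ge_hits[genus_of_species[nd]]; }
        else        { ++ge_hits[nd - S]; }
      }
    });
    int best_sp = -1, best_sp_n = 0, ties_sp = 0;
    for (int s = 0; s < S; ++s) {
      if (sp_hits[s] > best_sp_n) { best_sp_n = sp_hits[s]; best_sp = s; ties_sp = 1; }
      else if (sp_hits[s] == best_sp_n && sp_hits[s] > 0) ++ties_sp;
    }
    int best_ge = -1, best_ge_n = 0, ties_ge = 0;
    for (int g = 0; g < n_genus; ++g) {
      if (ge_hits[g] > best_ge_n) { best_ge_n = ge_hits[g]; best_ge = g; ties_ge = 1; }
      else if (ge_hits[g] == best_ge_n && ge_hits[g] > 0) ++ties_ge;
    }
    // Ties collapse to the deepest common ancestor: tied species resolve at
    // species rank to nothing (the unit still votes at genus rank through the
    // genus tally); tied genera resolve to root (unclassified at genus rank).
    int sp_out = (best_sp >= 0 && ties_sp == 1) ? best_sp : -1;
    int ge_out = (best_ge >= 0 && ties_ge == 1) ? best_ge : -1;
    out(u, 0) = sp_out;
    out(u, 1) = ge_out;
    out(u, 2) = tot;
  }
  return out;
}

// Ungapped placements of each query in one subject sequence via shared-k-mer
// offset voting, both strands. A placement requires the full query inside the
// subject and at least min_support anchoring k-mers; identity is the fraction of
// matching bases at that offset. Used for core-scheme building and the
// core-gene (completeness/duplication) assessment.
// [[Rcpp::export]]
DataFrame cpp_locate(CharacterVector queries, std::string subject, int k,
                     int min_support) {
  // fwd-packed k-mer -> subject positions (capped: highly repetitive k-mers
  // stop anchoring but the flanks of a repeat still vote)
  const size_t max_pos = 8;
  std::unordered_map<uint64_t, std::vector<long>> pos1;
  pos1.reserve(subject.size() * 2);
  for_each_kmer(subject, k, [&](long p, uint64_t fwd, uint64_t) {
    auto& v = pos1[fwd];
    if (v.size() < max_pos) v.push_back(p);
  });
  std::vector<int> q_idx, strand_v;
  std::vector<double> off_v, ident_v, supp_v;
  long slen = (long)subject.size();
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    long qlen = (long)q.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::string qs = strand == 0 ? q : revcomp(q);
      std::unordered_map<long, int> votes;
      for_each_kmer(qs, k, [&](long qp, uint64_t fwd, uint64_t) {
        auto it = pos1.find(fwd);
        if (it == pos1.end() || it->second.size() >= max_pos) return;
        for (long p : it->second) {
          long off = p - qp;
          if (off >= 0 && off + qlen <= slen) ++votes[off];
        }
      });
      for (auto& kv : votes) {
        if (kv.second < min_support) continue;
        long off = kv.first;
        long match = 0;
        for (long i = 0; i < qlen; ++i)
          if (subject[off + i] == qs[i]) ++match;
        q_idx.push_back(qi + 1);
        off_v.push_back((double)off);
        strand_v.push_back(strand == 0 ? 1 : -1);
        ident_v.push_back((double)match / (double)qlen);
        supp_v.push_back((double)kv.second);
      }
    }
  }
  return DataFrame::create(_["query"] = q_idx, _["offset"] = off_v,
                           _["strand"] = strand_v, _["identity"] = ident_v,
                           _["support"] = supp_v);
}
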