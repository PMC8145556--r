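#include <Rcpp.h>
#include <unordered_map>
#include "kmer_common.h"

using namespace Rcpp;

// Exact unique-k-mer anchoring of contigs onto a reference: maximal runs of
// consecutive matches to reference-unique k-mers are merged into blocks and
// reported in 0-based half-open reference coordinates. Both contig strands are
// scanned. Blocks shorter than min_block are discarded.
// [[Rcpp::export]]
DataFrame cpp_anchor_map(CharacterVector contigs, std::string reference, int k,
                         int min_block) {
  std::unordered_map<uint64_t, long> upos;  // fwd k-mer -> position, -2 ambiguous
  upos.reserve(reference.size() * 2);
  for_each_kmer(reference, k, [&](long p, uint64_t fwd, uint64_t) {
    auto it = upos.find(fwd);
    if (it == upos.end()) upos[fwd] = p; else it->second = -2;
  });
  std::vector<int> contig_v;
  std::vector<double> start_v, end_v;
  for (int ci = 0; ci < contigs.size(); ++ci) {
    std::string c0 = as<std::string>(contigs[ci]);
    for (int strand = 0; strand < 2; ++strand) {
      std::string c = strand == 0 ? c0 : revcomp(c0);
      long run_start = -1, prev = -10;
      auto flush = [&](long last) {
        if (run_start >= 0) {
          long bs = run_start, be = last + k;  // half-open
          if (be - bs >= min_block) {
            contig_v.push_back(ci + 1);
            start_v.push_back((double)bs);
            end_v.push_back((double)be);
          }
        }
        run_start = -1;
      };
      for_each_kmer(c, k, [&](long, uint64_t fwd, uint64_t) {
        auto it = upos.find(fwd);
        long p = (it != upos.end() && it->second >= 0) ? it->second : -1;
        if (p >= 0 && p == prev + 1) {
          prev = p;
        } else {
          flush(prev);
          if (p >= 0) { run_start = p; prev = p; } else prev = -10;
        }
      });
      flush(prev);
    }
  }
  return DataFrame::create(_["contig"] = contig_v, _["ref_start"] = start_v,
                           _["ref_end"] = end_v);
}

// Assign each read to the scheme locus it shares the most canonical k-mers
// with (0 = unassigned). K-mers occurring in more than one locus are ignored.
// [[Rcpp::export]]
IntegerVector cpp_bait(CharacterVector reads, CharacterVector loci, int k) {
  std::unordered_map<uint64_t, int> owner;  // canonical k-mer -> locus (1-based), -1 shared
  for (int li = 0; li < loci.size(); ++li) {
    std::string lseq = as<std::string>(loci[li]);
    for_each_kmer(lseq, k, [&](long, uint64_t, uint64_t canon) {
      auto it = owner.find(canon);
      if (it == owner.end()) owner[canon] = li + 1;
      else if (it->second != li + 1) it->second = -1;
    });
  }
  int n = reads.size();
  IntegerVector out(n);
  std::unordered_map<int, int> votes;
  for (int r = 0; r < n; ++r) {
    votes.clear();
    std::string rs = as<std::string>(reads[r]);
    for_each_kmer(rs, k, [&](long, uint64_t, uint64_t canon) {
      auto it = owner.find(canon);
      if (it != owner.end() && it->second > 0) ++votes[it->second];
    });
    int best = 0, best_n = 0;
    for (auto& kv : votes)
      if (kv.second > best_n || (kv.second == best_n && kv.first < best)) {
        best = kv.first; best_n = kv.second;
      }
    out[r] = best_n > 0 ? best : 0;
  }
  return out;
}

// Ungapped pileup of baited reads on one locus sequence. Each read is placed at
// the offset (and orientation) supported by the most exact k-mer anchors; reads
// without an anchor, and bases below min_bq or falling outside the locus, are
// dropped. Returns a 4 x L count matrix (rows A, C, G, T).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector reads, CharacterVector quals,
                         std::string locus, int k, int min_bq) {
  std::unordered_map<uint64_t, long> lpos;
  for_each_kmer(locus, k, [&](long p, uint64_t fwd, uint64_t) {
    auto it = lpos.find(fwd);
    if (it == lpos.end()) lpos[fwd] = p; else it->second = -2;
  });
  long L = (long)locus.size();
  IntegerMatrix counts(4, L);
  char qcut = (char)(33 + min_bq);
  bool have_quals = quals.size() == reads.size();
  std::unordered_map<long, int> votes;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rs = as<std::string>(reads[r]);
    std::string qs = have_quals ? as<std::string>(quals[r]) : std::string();
    long best_off = 0; int best_n = 0, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string rr = strand == 0 ? rs : revcomp(rs);
      votes.clear();
      for_each_kmer(rr, k, [&](long qp, uint64_t fwd, uint64_t) {
        auto it = lpos.find(fwd);
        if (it != lpos.end() && it->second >= 0) ++votes[it->second - qp];
      });
      for (auto& kv : votes)
        if (kv.second > best_n) { best_n = kv.second; best_off = kv.first; best_strand = strand; }
    }
    if (best_n == 0) continue;
    std::string rr = best_strand == 0 ? rs : revcomp(rs);
    std::string qq = qs;
    if (best_strand == 1 && have_quals) std::reverse(qq.begin(), qq.end());
    for (long i = 0; i < (long)rr.size(); ++i) {
      long p = best_off + i;
      if (p < 0 || p >= L) continue;
      if (have_quals && qq[i] < qcut) continue;
      int b = base_code(rr[i]);
      if (b >= 0) ++counts(b, p);
    }
  }
  return counts;
}
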