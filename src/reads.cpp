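#include <Rcpp.h>
#include "kmer_common.h"

using namespace Rcpp;

// Substitution-error short-read simulator. Sources (chromosome, plasmids) are
// sampled proportionally to `weights`; start positions and strand are uniform.
// Per-base quality is a two-point mixture (q_hi with prob 1 - p_lo, else q_lo)
// and substitution errors are drawn conditional on the base's own quality
// (error prob = 10^(-q/10)), so qualities are consistent with the realised
// error rate. Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export]]
List cpp_simulate_reads(CharacterVector seqs, NumericVector weights, int n_reads,
                        int read_len, double p_lo, int q_hi, int q_lo) {
  int ns = seqs.size();
  std::vector<std::string> src(ns);
  for (int i = 0; i < ns; ++i) src[i] = as<std::string>(seqs[i]);
  std::vector<double> cum(ns);
  double tot = 0;
  for (int i = 0; i < ns; ++i) { tot += weights[i]; cum[i] = tot; }
  // p_lo < 0 signals an error-free simulation (exact substrings, q_hi quality)
  double e_hi = std::pow(10.0, -q_hi / 10.0);
  double e_lo = std::pow(10.0, -q_lo / 10.0);
  if (p_lo < 0) { p_lo = 0.0; e_hi = 0.0; e_lo = 0.0; }
  CharacterVector rseq(n_reads), rqual(n_reads);
  IntegerVector rsrc(n_reads), rpos(n_reads), rstrand(n_reads);
  std::string buf(read_len, 'N'), qbuf(read_len, '!');
  for (int r = 0; r < n_reads; ++r) {
    double u = unif_rand() * tot;
    int s = 0;
    while (s < ns - 1 && u > cum[s]) ++s;
    long L = (long)src[s].size();
    long maxstart = L - read_len;
    if (maxstart < 0) maxstart = 0;
    long start = (long)(unif_rand() * (maxstart + 1));
    if (start > maxstart) start = maxstart;
    bool minus = unif_rand() < 0.5;
    std::string frag = src[s].substr(start, read_len);
    if (minus) frag = revcomp(frag);
    for (int i = 0; i < read_len && i < (int)frag.size(); ++i) {
      bool lo = unif_rand() < p_lo;
      int q = lo ? q_lo : q_hi;
      double e = lo ? e_lo : e_hi;
      char b = frag[i];
      if (e > 0 && base_code(b) >= 0 && unif_rand() < e) {
        int nb = (base_code(b) + 1 + (int)(unif_rand() * 3)) & 3;
        b = code_base(nb);
      }
      buf[i] = b;
      qbuf[i] = (char)(33 + q);
    }
    rseq[r] = buf;
    rqual[r] = qbuf;
    rsrc[r] = s + 1;
    rpos[r] = (int)start;
    rstrand[r] = minus ? -1 : 1;
  }
  return List::create(_["seq"] = rseq, _["qual"] = rqual, _["src"] = rsrc,
                      _["pos"] = rpos, _["strand"] = rstrand);
}

// Count bases at or above a Phred threshold across Phred+33 quality strings.
// [[Rcpp::export]]
NumericVector cpp_qual_counts(CharacterVector quals, int thresh) {
  double above = 0, total = 0;
  char cut = (char)(33 + thresh);
  for (int i = 0; i < quals.size(); ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    for (; *q; ++q) { ++total; if (*q >= cut) ++above; }
  }
  return NumericVector::create(above, total);
}

// G+C and unambiguous-base counts over a set of sequences (N excluded).
// [[Rcpp::export]]
NumericVector cpp_gc_counts(CharacterVector seqs) {
  double gc = 0, acgt = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for (; *s; ++s) {
      switch (*s) {
        case 'G': case 'C': case 'g': case 'c': ++gc; ++acgt; break;
        case 'A': case 'T': case 'a': case 't': ++acgt; break;
        default: break;
      }
    }
  }
  return NumericVector::create(gc, acgt);
}
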