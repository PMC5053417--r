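#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Ungapped mismatch count of each read placed at starts[i] (1-based) on the
// target sequence. Returns -1 where the placement runs off either end.
// [[Rcpp::export(name = ".mismatch_count_at")]]
IntegerVector mismatch_count_at(std::string target, CharacterVector reads,
                                IntegerVector starts) {
  const int n = reads.size();
  const long tlen = (long)target.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const long rlen = (long)LENGTH(STRING_ELT(reads, i));
    const long s = (long)starts[i] - 1L;
    if (s < 0 || s + rlen > tlen) { out[i] = -1; continue; }
    int mm = 0;
    const char *t = target.data() + s;
    for (long j = 0; j < rlen; ++j) if (r[j] != t[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Banded semi-global alignment of each read against a window of the target
// centred on a candidate diagonal. The read is aligned end to end; the
// window start is free. Linear gap penalty. Returns per read:
//   matches, columns (aligned length incl. gaps), ref_start, ref_end (1-based,
//   half-open converted by caller), score. ref_start = -1 when the window is
//   out of range.
// [[Rcpp::export(name = ".banded_align_batch")]]
NumericMatrix banded_align_batch(std::string target, CharacterVector reads,
                                 IntegerVector starts, int band,
                                 double match, double mismatch, double gap) {
  const int n = reads.size();
  const long tlen = (long)target.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("matches", "columns", "ref_start",
                                          "ref_end", "score");
  const double NEG = -1e18;
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int rlen = LENGTH(STRING_ELT(reads, i));
    long w0 = (long)starts[i] - 1L - band;          // window start, 0-based
    long w1 = (long)starts[i] - 1L + rlen + band;   // window end, exclusive
    if (w0 < 0) w0 = 0;
    if (w1 > tlen) w1 = tlen;
    const int wlen = (int)(w1 - w0);
    if (wlen < rlen - band || wlen <= 0) { out(i, 2) = -1; continue; }
    const int W = 2 * band + 1;
    // dp[row][d]: best score aligning read[0..row) ending at window column
    // col = row + (d - band) + off, with off = (long)(starts[i]-1-w0) - band
    // folded in: col(row, d) = row + d + off0 where off0 = starts[i]-1-w0-band
    const long off0 = (long)starts[i] - 1L - w0 - band;
    std::vector<double> prev(W, NEG), cur(W, NEG);
    std::vector<signed char> bt((size_t)(rlen + 1) * W, 0); // 0 diag,1 up(gap in ref),2 left(gap in read),3 start
    // row 0: free start anywhere on the valid diagonal range
    for (int d = 0; d < W; ++d) {
      long col = 0 + d + off0;
      if (col >= 0 && col <= wlen) { prev[d] = 0.0; bt[d] = 3; }
    }
    for (int row = 1; row <= rlen; ++row) {
      const char rc = r[row - 1];
      for (int d = 0; d < W; ++d) cur[d] = NEG;
      for (int d = 0; d < W; ++d) {
        long col = row + d + off0;
        if (col < 1 || col > wlen) continue;
        // diagonal: from (row-1, col-1) -> same d
        double best = NEG; signed char dir = 0;
        if (prev[d] > 0.5 * NEG) {
          double sub = (rc == target[w0 + col - 1]) ? match : mismatch;
          best = prev[d] + sub; dir = 0;
        }
        // up: gap in reference (read consumed, col same) -> from (row-1, col) = prev d+1
        if (d + 1 < W && prev[d + 1] > 0.5 * NEG) {
          double v = prev[d + 1] + gap;
          if (v > best) { best = v; dir = 1; }
        }
        // left: gap in read (col consumed) -> from (row, col-1) = cur d-1
        if (d - 1 >= 0 && cur[d - 1] > 0.5 * NEG) {
          double v = cur[d - 1] + gap;
          if (v > best) { best = v; dir = 2; }
        }
        if (best > 0.5 * NEG) {
          cur[d] = best;
          bt[(size_t)row * W + d] = dir;
        }
      }
      std::swap(prev, cur);
    }
    // best end over last row (free end in window)
    double bestScore = NEG; int bestD = -1;
    for (int d = 0; d < W; ++d) {
      long col = rlen + d + off0;
      if (col < 0 || col > wlen) continue;
      if (prev[d] > bestScore) { bestScore = prev[d]; bestD = d; }
    }
    if (bestD < 0) { out(i, 2) = -1; continue; }
    // traceback
    int row = rlen, d = bestD;
    long colEnd = rlen + bestD + off0;
    long col = colEnd;
    int matches = 0, columns = 0;
    while (row > 0) {
      signed char dir = bt[(size_t)row * W + d];
      if (dir == 3) break;
      if (dir == 0) {
        ++columns;
        if (r[row - 1] == target[w0 + col - 1]) ++matches;
        --row; --col;
      } else if (dir == 1) { ++columns; --row; ++d; }
      else { ++columns; --col; --d; }
    }
    out(i, 0) = matches;
    out(i, 1) = columns;
    out(i, 2) = (double)(w0 + col + 1); // 1-based ref start
    out(i, 3) = (double)(w0 + colEnd);  // 1-based ref end (inclusive)
    out(i, 4) = bestScore;
  }
  return out;
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Canonical k-mer counting over a set of sequences (upper-case expected).
// k-mers containing non-ACGT characters are skipped. Returns a two-column
// matrix: multiplicity, n_distinct_kmers — i.e. the k-mer histogram.
// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
IntegerMatrix kmer_histogram_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    const int len = LENGTH(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(p[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }
  std::unordered_map<uint32_t, uint32_t> hist;
  for (auto &kv : counts) ++hist[kv.second];
  IntegerMatrix out(hist.size(), 2);
  colnames(out) = CharacterVector::create("multiplicity", "count");
  int i = 0;
  for (auto &kv : hist) { out(i, 0) = kv.first; out(i, 1) = kv.second; ++i; }
  return out;
}
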