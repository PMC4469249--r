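#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
// A gap of length k scores gap_open + k * gap_extend (both <= 0),
// matching the convention of pairwiseAlignment(gapOpening, gapExtension).
// [[Rcpp::export]]
int sw_score_cpp(const std::string& a, const std::string& b,
                 int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  const long NEG = -1000000000L;
  const long open1 = (long)gap_open + gap_extend; // cost of a length-1 gap
  std::vector<long> H(m + 1, 0);   // previous row, overwritten in place
  std::vector<long> F(m + 1, NEG); // vertical gap state per column
  long best = 0;
  for (int i = 1; i <= n; ++i) {
    long diag = H[0]; // H[i-1][j-1]
    long left = 0;    // H[i][j-1]
    long E = NEG;     // horizontal gap state E[i][j-1] -> E[i][j]
    for (int j = 1; j <= m; ++j) {
      E = std::max(left + open1, E + gap_extend);
      F[j] = std::max(H[j] + open1, F[j] + gap_extend);
      long s = diag + (a[i - 1] == b[j - 1] ? match : mismatch);
      long h = std::max(std::max(s, 0L), std::max(E, F[j]));
      diag = H[j];
      H[j] = h;
      left = h;
      if (h > best) best = h;
    }
  }
  return (int)best;
}

// Vectorized Smith-Waterman over paired sequence vectors.
// [[Rcpp::export]]
IntegerVector sw_batch_cpp(CharacterVector a, CharacterVector b,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = sw_score_cpp(as<std::string>(a[i]), as<std::string>(b[i]),
                          match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// Longest contiguous block of identical nucleotides in the 5'-anchored,
// ungapped position-wise comparison of two sequences.
// [[Rcpp::export]]
IntegerVector longest_run_cpp(CharacterVector reads, CharacterVector refs) {
  const int n = reads.size();
  if (refs.size() != n) stop("reads and refs must have equal length");
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string a = as<std::string>(reads[k]);
    std::string b = as<std::string>(refs[k]);
    int lim = (int)std::min(a.size(), b.size());
    int best = 0, cur = 0;
    for (int i = 0; i < lim; ++i) {
      if (a[i] == b[i]) { if (++cur > best) best = cur; }
      else cur = 0;
    }
    out[k] = best;
  }
  return out;
}

// Ungapped placement test for the offset-tolerant exact-match tier.
// offset_5p = read start minus reference start (negative: read extends
// 5' of the reference); offset_3p = read end minus reference end.
// Every overlapping position must be identical; overhangs are free.
static bool placement_ok(const std::string& read, const std::string& ref,
                         int o5) {
  const int L = (int)read.size(), R = (int)ref.size();
  // reference coordinate c in [max(1, 1+o5), min(R, L+o5)]; read index c-o5
  int lo = std::max(1, 1 + o5), hi = std::min(R, L + o5);
  if (lo > hi) return false; // no overlap
  for (int c = lo; c <= hi; ++c)
    if (read[c - o5 - 1] != ref[c - 1]) return false;
  return true;
}

// Best qualifying placement of read against ref, minimizing |offset_5p|
// then |offset_3p|. Returns (found, offset_5p, offset_3p).
// [[Rcpp::export]]
IntegerVector tier1_pair_cpp(const std::string& read, const std::string& ref,
                             int max5, int max3) {
  const int L = (int)read.size(), R = (int)ref.size();
  int best_o5 = NA_INTEGER, best_o3 = NA_INTEGER;
  bool found = false;
  for (int o5 = -max5; o5 <= max5; ++o5) {
    int o3 = o5 + L - R;
    if (o3 < -max3 || o3 > max3) continue;
    if (!placement_ok(read, ref, o5)) continue;
    if (!found ||
        std::abs(o5) < std::abs(best_o5) ||
        (std::abs(o5) == std::abs(best_o5) &&
         std::abs(o3) < std::abs(best_o3))) {
      best_o5 = o5; best_o3 = o3; found = true;
    }
  }
  return IntegerVector::create(found ? 1 : 0, best_o5, best_o3);
}

// Scan each read against every reference; return, per read, the index of
// the winning reference (1-based, refs assumed sorted by id) with the
// smallest |offset_5p| + |offset_3p| (ties: first ref in order), plus the
// winning offsets. Index 0 = no reference qualifies.
// [[Rcpp::export]]
IntegerMatrix tier1_scan_cpp(CharacterVector reads, CharacterVector refs,
                             int max5, int max3) {
  const int n = reads.size(), m = refs.size();
  std::vector<std::string> rf(m);
  for (int j = 0; j < m; ++j) rf[j] = as<std::string>(refs[j]);
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int win = 0, w5 = NA_INTEGER, w3 = NA_INTEGER, wsum = 1 << 30;
    for (int j = 0; j < m; ++j) {
      IntegerVector hit = tier1_pair_cpp(rd, rf[j], max5, max3);
      if (hit[0] == 1) {
        int s = std::abs(hit[1]) + std::abs(hit[2]);
        if (s < wsum) { win = j + 1; w5 = hit[1]; w3 = hit[2]; wsum = s; }
      }
    }
    out(i, 0) = win; out(i, 1) = w5; out(i, 2) = w3;
  }
  return out;
}
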