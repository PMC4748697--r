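#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Rolling-index k-mer counting over a digit-encoded DNA sequence
// (A=0, T=1, G=2, C=3, anything else = sentinel >= 4).
//
// One pass maintains the base-4 index of the window of length kmax = max(K)
// starting at position i:
//   index_{i+1} = (index_i - a_i * 4^(kmax-1)) * 4 + a_{i+kmax}
// The index of the length-(kmax-j) prefix of the same window is
// index >> 2*j, so all k in K are counted simultaneously.  The sequence is
// conceptually padded with kmax-1 sentinels; a window contributes to the
// count for k only when its length-k prefix is sentinel-free (sentinels
// enter the index arithmetic as digit 0, and validity bookkeeping makes
// sure those bits are never used).

// [[Rcpp::export]]
List cpp_multi_kmer_counts(IntegerVector digits, IntegerVector ks) {
  const int nk = ks.size();
  if (nk == 0) stop("at least one k required");
  int kmax = 0;
  for (int j = 0; j < nk; ++j) {
    if (ks[j] < 1 || ks[j] > 12) stop("k must be in 1..12");
    if (ks[j] > kmax) kmax = ks[j];
  }
  const R_xlen_t n = digits.size();

  List out(nk);
  std::vector<int*> cptr(nk);
  for (int j = 0; j < nk; ++j) {
    IntegerVector cj((R_xlen_t)1 << (2 * ks[j]));  // zero-initialised
    out[j] = cj;
    cptr[j] = INTEGER(cj);
  }
  if (n == 0) return out;

  // nextSent[i]: smallest p >= i with a sentinel at p, or n (first pad sentinel)
  std::vector<R_xlen_t> nextSent(n + 1);
  nextSent[n] = n;
  for (R_xlen_t i = n - 1; i >= 0; --i) {
    const int d = digits[i];
    nextSent[i] = (d < 0 || d > 3) ? i : nextSent[i + 1];
    if (i == 0) break;
  }

  auto digitAt = [&](R_xlen_t p) -> uint64_t {
    if (p >= n) return 0;                 // pad sentinel
    const int d = digits[p];
    return (d < 0 || d > 3) ? 0 : (uint64_t)d;
  };

  // index of the (padded) window starting at 0
  uint64_t index = 0;
  for (int p = 0; p < kmax; ++p) index = (index << 2) | digitAt(p);
  const uint64_t top = (uint64_t)1 << (2 * (kmax - 1));

  for (R_xlen_t i = 0; i < n; ++i) {
    const R_xlen_t validLen = nextSent[i] - i;  // sentinel-free run from i
    for (int j = 0; j < nk; ++j) {
      const int k = ks[j];
      if ((R_xlen_t)k <= validLen)
        ++cptr[j][index >> (2 * (kmax - k))];
    }
    // roll: drop leading digit, append digit at i + kmax
    index = ((index - digitAt(i) * top) << 2) | digitAt(i + kmax);
  }
  return out;
}

// Sequence of rolling window indices for one k (NA where the window leaves
// the sequence or covers a sentinel).  Used for worked examples and tests.

// [[Rcpp::export]]
IntegerVector cpp_rolling_indices(IntegerVector digits, int k) {
  if (k < 1 || k > 12) stop("k must be in 1..12");
  const R_xlen_t n = digits.size();
  const R_xlen_t nw = n - k + 1;
  if (nw <= 0) return IntegerVector(0);
  IntegerVector idx(nw, NA_INTEGER);
  std::vector<R_xlen_t> nextSent(n + 1);
  nextSent[n] = n;
  for (R_xlen_t i = n - 1; i >= 0; --i) {
    const int d = digits[i];
    nextSent[i] = (d < 0 || d > 3) ? i : nextSent[i + 1];
    if (i == 0) break;
  }
  auto digitAt = [&](R_xlen_t p) -> uint64_t {
    const int d = digits[p];
    return (d < 0 || d > 3) ? 0 : (uint64_t)d;
  };
  uint64_t index = 0;
  for (int p = 0; p < k; ++p) index = (index << 2) | digitAt(p);
  const uint64_t top = (uint64_t)1 << (2 * (k - 1));
  for (R_xlen_t i = 0; i < nw; ++i) {
    if (nextSent[i] - i >= (R_xlen_t)k) idx[i] = (int)index;
    if (i + 1 < nw)
      index = ((index - digitAt(i) * top) << 2) | digitAt(i + k);
  }
  return idx;
}

// Order-3 Markov chain sequence simulator used by the synthetic-community
// generator.  `trans` is a 64 x 4 row-stochastic matrix indexed by the
// base-4 encoding of the previous three digits.  Uses R's RNG so results
// are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector cpp_markov_generate(NumericMatrix trans, int len) {
  if (trans.nrow() != 64 || trans.ncol() != 4)
    stop("trans must be 64 x 4");
  if (len < 0) stop("len must be >= 0");
  RNGScope scope;
  IntegerVector out(len);
  if (len == 0) return out;
  int hist[3];
  for (int i = 0; i < 3 && i < len; ++i) {
    int d = (int)(unif_rand() * 4.0);
    if (d > 3) d = 3;
    out[i] = d;
    hist[i] = d;
  }
  for (int i = 3; i < len; ++i) {
    const int state = hist[0] * 16 + hist[1] * 4 + hist[2];
    const double u = unif_rand();
    double acc = 0.0;
    int d = 3;
    for (int b = 0; b < 4; ++b) {
      acc += trans(state, b);
      if (u <= acc) { d = b; break; }
    }
    out[i] = d;
    hist[0] = hist[1]; hist[1] = hist[2]; hist[2] = d;
  }
  return out;
}
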