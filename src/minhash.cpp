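#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
using namespace Rcpp;

// Thomas Wang's 32-bit mix function (1997/2007). A bijection on uint32, so
// distinct inputs always map to distinct outputs.
static inline uint32_t mix32(uint32_t key) {
  key = ~key + (key << 15);
  key = key ^ (key >> 12);
  key = key + (key << 2);
  key = key ^ (key >> 4);
  key = key * 2057u;
  key = key ^ (key >> 16);
  return key;
}

// [[Rcpp::export]]
NumericVector cpp_mix32(NumericVector keys, double seed) {
  uint32_t s = (uint32_t) seed;
  R_xlen_t n = keys.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint32_t k = (uint32_t) keys[i];
    out[i] = (double) mix32(k ^ s);
  }
  return out;
}

// seed_j = mix32(mix32(master_seed) + j), j = 1..h: the outer mix keeps seeds
// within a family pairwise distinct (bijection), the inner mix scatters
// master seeds across the 32-bit range so nearby master seeds yield
// unrelated families
// [[Rcpp::export]]
NumericVector cpp_expand_seeds(double master_seed, int h) {
  NumericVector out(h);
  uint32_t base = mix32((uint32_t) master_seed);
  for (int j = 0; j < h; ++j)
    out[j] = (double) mix32(base + (uint32_t)(j + 1));
  return out;
}

// MinHash signatures: entry (c, j) is the feature id a in set c minimizing
// mix32(reduce(a) XOR seed_j); hash ties break to the smallest feature id
// because sets are ascending and the update uses strict <. Empty set -> -1.
// [[Rcpp::export]]
NumericMatrix cpp_signatures(List sets, NumericVector seeds, double modulus) {
  int m = sets.size();
  int h = seeds.size();
  NumericMatrix sig(m, h);
  std::vector<uint32_t> useeds(h);
  for (int j = 0; j < h; ++j) useeds[j] = (uint32_t) seeds[j];
  std::vector<uint32_t> reduced;
  for (int c = 0; c < m; ++c) {
    NumericVector A = sets[c];
    R_xlen_t f = A.size();
    if (f == 0) {
      for (int j = 0; j < h; ++j) sig(c, j) = -1.0;
      continue;
    }
    reduced.resize(f);
    uint64_t mod = (uint64_t) modulus;
    for (R_xlen_t i = 0; i < f; ++i)
      reduced[i] = (uint32_t) (((uint64_t) A[i]) % mod);
    for (int j = 0; j < h; ++j) {
      uint32_t s = useeds[j];
      uint32_t best = mix32(reduced[0] ^ s);
      double arg = A[0];
      for (R_xlen_t i = 1; i < f; ++i) {
        uint32_t v = mix32(reduced[i] ^ s);
        if (v < best) { best = v; arg = A[i]; }
      }
      sig(c, j) = arg;
    }
    if ((c & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return sig;
}

// Exact Jaccard over all pairs of ascending numeric id sets (the quadratic
// oracle path). Two-pointer intersection; J(empty, empty) = 0.
// [[Rcpp::export]]
NumericMatrix cpp_jaccard_matrix(List sets) {
  int m = sets.size();
  NumericMatrix J(m, m);
  std::vector<NumericVector> S(m);
  for (int i = 0; i < m; ++i) S[i] = as<NumericVector>(sets[i]);
  for (int a = 0; a < m; ++a) {
    J(a, a) = S[a].size() > 0 ? 1.0 : 0.0;
    for (int b = a + 1; b < m; ++b) {
      R_xlen_t na = S[a].size(), nb = S[b].size();
      R_xlen_t i = 0, k = 0, inter = 0;
      while (i < na && k < nb) {
        if (S[a][i] < S[b][k]) ++i;
        else if (S[a][i] > S[b][k]) ++k;
        else { ++inter; ++i; ++k; }
      }
      R_xlen_t uni = na + nb - inter;
      double j = uni > 0 ? (double) inter / (double) uni : 0.0;
      J(a, b) = j;
      J(b, a) = j;
    }
    Rcpp::checkUserInterrupt();
  }
  return J;
}

// Query signature rows against an inverse index given as a list of h
// per-function maps, each list(keys = sorted numeric, cells = list of 1-based
// ascending integer cell ids). Performs exactly h lookups per queried cell
// (one binary search per hash function); returns the n_query x index_m
// collision-count matrix with the self column (self_ids, 1-based, 0 = none)
// zeroed, plus the per-query lookup counts.
// [[Rcpp::export]]
List cpp_query_all(NumericMatrix sig, List maps, int index_m,
                   IntegerVector self_ids) {
  int m = sig.nrow();
  int h = sig.ncol();
  if ((int) maps.size() != h)
    stop("inverse index has %d functions but signatures have %d", (int) maps.size(), h);
  if (self_ids.size() != m)
    stop("self_ids must align with signature rows");
  IntegerMatrix counts(m, index_m);
  IntegerVector lookups(m);
  // pre-extract map columns
  std::vector<NumericVector> keys(h);
  std::vector<List> cells(h);
  for (int j = 0; j < h; ++j) {
    List mp = maps[j];
    keys[j] = as<NumericVector>(mp["keys"]);
    cells[j] = as<List>(mp["cells"]);
  }
  for (int c = 0; c < m; ++c) {
    int self = self_ids[c] - 1;
    int nl = 0;
    for (int j = 0; j < h; ++j) {
      double v = sig(c, j);
      ++nl; // one index lookup per hash function, sentinel rows included
      if (v < 0) continue;
      const NumericVector& K = keys[j];
      R_xlen_t lo = 0, hi = K.size();
      while (lo < hi) { // lower_bound
        R_xlen_t mid = (lo + hi) / 2;
        if (K[mid] < v) lo = mid + 1; else hi = mid;
      }
      if (lo < K.size() && K[lo] == v) {
        IntegerVector ids = cells[j][lo];
        for (R_xlen_t t = 0; t < ids.size(); ++t) {
          int id = ids[t] - 1;
          if (id != self) counts(c, id) += 1;
        }
      }
    }
    lookups[c] = nl;
    if ((c & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["lookups"] = lookups);
}

// Squared Euclidean distance between sparse rows (ascending ids + values).
// [[Rcpp::export]]
double cpp_sparse_euclidean2(NumericVector ia, NumericVector va,
                             NumericVector ib, NumericVector vb) {
  R_xlen_t na = ia.size(), nb = ib.size();
  R_xlen_t i = 0, k = 0;
  double acc = 0.0, d;
  while (i < na && k < nb) {
    if (ia[i] < ib[k]) { acc += va[i] * va[i]; ++i; }
    else if (ia[i] > ib[k]) { acc += vb[k] * vb[k]; ++k; }
    else { d = va[i] - vb[k]; acc += d * d; ++i; ++k; }
  }
  for (; i < na; ++i) acc += va[i] * va[i];
  for (; k < nb; ++k) acc += vb[k] * vb[k];
  return acc;
}
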