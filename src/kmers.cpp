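// Count-Min Sketch k-mer counting with 2-bit encoded canonical k-mers.
// All encoded paths require k <= 31 so a k-mer fits in 62 bits.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

namespace {

inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline uint64_t row_salt(int seed, int row) {
  return splitmix64(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(uint32_t)(row + 1));
}

inline R_xlen_t cell_of(uint64_t code, uint64_t salt, R_xlen_t width) {
  return (R_xlen_t)(splitmix64(code ^ salt) % (uint64_t)width);
}

// f(canonical_code) for every N-free k-window of s
template <typename F>
void for_each_canonical(const char* s, R_xlen_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) f(fwd < rc ? fwd : rc);
  }
}

std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BITS2BASE[code & 3ULL]; code >>= 2; }
  return s;
}

uint64_t rc_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3ULL - (x & 3ULL)); x >>= 2; }
  return r;
}

void check_k(int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31 for sketch operations");
}

// encode a query k-mer; error on wrong length or non-ACGT
uint64_t encode_query(SEXP sx, int k, R_xlen_t which) {
  const char* s = CHAR(sx);
  R_xlen_t n = LENGTH(sx);
  if (n != k)
    stop("k-mer %d has length %d, expected %d", (int)(which + 1), (int)n, k);
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0)
      stop("k-mer %d contains a character outside {A,C,G,T}", (int)(which + 1));
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

inline int cms_query(const int* C, R_xlen_t width, int depth,
                     const std::vector<uint64_t>& salts, uint64_t code) {
  int est = INT_MAX;
  for (int r = 0; r < depth; ++r) {
    int v = C[(R_xlen_t)r * width + cell_of(code, salts[r], width)];
    if (v < est) est = v;
  }
  return est;
}

std::vector<uint64_t> make_salts(int seed, int depth) {
  std::vector<uint64_t> salts(depth);
  for (int r = 0; r < depth; ++r) salts[r] = row_salt(seed, r);
  return salts;
}

} // namespace

// [[Rcpp::export]]
List cms_build_cpp(CharacterVector reads, int k, int width, int depth, int seed) {
  check_k(k);
  if (width < 1 || depth < 1) stop("width and depth must be >= 1");
  IntegerVector counters((R_xlen_t)width * depth);
  int* C = INTEGER(counters);
  std::vector<uint64_t> salts = make_salts(seed, depth);
  double inserted = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    for_each_canonical(CHAR(sx), LENGTH(sx), k, [&](uint64_t code) {
      for (int r = 0; r < depth; ++r) {
        R_xlen_t idx = (R_xlen_t)r * width + cell_of(code, salts[r], width);
        if (C[idx] < INT_MAX) ++C[idx];
      }
      inserted += 1;
    });
  }
  return List::create(_["counters"] = counters, _["n_inserted"] = inserted);
}

// [[Rcpp::export]]
IntegerVector cms_estimate_cpp(IntegerVector counters, int k, int width, int depth,
                               int seed, CharacterVector kmers) {
  check_k(k);
  const int* C = INTEGER(counters);
  std::vector<uint64_t> salts = make_salts(seed, depth);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP sx = STRING_ELT(kmers, i);
    if (sx == NA_STRING) stop("k-mer %d is NA", (int)(i + 1));
    uint64_t code = encode_query(sx, k, i);
    uint64_t rc = rc_code(code, k);
    out[i] = cms_query(C, width, depth, salts, code < rc ? code : rc);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cms_max_per_read_cpp(IntegerVector counters, int k, int width, int depth,
                                   int seed, CharacterVector reads) {
  check_k(k);
  const int* C = INTEGER(counters);
  std::vector<uint64_t> salts = make_salts(seed, depth);
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    int best = 0;
    if (sx != NA_STRING) {
      for_each_canonical(CHAR(sx), LENGTH(sx), k, [&](uint64_t code) {
        int est = cms_query(C, width, depth, salts, code);
        if (est > best) best = est;
      });
    }
    out[i] = best;
  }
  return out;
}

// Exact canonical k-mer multiset over a read pool: the test oracle for the
// sketch's one-sided error claim. Desk-scale only (hash map in memory).
// [[Rcpp::export]]
List exact_kmer_counts_cpp(CharacterVector reads, int k) {
  check_k(k);
  std::unordered_map<uint64_t, int> m;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    for_each_canonical(CHAR(sx), LENGTH(sx), k, [&](uint64_t code) { ++m[code]; });
  }
  std::vector<std::pair<uint64_t, int> > v(m.begin(), m.end());
  std::sort(v.begin(), v.end());
  CharacterVector kmers(v.size());
  IntegerVector counts(v.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i) {
    kmers[i] = decode_kmer(v[i].first, k);
    counts[i] = v[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// Bulk comparison of sketch estimates against exact counts over every distinct
// canonical k-mer in `reads` (avoids materialising millions of strings in R).
// [[Rcpp::export]]
List cms_exact_compare_cpp(IntegerVector counters, int k, int width, int depth,
                           int seed, CharacterVector reads) {
  check_k(k);
  std::unordered_map<uint64_t, int> m;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    for_each_canonical(CHAR(sx), LENGTH(sx), k, [&](uint64_t code) { ++m[code]; });
  }
  const int* C = INTEGER(counters);
  std::vector<uint64_t> salts = make_salts(seed, depth);
  double n_distinct = 0, n_under = 0, n_equal = 0, max_over = 0;
  for (std::unordered_map<uint64_t, int>::const_iterator it = m.begin();
       it != m.end(); ++it) {
    int est = cms_query(C, width, depth, salts, it->first);
    n_distinct += 1;
    if (est < it->second) n_under += 1;
    else if (est == it->second) n_equal += 1;
    double over = est - it->second;
    if (over > max_over) max_over = over;
  }
  return List::create(_["n_distinct"] = n_distinct, _["n_under"] = n_under,
                      _["n_equal"] = n_equal, _["max_overestimate"] = max_over);
}
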