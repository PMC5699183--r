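// Built-in read mapper for depth profiling: exact k-mer seeding (default 21),
// diagonal voting, ungapped verification, best single placement per read.
// Depth only -- no alignment records are produced.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

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

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

// f(code, start) for every N-free forward k-window
template <typename F>
void for_each_forward(const char* s, R_xlen_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(fwd, (int)(i - k + 1));
  }
}

bool encode_at(const std::string& s, int pos, int k, uint64_t* out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  *out = code;
  return true;
}

} // namespace

// [[Rcpp::export]]
IntegerVector map_depth_cpp(std::string anchor, CharacterVector reads,
                            int seed_len, double max_mismatch_frac,
                            int min_overlap) {
  const int alen = (int)anchor.size();
  if (alen < seed_len) return IntegerVector(alen);

  std::unordered_map<uint64_t, std::vector<int> > index;
  for_each_forward(anchor.c_str(), alen, seed_len,
                   [&](uint64_t code, int pos) { index[code].push_back(pos); });

  const int max_hits_per_seed = 50;  // skip hyper-repetitive seeds
  std::vector<int> delta(alen + 1, 0);

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    std::string fw(CHAR(sx));
    int len = (int)fw.size();
    if (len < seed_len) continue;
    std::string rv(fw.rbegin(), fw.rend());
    for (size_t j = 0; j < rv.size(); ++j) rv[j] = comp(rv[j]);

    int offs[3] = {0, (len - seed_len) / 2, len - seed_len};
    // votes keyed by (strand, diagonal); ordered map makes tie-breaks
    // deterministic (forward strand first, then smallest diagonal)
    std::map<std::pair<int, int>, int> votes;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& o = (strand == 0) ? fw : rv;
      int prev = -1;
      for (int t = 0; t < 3; ++t) {
        int off = offs[t];
        if (off == prev) continue;
        prev = off;
        uint64_t code;
        if (!encode_at(o, off, seed_len, &code)) continue;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            index.find(code);
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_hits_per_seed) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          ++votes[std::make_pair(strand, it->second[h] - off)];
      }
    }
    if (votes.empty()) continue;
    std::pair<int, int> best;
    int best_votes = -1;
    for (std::map<std::pair<int, int>, int>::const_iterator it = votes.begin();
         it != votes.end(); ++it)
      if (it->second > best_votes) { best_votes = it->second; best = it->first; }

    const std::string& o = (best.first == 0) ? fw : rv;
    int diag = best.second;
    int a0 = std::max(0, diag), a1 = std::min(alen, diag + len);
    int ov = a1 - a0;
    if (ov < min_overlap) continue;
    int mm = 0;
    for (int p = a0; p < a1; ++p)
      if (o[p - diag] != anchor[p]) ++mm;
    if (mm > max_mismatch_frac * ov) continue;
    ++delta[a0];
    --delta[a1];
  }

  IntegerVector depth(alen);
  int acc = 0;
  for (int p = 0; p < alen; ++p) { acc += delta[p]; depth[p] = acc; }
  return depth;
}
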