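// Minimal canonical de Bruijn unitig assembler: count k-mers, drop those
// below min_count, pop short tips, compact unbranched paths. One k per call;
// the iterative-k strategy (unitigs of the previous k re-entering as
// pseudo-reads) is driven from R. String-keyed, so any odd k works.

#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

std::string canon_str(const std::string& s) {
  std::string r = rc_str(s);
  return s < r ? s : r;
}

// f(window) for every {A,C,G,T}-only k-window
template <typename F>
void for_each_window(const char* s, size_t n, int k, F f) {
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    if (base_ok(s[i])) ++run; else run = 0;
    if (run >= k) f(std::string(s + i - k + 1, (size_t)k));
  }
}

struct DBG {
  int k;
  std::unordered_set<std::string> keep;  // canonical k-mers

  bool has(const std::string& s) const { return keep.count(canon_str(s)) > 0; }

  std::vector<std::string> succ(const std::string& u) const {
    std::vector<std::string> out;
    std::string v = u.substr(1) + "A";
    const char B[4] = {'A', 'C', 'G', 'T'};
    for (int i = 0; i < 4; ++i) {
      v[v.size() - 1] = B[i];
      if (has(v)) out.push_back(v);
    }
    return out;
  }

  std::vector<std::string> pred(const std::string& u) const {
    std::vector<std::string> out;
    std::string v = "A" + u.substr(0, u.size() - 1);
    const char B[4] = {'A', 'C', 'G', 'T'};
    for (int i = 0; i < 4; ++i) {
      v[0] = B[i];
      if (has(v)) out.push_back(v);
    }
    return out;
  }
};

// Maximal unbranched paths; each canonical k-mer visited once, so every
// unitig (and its reverse complement) is emitted exactly once. Sorted
// iteration over start k-mers makes the result independent of read order.
std::vector<std::string> build_unitigs(const DBG& g) {
  std::vector<std::string> keys(g.keep.begin(), g.keep.end());
  std::sort(keys.begin(), keys.end());
  std::unordered_set<std::string> visited;
  std::vector<std::string> unitigs;
  for (size_t s = 0; s < keys.size(); ++s) {
    const std::string& start = keys[s];
    if (visited.count(start)) continue;
    visited.insert(start);
    std::string seq = start;
    for (;;) {  // extend right
      std::string cur = seq.substr(seq.size() - g.k);
      std::vector<std::string> nx = g.succ(cur);
      if (nx.size() != 1) break;
      const std::string& v = nx[0];
      if (g.pred(v).size() != 1) break;
      std::string cv = canon_str(v);
      if (visited.count(cv)) break;  // cycle closed or already consumed
      visited.insert(cv);
      seq.push_back(v[v.size() - 1]);
    }
    for (;;) {  // extend left
      std::string cur = seq.substr(0, g.k);
      std::vector<std::string> pv = g.pred(cur);
      if (pv.size() != 1) break;
      const std::string& v = pv[0];
      if (g.succ(v).size() != 1) break;
      std::string cv = canon_str(v);
      if (visited.count(cv)) break;
      visited.insert(cv);
      seq.insert(seq.begin(), v[0]);
    }
    unitigs.push_back(seq);
  }
  return unitigs;
}

} // namespace

// [[Rcpp::export]]
CharacterVector assemble_k_cpp(CharacterVector reads, CharacterVector pseudo,
                               int k, int min_count, int tip_rounds) {
  if (k < 2) stop("assembly k must be >= 2");
  if (k % 2 == 0) stop("assembly k must be odd (avoids palindromic k-mers)");

  std::unordered_map<std::string, int> counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP sx = STRING_ELT(reads, i);
    if (sx == NA_STRING) continue;
    for_each_window(CHAR(sx), (size_t)LENGTH(sx), k,
                    [&](const std::string& w) { ++counts[canon_str(w)]; });
  }

  DBG g;
  g.k = k;
  for (std::unordered_map<std::string, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    if (it->second >= min_count) g.keep.insert(it->first);
  // unitigs from the previous (smaller) k were already validated; their
  // k-mers enter unconditionally, which is what lets contigs grow across
  // low-coverage stretches at larger k
  for (R_xlen_t i = 0; i < pseudo.size(); ++i) {
    SEXP sx = STRING_ELT(pseudo, i);
    if (sx == NA_STRING) continue;
    for_each_window(CHAR(sx), (size_t)LENGTH(sx), k,
                    [&](const std::string& w) { g.keep.insert(canon_str(w)); });
  }

  std::vector<std::string> unitigs = build_unitigs(g);
  for (int round = 0; round < tip_rounds; ++round) {
    bool removed = false;
    for (size_t u = 0; u < unitigs.size(); ++u) {
      const std::string& seq = unitigs[u];
      if ((int)seq.size() >= 2 * k) continue;
      bool left_dead = g.pred(seq.substr(0, k)).empty();
      bool right_dead = g.succ(seq.substr(seq.size() - k)).empty();
      if (left_dead == right_dead) continue;  // tip == exactly one dead end
      for_each_window(seq.c_str(), seq.size(), k,
                      [&](const std::string& w) { g.keep.erase(canon_str(w)); });
      removed = true;
    }
    if (!removed) break;
    unitigs = build_unitigs(g);
  }

  // canonical orientation + (length desc, lexicographic) order: fully
  // deterministic and invariant under read permutation
  for (size_t u = 0; u < unitigs.size(); ++u)
    unitigs[u] = canon_str(unitigs[u]);
  std::sort(unitigs.begin(), unitigs.end(),
            [](const std::string& a, const std::string& b) {
              if (a.size() != b.size()) return a.size() > b.size();
              return a < b;
            });
  unitigs.erase(std::unique(unitigs.begin(), unitigs.end()), unitigs.end());
  return wrap(unitigs);
}
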