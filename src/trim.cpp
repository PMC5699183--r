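// 3' adapter and quality trimming. Adapter rule: the leftmost position at
// which the remainder of the read matches a prefix of an adapter exactly
// (overlap >= min_overlap) marks the cut; read-through past a full adapter
// is also cut there. Quality rule: strip the 3' tail while Phred < cutoff.

#include <Rcpp.h>
#include <string>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector bases, CharacterVector quals,
                    CharacterVector adapters, int min_overlap,
                    int qual_cutoff) {
  R_xlen_t n = bases.size();
  CharacterVector out_b(n), out_q(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string b = as<std::string>(bases[i]);
    std::string q = as<std::string>(quals[i]);
    int len = (int)b.size();
    int cut = len;

    for (R_xlen_t a = 0; a < adapters.size(); ++a) {
      std::string ad = as<std::string>(adapters[a]);
      int alen = (int)ad.size();
      if (alen < min_overlap) continue;
      for (int pos = 0; pos <= len - min_overlap && pos < cut; ++pos) {
        int ov = std::min(len - pos, alen);
        if (b.compare(pos, ov, ad, 0, ov) == 0) { cut = pos; break; }
      }
    }

    while (cut > 0 && (int)q[cut - 1] - 33 < qual_cutoff) --cut;

    out_b[i] = b.substr(0, cut);
    out_q[i] = q.substr(0, cut);
  }
  return List::create(_["bases"] = out_b, _["quals"] = out_q);
}
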