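#include <Rcpp.h>
using namespace Rcpp;

// 3' adapter trimming. For each read, finds the earliest start position s
// such that the read substring from s matches a prefix of the adapter with
// >= min_overlap aligned bases and <= max_mm_rate mismatches, where the
// match either runs to the read's 3' end (read-through cut by the read end)
// or covers the whole adapter (adapter fully contained, followed by filler).
// Everything from s onward is removed. Reads with no acceptable match are
// returned unchanged.

// [[Rcpp::export]]
CharacterVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap, double max_mm_rate) {
  const int alen = (int) adapter.size();
  CharacterVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    const int L = (int) read.size();
    int cut = -1;
    for (int s = 0; s <= L - min_overlap && cut < 0; ++s) {
      int ov = std::min(L - s, alen);
      if (ov < min_overlap) break;
      bool to_end = (s + ov == L) || (ov == alen);
      if (!to_end) continue; // cannot happen given ov definition; kept for clarity
      int mm = 0, allowed = (int) (max_mm_rate * ov);
      for (int i = 0; i < ov; ++i) {
        if (read[s + i] != adapter[i] && ++mm > allowed) break;
      }
      if (mm <= allowed) cut = s;
    }
    out[r] = (cut >= 0) ? read.substr(0, cut) : read;
  }
  if (reads.hasAttribute("names")) out.names() = reads.names();
  return out;
}
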