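#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
// Gap of length g scores gap_open + g * gap_extend (open charged once per
// gap, extend per base), matching the convention of standard DP aligners.
// Scores are ints; penalties are passed as negative numbers.
//
// Traceback byte layout per cell:
//   bits 0-1: H source (0 = stop, 1 = diagonal, 2 = E [gap in query /
//             left move], 3 = F [gap in ref / up move])
//   bit 2   : E opened from H (1) or extended from E (0)
//   bit 3   : F opened from H (1) or extended from F (0)

static inline int base_match(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) query.size();
  const int n = (int) ref.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);

  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // E: gap in query (left)
  std::vector<int> F(n + 1, NEG);                        // F: gap in ref (up)
  std::vector<unsigned char> tb((size_t) m * n, 0);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      unsigned char t = 0;
      // E: gap in query, moving left along ref
      int e_open = Hcur[j - 1] + gap_open + gap_extend;
      int e_ext  = Ecur[j - 1] + gap_extend;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_open >= e_ext) t |= 4;
      Ecur[j] = e;
      // F: gap in ref, moving up along query
      int f_open = Hprev[j] + gap_open + gap_extend;
      int f_ext  = F[j] + gap_extend;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_open >= f_ext) t |= 8;
      F[j] = f;
      // H
      int diag = Hprev[j - 1] + base_match(qc, ref[j - 1], match, mismatch);
      int h = 0; unsigned char src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h)    { h = e;    src = 2; }
      if (f > h)    { h = f;    src = 3; }
      Hcur[j] = h;
      t |= src;
      tb[(size_t)(i - 1) * n + (j - 1)] = t;
      // deterministic tie-break: keep earliest (smallest ref end, then
      // smallest query end) cell attaining the maximum
      if (h > best) { best = h; bi = i; bj = j; }
      else if (h == best && best > 0 && (bj > j || (bj == j && bi > i))) {
        bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_bases = 0, cols = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)(i - 1) * n + (j - 1)];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++cols;
        if (query[i - 1] == ref[j - 1] && query[i - 1] != 'N') ++matches;
        else ++mismatches;
        --i; --j;
      } else {
        state = src; // enter E or F without consuming
      }
    } else if (state == 2) { // E: gap in query, consume ref
      ++cols; ++gap_bases;
      bool opened = (t & 4) != 0;
      --j;
      if (opened) { ++gap_opens; state = 0; }
    } else { // F: gap in ref, consume query
      ++cols; ++gap_bases;
      bool opened = (t & 8) != 0;
      --i;
      if (opened) { ++gap_opens; state = 0; }
    }
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = i,        // 0-based start (half-open interval [qstart, qend))
    _["qend"] = bi,
    _["rstart"] = j,
    _["rend"] = bj,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens,
    _["gap_bases"] = gap_bases,
    _["align_len"] = cols);
}

// Score-only Smith-Waterman (no traceback, no matrices beyond two rows).
// Used for strand/construct selection and margin computation, where only
// the maximal score matters.
// [[Rcpp::export]]
int sw_score_cpp(std::string query, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) query.size();
  const int n = (int) ref.size();
  if (m == 0 || n == 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Ecur(n + 1, NEG), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(Hcur[j - 1] + gap_open + gap_extend,
                       Ecur[j - 1] + gap_extend);
      Ecur[j] = e;
      int f = std::max(Hprev[j] + gap_open + gap_extend, F[j] + gap_extend);
      F[j] = f;
      int h = Hprev[j - 1] + base_match(qc, ref[j - 1], match, mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Batch wrapper: align each query against one reference, forward only.
// [[Rcpp::export]]
List sw_align_batch_cpp(CharacterVector queries, std::string ref,
                        int match, int mismatch, int gap_open, int gap_extend) {
  int n = queries.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = sw_align_cpp(as<std::string>(queries[i]), ref,
                          match, mismatch, gap_open, gap_extend);
  }
  return out;
}
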