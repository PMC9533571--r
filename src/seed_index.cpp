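#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact-match word index over a set of named sequences (forward strand).
// Words containing non-ACGT characters are skipped; both strands are
// handled at query time by also querying the reverse complement.

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<int> lengths;
  std::unordered_map<std::uint64_t, std::vector<std::uint64_t>> map; // (chrom<<32)|pos
  std::size_t n_words;
};

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
SEXP seed_index_build_cpp(CharacterVector seqs, int k) {
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  idx->n_words = 0;
  CharacterVector nm = seqs.names();
  const std::uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    idx->names.push_back(nm.size() ? as<std::string>(nm[s]) : std::to_string(s + 1));
    idx->lengths.push_back((int) seq.size());
    std::uint64_t w = 0;
    int valid = 0;
    for (int i = 0; i < (int) seq.size(); ++i) {
      int c = code(seq[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (std::uint64_t) c) & mask;
      if (++valid >= k) {
        int pos = i - k + 1; // 0-based word start
        idx->map[w].push_back(((std::uint64_t) s << 32) | (std::uint64_t) pos);
        ++idx->n_words;
      }
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

static bool encode_word(const std::string &s, int from, int k, std::uint64_t &w) {
  w = 0;
  for (int i = from; i < from + k; ++i) {
    int c = code(s[i]);
    if (c < 0) return false;
    w = (w << 2) | (std::uint64_t) c;
  }
  return true;
}

// [[Rcpp::export]]
List seed_index_info_cpp(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return List::create(_["word_size"] = idx->k,
                      _["chromosomes"] = wrap(idx->names),
                      _["lengths"] = wrap(idx->lengths),
                      _["n_words"] = (double) idx->n_words);
}

// [[Rcpp::export]]
DataFrame seed_index_lookup_cpp(SEXP ptr, std::string word) {
  XPtr<SeedIndex> idx(ptr);
  std::vector<int> chrom, pos;
  std::uint64_t w;
  if ((int) word.size() == idx->k && encode_word(word, 0, idx->k, w)) {
    auto it = idx->map.find(w);
    if (it != idx->map.end()) {
      for (std::uint64_t v : it->second) {
        chrom.push_back((int) (v >> 32) + 1);
        pos.push_back((int) (v & 0xffffffffULL));
      }
    }
  }
  return DataFrame::create(_["chrom"] = wrap(chrom), _["pos"] = wrap(pos));
}

// All seed hits of a fragment: every word start of `frag` is looked up;
// returns (chrom index, ref word start, query word start), all 0-based
// except chrom which is 1-based into the index's chromosome vector.
// [[Rcpp::export]]
DataFrame seed_index_hits_cpp(SEXP ptr, std::string frag) {
  XPtr<SeedIndex> idx(ptr);
  const int k = idx->k;
  std::vector<int> chrom, rpos, qpos;
  const int L = (int) frag.size();
  for (int q = 0; q + k <= L; ++q) {
    std::uint64_t w;
    if (!encode_word(frag, q, k, w)) continue;
    auto it = idx->map.find(w);
    if (it == idx->map.end()) continue;
    for (std::uint64_t v : it->second) {
      chrom.push_back((int) (v >> 32) + 1);
      rpos.push_back((int) (v & 0xffffffffULL));
      qpos.push_back(q);
    }
  }
  return DataFrame::create(_["chrom"] = wrap(chrom), _["rpos"] = wrap(rpos),
                           _["qpos"] = wrap(qpos));
}
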