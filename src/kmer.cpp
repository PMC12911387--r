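#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit nucleotide encoding; k-mers up to k = 31 fit one 64-bit word.
// Sequences are plain A/C/G/T strings; any other character invalidates
// every k-mer window covering it.

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Rolling k-mer extraction: calls f(pos, kmer) for every valid window.
template <typename F>
static void for_each_kmer(const char *s, R_xlen_t n, int k, F f) {
  uint64_t kmer = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  int run = 0;  // valid bases accumulated
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) f((R_xlen_t)(i - k + 1), kmer);
  }
}

// [[Rcpp::export]]
List cpp_fragment_containment(std::string query, std::string ref, int k,
                              int fragment) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> refset;
  refset.reserve(ref.size());
  for_each_kmer(ref.c_str(), (R_xlen_t)ref.size(), k,
                [&](R_xlen_t, uint64_t km) { refset.insert(km); });
  R_xlen_t L = (R_xlen_t)query.size();
  R_xlen_t nfrag = L / fragment;
  NumericVector containment(nfrag);
  IntegerVector nkmer(nfrag);
  const char *q = query.c_str();
  for (R_xlen_t f = 0; f < nfrag; ++f) {
    R_xlen_t shared = 0, total = 0;
    for_each_kmer(q + f * fragment, (R_xlen_t)fragment, k,
                  [&](R_xlen_t, uint64_t km) {
                    ++total;
                    if (refset.count(km)) ++shared;
                  });
    containment[f] = total > 0 ? (double)shared / (double)total : NA_REAL;
    nkmer[f] = (int)total;
  }
  return List::create(_["containment"] = containment, _["n_kmers"] = nkmer);
}

// Fraction of each read's k-mers present in a single reference sequence.
// [[Rcpp::export]]
NumericVector cpp_match_fraction(CharacterVector reads, std::string ref,
                                 int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> refset;
  refset.reserve(ref.size());
  for_each_kmer(ref.c_str(), (R_xlen_t)ref.size(), k,
                [&](R_xlen_t, uint64_t km) { refset.insert(km); });
  R_xlen_t n = reads.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(reads, i));
    R_xlen_t shared = 0, total = 0;
    for_each_kmer(r, len, k, [&](R_xlen_t, uint64_t km) {
      ++total;
      if (refset.count(km)) ++shared;
    });
    out[i] = total > 0 ? (double)shared / (double)total : NA_REAL;
  }
  return out;
}

// All-pairs fragment containment: one combined k-mer -> genome-bitmask
// hash serves every query/reference direction at once.  For query g the
// result is an (n_fragments x n_genomes) matrix of containment values.
// [[Rcpp::export]]
List cpp_all_pairs_containment(CharacterVector genomes, int k,
                               int fragment) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  int ng = (int)genomes.size();
  if (ng < 1 || ng > 64) stop("between 1 and 64 genomes supported");
  std::unordered_map<uint64_t, uint64_t> masks;
  size_t tot = 0;
  for (int g = 0; g < ng; ++g) tot += LENGTH(STRING_ELT(genomes, g));
  masks.reserve(tot);
  for (int g = 0; g < ng; ++g) {
    const char *s = CHAR(STRING_ELT(genomes, g));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(genomes, g));
    uint64_t bit = 1ULL << g;
    for_each_kmer(s, len, k, [&](R_xlen_t, uint64_t km) {
      masks[km] |= bit;
    });
  }
  List out(ng);
  std::vector<double> cnt((size_t)ng);
  for (int g = 0; g < ng; ++g) {
    const char *s = CHAR(STRING_ELT(genomes, g));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(genomes, g));
    R_xlen_t nfrag = len / fragment;
    NumericMatrix m(nfrag, ng);
    for (R_xlen_t f = 0; f < nfrag; ++f) {
      std::fill(cnt.begin(), cnt.end(), 0.0);
      R_xlen_t total = 0;
      for_each_kmer(s + f * fragment, (R_xlen_t)fragment, k,
                    [&](R_xlen_t, uint64_t km) {
                      ++total;
                      auto it = masks.find(km);
                      if (it != masks.end()) {
                        uint64_t mm = it->second;
                        while (mm) {
                          int h = __builtin_ctzll(mm);
                          cnt[h] += 1.0;
                          mm &= mm - 1;
                        }
                      }
                    });
      for (int h = 0; h < ng; ++h)
        m(f, h) = total > 0 ? cnt[h] / (double)total : NA_REAL;
    }
    out[g] = m;
  }
  return out;
}

// Reusable competitive-assignment index (combined bitmask hash plus
// per-genome first-occurrence positions), held as an external pointer.
struct AssignIndex {
  int k;
  int ng;
  std::unordered_map<uint64_t, uint64_t> masks;
  std::vector<std::unordered_map<uint64_t, int>> firstpos;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector genomes, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  int ng = (int)genomes.size();
  if (ng < 1 || ng > 64) stop("between 1 and 64 genomes supported");
  XPtr<AssignIndex> idx(new AssignIndex(), true);
  idx->k = k;
  idx->ng = ng;
  size_t tot = 0;
  for (int g = 0; g < ng; ++g) tot += LENGTH(STRING_ELT(genomes, g));
  idx->masks.reserve(tot);
  idx->firstpos.resize(ng);
  for (int g = 0; g < ng; ++g) {
    const char *s = CHAR(STRING_ELT(genomes, g));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(genomes, g));
    idx->firstpos[g].reserve(len);
    uint64_t bit = 1ULL << g;
    for_each_kmer(s, len, k, [&](R_xlen_t pos, uint64_t km) {
      idx->masks[km] |= bit;
      idx->firstpos[g].emplace(km, (int)pos);
    });
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_score_reads_idx(CharacterVector reads, SEXP ptr,
                         double min_frac) {
  XPtr<AssignIndex> idx(ptr);
  int k = idx->k;
  int ng = idx->ng;
  R_xlen_t n = reads.size();
  IntegerVector n_kmers(n), best_score(n), n_best(n);
  std::vector<int> out_read, out_strain, out_start;
  std::vector<int> cnt(ng);
  std::vector<uint64_t> readkm;
  std::vector<int> readoff;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(reads, i));
    std::fill(cnt.begin(), cnt.end(), 0);
    readkm.clear();
    readoff.clear();
    int total = 0;
    for_each_kmer(r, len, k, [&](R_xlen_t pos, uint64_t km) {
      ++total;
      readkm.push_back(km);
      readoff.push_back((int)pos);
      auto it = idx->masks.find(km);
      if (it != idx->masks.end()) {
        uint64_t m = it->second;
        while (m) {
          int g = __builtin_ctzll(m);
          ++cnt[g];
          m &= m - 1;
        }
      }
    });
    n_kmers[i] = total;
    int best = 0;
    for (int g = 0; g < ng; ++g) if (cnt[g] > best) best = cnt[g];
    best_score[i] = best;
    int minscore = (int)std::ceil(min_frac * (double)total);
    if (minscore < 1) minscore = 1;
    int nb = 0;
    if (best >= minscore) {
      for (int g = 0; g < ng; ++g) {
        if (cnt[g] == best) {
          ++nb;
          int start = NA_INTEGER;
          for (size_t j = 0; j < readkm.size(); ++j) {
            auto it = idx->firstpos[g].find(readkm[j]);
            if (it != idx->firstpos[g].end()) {
              start = it->second - readoff[j];
              break;
            }
          }
          out_read.push_back((int)i + 1);
          out_strain.push_back(g + 1);
          out_start.push_back(start);
        }
      }
    }
    n_best[i] = nb;
  }
  return List::create(
      _["read"] = IntegerVector(out_read.begin(), out_read.end()),
      _["strain"] = IntegerVector(out_strain.begin(), out_strain.end()),
      _["start"] = IntegerVector(out_start.begin(), out_start.end()),
      _["n_kmers"] = n_kmers, _["best_score"] = best_score,
      _["n_best"] = n_best);
}

// Competitive read scoring against all member genomes (one-shot
// convenience wrapper over the reusable index).
//
// Returns a long-format assignment table plus per-read summaries; policy
// (unique vs fractional weighting) is applied on the R side.
// [[Rcpp::export]]
List cpp_score_reads(CharacterVector reads, CharacterVector genomes, int k,
                     double min_frac) {
  SEXP idx = cpp_build_index(genomes, k);
  return cpp_score_reads_idx(reads, idx, min_frac);
}

// Per-base substitution errors at a fixed rate, using R's RNG so that
// results are reproducible under set.seed().  Substitutions are drawn
// uniformly from the three alternative bases.
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector reads, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(reads, i));
    buf.assign(r, (size_t)len);
    for (R_xlen_t j = 0; j < len; ++j) {
      if (unif_rand() < error_rate) {
        int cur = base2bits(buf[(size_t)j]);
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        // pick among the three bases != current
        int pick = (alt >= cur && cur >= 0) ? alt + 1 : alt;
        buf[(size_t)j] = bases[pick & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}
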