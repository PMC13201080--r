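#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3. Lexicographic order on k-mer strings
// equals numeric order on codes, so sorting codes sorts k-mers.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char* bases = "ACGT";
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline bool encode_kmer(const char* s, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// Count canonical k-mers (min of forward and reverse-complement code) across
// all sequences. Windows containing a non-ACGT base are skipped. Returns the
// table sorted lexicographically by k-mer.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (const char* p = str; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
      if (run < k) ++run;
      if (run == k) ++counts[fwd < rc ? fwd : rc];
    }
  }
  std::vector<std::pair<uint64_t, uint32_t> > v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  R_xlen_t n = (R_xlen_t)v.size();
  CharacterVector kmers(n);
  IntegerVector cnt(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    kmers[i] = decode_kmer(v[(size_t)i].first, k);
    cnt[i] = (int)v[(size_t)i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Document frequency: for each query k-mer (given as canonical string), the
// number of sequences whose canonical window set contains it.
// [[Rcpp::export]]
IntegerVector cpp_doc_freq(CharacterVector seqs, int k, CharacterVector kmers) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> index;
  index.reserve((size_t)kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t code;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)), k, code))
      stop("non-ACGT character in query k-mer");
    index[code] = (int)i;
  }
  std::vector<int> stamp(index.size(), -1);
  IntegerVector df((R_xlen_t)kmers.size());
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (const char* p = str; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
      if (run < k) ++run;
      if (run == k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        std::unordered_map<uint64_t, int>::const_iterator it = index.find(canon);
        if (it != index.end() && stamp[(size_t)it->second] != (int)s) {
          stamp[(size_t)it->second] = (int)s;
          ++df[it->second];
        }
      }
    }
  }
  return df;
}

// Literal matching of alphabet k-mers in each read and in its reverse
// complement. Row 2*r (0-based) holds matches of the read as given (+), row
// 2*r + 1 matches of its reverse complement (-). A window of the read whose
// reverse complement equals an alphabet k-mer is exactly a window of the
// reverse-complemented read, so one pass computes both rows. Returns 0-based
// triplets (i, j, count).
// [[Rcpp::export]]
List cpp_featurize(CharacterVector seqs, int k, CharacterVector alphabet) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const int m = (int)alphabet.size();
  std::unordered_map<uint64_t, int> index;
  index.reserve((size_t)m * 2);
  for (int i = 0; i < m; ++i) {
    uint64_t code;
    if (!encode_kmer(CHAR(STRING_ELT(alphabet, i)), k, code))
      stop("non-ACGT character in alphabet k-mer");
    index[code] = i;
  }
  std::vector<int> cnt_plus((size_t)m, 0), cnt_minus((size_t)m, 0);
  std::vector<int> touched_plus, touched_minus;
  std::vector<int> out_i, out_j, out_x;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    touched_plus.clear();
    touched_minus.clear();
    for (const char* p = str; *p; ++p) {
      int b = base_code(*p);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
      if (run < k) ++run;
      if (run == k) {
        std::unordered_map<uint64_t, int>::const_iterator it = index.find(fwd);
        if (it != index.end()) {
          if (cnt_plus[(size_t)it->second]++ == 0) touched_plus.push_back(it->second);
        }
        it = index.find(rc);
        if (it != index.end()) {
          if (cnt_minus[(size_t)it->second]++ == 0) touched_minus.push_back(it->second);
        }
      }
    }
    std::sort(touched_plus.begin(), touched_plus.end());
    std::sort(touched_minus.begin(), touched_minus.end());
    for (size_t t = 0; t < touched_plus.size(); ++t) {
      int j = touched_plus[t];
      out_i.push_back(2 * (int)s);
      out_j.push_back(j);
      out_x.push_back(cnt_plus[(size_t)j]);
      cnt_plus[(size_t)j] = 0;
    }
    for (size_t t = 0; t < touched_minus.size(); ++t) {
      int j = touched_minus[t];
      out_i.push_back(2 * (int)s + 1);
      out_j.push_back(j);
      out_x.push_back(cnt_minus[(size_t)j]);
      cnt_minus[(size_t)j] = 0;
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}
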