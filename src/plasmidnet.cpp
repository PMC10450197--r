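#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Fixed seed so sketches are identical across runs and platforms.
static const uint64_t kHashSeed = 0x9c1f2d3a5b7e11c4ULL;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Bottom-s MinHash sketch over canonical k-mers.
//
// k-mers are 2-bit packed most-significant-base-first so numeric order of
// codes equals lexicographic order of the k-mer strings; the canonical form
// is the smaller of the forward and reverse-complement codes.  k-mers
// containing non-ACGT symbols are skipped.  Each distinct canonical code is
// hashed with seeded splitmix64 and the 64-bit value truncated to its top
// 53 bits so hashes are exactly representable as R doubles.
// [[Rcpp::export(name = ".sketch_seq_cpp")]]
List sketch_seq_cpp(const std::string& seq, int k, int s) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const int n = static_cast<int>(seq.size());
  if (n < k) stop("sequence too short to sketch");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int rc_shift = 2 * (k - 1);

  std::unordered_set<uint64_t> canon;
  canon.reserve(static_cast<size_t>(n));
  uint64_t fwd = 0, rc = 0;
  int run = 0;  // length of current valid-base run
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & mask;
    rc = (rc >> 2) | (static_cast<uint64_t>(3 - c) << rc_shift);
    if (++run >= k) canon.insert(std::min(fwd, rc));
  }

  std::vector<double> hashes;
  hashes.reserve(canon.size());
  for (uint64_t code : canon) {
    uint64_t h = splitmix64(code ^ kHashSeed) >> 11;  // top 53 bits
    hashes.push_back(static_cast<double>(h));
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  if (s > 0 && static_cast<int>(hashes.size()) > s) hashes.resize(s);

  return List::create(_["hashes"] = NumericVector(hashes.begin(), hashes.end()),
                      _["n_kmers"] = static_cast<double>(canon.size()));
}

// Booth's least-rotation algorithm: index of the lexicographically smallest
// rotation of s.
static size_t least_rotation_index(const std::string& s) {
  const size_t n = s.size();
  std::string ss = s + s;
  std::vector<long> f(2 * n, -1);
  size_t kidx = 0;
  for (size_t j = 1; j < 2 * n; ++j) {
    char sj = ss[j];
    long i = f[j - kidx - 1];
    while (i != -1 && sj != ss[kidx + i + 1]) {
      if (sj < ss[kidx + i + 1]) kidx = j - i - 1;
      i = f[i];
    }
    if (sj != ss[kidx + i + 1]) {
      if (sj < ss[kidx]) kidx = j;
      f[j - kidx] = -1;
    } else {
      f[j - kidx] = i + 1;
    }
  }
  return kidx;
}

// [[Rcpp::export(name = ".least_rotation_cpp")]]
std::string least_rotation_cpp(const std::string& s) {
  if (s.empty()) return s;
  size_t i = least_rotation_index(s);
  return s.substr(i) + s.substr(0, i);
}

// Longest direct terminal repeat: largest L in [min_len, n/2] such that the
// length-L prefix and suffix differ in at most max_mismatch positions.
// Returns c(length, n_mismatch), or c(-1, -1) when none is found.
// [[Rcpp::export(name = ".dtr_scan_cpp")]]
IntegerVector dtr_scan_cpp(const std::string& s, int min_len, int max_mismatch) {
  const int n = static_cast<int>(s.size());
  const int lmax = n / 2;
  for (int L = lmax; L >= min_len; --L) {
    int mism = 0;
    const char* pre = s.data();
    const char* suf = s.data() + (n - L);
    for (int i = 0; i < L; ++i) {
      if (pre[i] != suf[i] && ++mism > max_mismatch) break;
    }
    if (mism <= max_mismatch) return IntegerVector::create(L, mism);
  }
  return IntegerVector::create(-1, -1);
}
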