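#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// 64-bit mixing and string hashing used by the MinHash/LSH machinery.
// Fixed constants, no platform-dependent behaviour: signatures are
// reproducible across machines for a given seed.

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// splitmix64 finalizer: full-avalanche 64-bit mix. Used as the per-component
// hash function in MinHash so each component behaves like an independent
// random function of the token, making the collision-rate estimator of the
// Jaccard similarity unbiased.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a64(const char *s, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ seed;
  for (; *s; ++s) {
    h ^= (uint64_t)(unsigned char)(*s);
    h *= 1099511628211ULL;
  }
  return h;
}

// MinHash signatures for token sets.
// sets: list of integer vectors, 1-based indices into vocab.
// Each of the k hash functions is a seeded multiply-shift permutation of a
// per-token 64-bit base hash; the signature component is the 32-bit top
// slice of the minimum, exactly representable in a double.
// [[Rcpp::export]]
NumericMatrix cpp_minhash(List sets, CharacterVector vocab, int k, int seed) {
  const int n = sets.size();
  const int m = vocab.size();

  std::vector<uint64_t> base(m);
  uint64_t hs = 0x6D657468ULL ^ (uint64_t)(uint32_t)seed;
  uint64_t token_salt = splitmix64(hs);
  for (int v = 0; v < m; ++v)
    base[v] = fnv1a64(CHAR(STRING_ELT(vocab, v)), token_salt);

  std::vector<uint64_t> salt(k);
  for (int i = 0; i < k; ++i) salt[i] = splitmix64(hs);

  NumericMatrix sig(k, n);
  for (int j = 0; j < n; ++j) {
    IntegerVector s = sets[j];
    const int ns = s.size();
    if (ns == 0) stop("minhash: empty token set at position %d", j + 1);
    for (int i = 0; i < k; ++i) {
      uint64_t mn = UINT64_MAX;
      const uint64_t si = salt[i];
      for (int t = 0; t < ns; ++t) {
        uint64_t h = mix64(base[s[t] - 1] ^ si);
        if (h < mn) mn = h;
      }
      sig(i, j) = (double)(uint32_t)(mn >> 32);
    }
  }
  return sig;
}

// Band keys for banded LSH. sig is k x n (k = b * r). Returns b x n matrix of
// bucket keys: 52-bit hashes of each band's r signature values, exactly
// representable in doubles.
// [[Rcpp::export]]
NumericMatrix cpp_band_keys(NumericMatrix sig, int b, int r, int seed) {
  const int k = sig.nrow(), n = sig.ncol();
  if (b * r != k) stop("band/row mismatch: b * r must equal k");
  NumericMatrix keys(b, n);
  for (int j = 0; j < n; ++j) {
    for (int band = 0; band < b; ++band) {
      uint64_t h = 1469598103934665603ULL ^ (uint64_t)(uint32_t)seed;
      h ^= (uint64_t)(band + 1);
      h *= 1099511628211ULL;
      for (int row = 0; row < r; ++row) {
        uint64_t v = (uint64_t)sig(band * r + row, j);
        for (int byte = 0; byte < 8; ++byte) {
          h ^= (v >> (8 * byte)) & 0xFFULL;
          h *= 1099511628211ULL;
        }
      }
      keys(band, j) = (double)(h >> 12);
    }
  }
  return keys;
}

static inline int intersect_size(const int *a, int na, const int *b, int nb) {
  int i = 0, j = 0, out = 0;
  while (i < na && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++out; ++i; ++j; }
  }
  return out;
}

// Intersection sizes for given candidate pairs (two-pointer over sorted
// unique integer vectors). pairs is a 2-column matrix of 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_intersection_sizes(List sets, IntegerMatrix pairs) {
  const int np = pairs.nrow();
  std::vector<const int *> ptr(sets.size());
  std::vector<int> len(sets.size());
  for (int i = 0; i < (int)sets.size(); ++i) {
    IntegerVector s = sets[i];
    ptr[i] = INTEGER(s);
    len[i] = s.size();
  }
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    out[p] = intersect_size(ptr[i], len[i], ptr[j], len[j]);
  }
  return out;
}

// Exhaustive all-pairs containment scan (the brute-force oracle path).
// Emits every cross-document pair whose max-direction containment
// (|A∩B| / min(|A|,|B|)) reaches the threshold.
// [[Rcpp::export]]
List cpp_all_pairs(List sets, IntegerVector doc, double threshold) {
  const int n = sets.size();
  std::vector<const int *> ptr(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = sets[i];
    ptr[i] = INTEGER(s);
    len[i] = s.size();
  }
  std::vector<int> ii, jj, inter;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (doc[i] == doc[j]) continue;
      int mn = len[i] < len[j] ? len[i] : len[j];
      int isz = intersect_size(ptr[i], len[i], ptr[j], len[j]);
      if ((double)isz / (double)mn >= threshold) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        inter.push_back(isz);
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["inter"] = wrap(inter));
}

// FNV-1a of a whole string, masked to 52 bits; used for config hashes in
// output headers.
// [[Rcpp::export]]
double cpp_fnv52(std::string s) {
  uint64_t h = fnv1a64(s.c_str(), 0);
  return (double)(h >> 12);
}
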