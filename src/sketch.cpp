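#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <deque>
#include <string>
#include <vector>

using namespace Rcpp;

// Fixed seed XORed into the packed k-mer before mixing; makes the hash
// family explicit and reproducible across builds.
static const uint64_t HASH_SEED = 0xD6E8FEB86659FD93ULL;

// splitmix64 finalizer (Steele et al.); bijective on 64-bit ints.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:  return -1;
  }
}

static inline std::string hashHex(uint64_t h) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long) h);
  return std::string(buf);
}

static void checkParams(int k, int w) {
  if (k < 2 || k > 32) stop("k must be in [2, 32]");
  if (w < 1) stop("w must be >= 1");
}

// Canonical (strand-neutral) hashes of every k-mer start position of `seq`.
// Positions covering an ambiguous base get UINT64_MAX ("infinite" hash).
static void kmerHashes(const std::string &seq, int k,
                       std::vector<uint64_t> &H, std::vector<char> &S) {
  const int n = (int) seq.size();
  const int npos = n - k + 1;
  H.assign(npos > 0 ? npos : 0, UINT64_MAX);
  S.assign(npos > 0 ? npos : 0, '+');
  if (npos <= 0) return;

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int lastInvalid = -1;

  for (int i = 0; i < n; ++i) {
    const int c = baseCode(seq[i]);
    if (c < 0) {
      lastInvalid = i;
      fwd = 0; rc = 0;
    } else {
      fwd = ((fwd << 2) | (uint64_t) c) & mask;
      rc = (rc >> 2) | ((uint64_t) (3 - c) << shift);
    }
    const int p = i - k + 1;
    if (p >= 0 && lastInvalid < p) {
      const uint64_t hf = splitmix64(fwd ^ HASH_SEED);
      const uint64_t hr = splitmix64(rc ^ HASH_SEED);
      H[p] = hf <= hr ? hf : hr;
      S[p] = hf <= hr ? '+' : '-';
    }
  }
}

//' Ordered minimizer sketch of one sequence (C++ backend).
//'
//' For every window of w consecutive k-mers the k-mer with the minimum
//' canonical hash is selected (leftmost on ties); consecutive windows
//' selecting the same position collapse to one record. Windows in which all
//' k-mers overlap an ambiguous base yield no minimizer.
//'
//' @noRd
// [[Rcpp::export]]
DataFrame sketch_sequence_cpp(std::string seq, int k, int w) {
  checkParams(k, w);
  std::vector<uint64_t> H;
  std::vector<char> S;
  kmerHashes(seq, k, H, S);
  const int npos = (int) H.size();

  std::vector<int> outPos;
  std::vector<std::string> outHash;
  std::vector<std::string> outStrand;

  if (npos >= w) {
    std::deque<int> dq;  // indices with increasing hash; front = window min
    int lastSel = -1;
    for (int i = 0; i < npos; ++i) {
      while (!dq.empty() && H[dq.back()] > H[i]) dq.pop_back();
      dq.push_back(i);
      const int j = i - w + 1;  // window start
      if (j >= 0) {
        while (dq.front() < j) dq.pop_front();
        const int m = dq.front();
        if (H[m] != UINT64_MAX && m != lastSel) {
          outPos.push_back(m);
          outHash.push_back(hashHex(H[m]));
          outStrand.push_back(std::string(1, S[m]));
          lastSel = m;
        }
      }
    }
  }

  return DataFrame::create(
      _["pos"] = IntegerVector(outPos.begin(), outPos.end()),
      _["strand"] = CharacterVector(outStrand.begin(), outStrand.end()),
      _["hash"] = CharacterVector(outHash.begin(), outHash.end()),
      _["stringsAsFactors"] = false);
}

//' Strand-neutral hash of individual k-mers (vectorised).
//'
//' Returns the canonical hash (lower of forward and reverse-complement
//' hashes) as a 16-character lowercase hex string plus the winning strand.
//' K-mers containing non-ACGT characters yield NA.
//'
//' @noRd
// [[Rcpp::export]]
DataFrame canonical_hash_cpp(CharacterVector kmers) {
  const int n = kmers.size();
  CharacterVector hash(n), strand(n);
  for (int i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { hash[i] = NA_STRING; strand[i] = NA_STRING; continue; }
    const std::string km = as<std::string>(kmers[i]);
    const int k = (int) km.size();
    if (k < 2 || k > 32) stop("k-mer length must be in [2, 32]");
    std::vector<uint64_t> H;
    std::vector<char> S;
    kmerHashes(km, k, H, S);
    if (H[0] == UINT64_MAX) {
      hash[i] = NA_STRING;
      strand[i] = NA_STRING;
    } else {
      hash[i] = hashHex(H[0]);
      strand[i] = std::string(1, S[0]);
    }
  }
  return DataFrame::create(_["hash"] = hash, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
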