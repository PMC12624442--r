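#include "core.h"
using namespace Rcpp;

// Enumerate the K-mer records of a genome on both strands, keeping only
// K-mers whose first s bases are a closed (s,m) syncmer.  The syncmer test
// uses canonical m-mer values (min of the value of the m-mer and of its
// reverse complement), which makes the retained set strand-symmetric at the
// s-mer level.  Reverse-strand K-mers are the K-mers of the reverse
// complement of each contig; their positions are offsets on that strand.

namespace {

// canonical value of every m-mer of a code vector, rolling in O(n)
static void canon_values(const int *c, int len, int m, std::vector<long long> &out) {
  int nw = len - m + 1;
  out.resize(nw > 0 ? nw : 0);
  if (nw <= 0) return;
  long long hi = 1;  // 4^(m-1)
  for (int i = 1; i < m; ++i) hi *= 4;
  long long v = 0, w = 0;
  for (int i = 0; i < m; ++i) v = v * 4 + c[i];  // big-endian phi of window
  // phi of the reverse complement: little-endian in (3 - c)
  long long p4 = 1;
  for (int i = 0; i < m; ++i) { w += (long long)(3 - c[i]) * p4; p4 *= 4; }
  out[0] = v < w ? v : w;
  for (int q = 1; q < nw; ++q) {
    v = (v - (long long)c[q - 1] * hi) * 4 + c[q + m - 1];
    w = (w - (long long)(3 - c[q - 1])) / 4 + (long long)(3 - c[q + m - 1]) * hi;
    out[q] = v < w ? v : w;
  }
}

static bool syncmer_at(const std::vector<long long> &canon, int p, int s, int m) {
  int last = p + s - m;
  long long mn = canon[p];
  for (int q = p + 1; q <= last; ++q)
    if (canon[q] < mn) mn = canon[q];
  long long ends = canon[p] < canon[last] ? canon[p] : canon[last];
  return ends == mn;
}

}  // namespace

// contigs: list of integer code vectors.  Returns unsorted records.
// [[Rcpp::export]]
List cpp_build_records(List contigs, int K, int s, int m) {
  int kw = (K + 3) / 4;
  std::vector<uint8_t> keys;
  std::vector<int> ctg, pos, strand;
  std::vector<long long> canon;
  std::vector<int> rc;
  for (int ci = 0; ci < contigs.size(); ++ci) {
    IntegerVector cv = contigs[ci];
    int len = cv.size();
    if (len < K) continue;  // caller warns
    std::vector<int> fwd(cv.begin(), cv.end());
    rc.resize(len);
    for (int i = 0; i < len; ++i) rc[i] = 3 - fwd[len - 1 - i];
    for (int st = 0; st < 2; ++st) {
      const int *c = st == 0 ? fwd.data() : rc.data();
      canon_values(c, len, m, canon);
      int npos = len - K + 1;
      for (int p = 0; p < npos; ++p) {
        if (!syncmer_at(canon, p, s, m)) continue;
        size_t off = keys.size();
        keys.resize(off + kw);
        aa_pack_kmer(c + p, K, keys.data() + off, kw);
        ctg.push_back(ci + 1);
        pos.push_back(p);
        strand.push_back(st == 0 ? 1 : -1);
      }
    }
  }
  int n = (int)ctg.size();
  RawVector rkeys((R_xlen_t)n * kw);
  if (n) std::memcpy(RAW(rkeys), keys.data(), keys.size());
  return List::create(_["keys"] = rkeys, _["contig"] = wrap(ctg),
                      _["pos"] = wrap(pos), _["strand"] = wrap(strand),
                      _["n"] = n);
}

// Drop whole K-mer groups (runs of records with lcp == K, i.e. identical
// K-mers) whose occurrence count is >= tau, recomputing the lcp chain for
// the surviving records (lcp across a removed span is the min over the span).
// [[Rcpp::export]]
List cpp_tau_filter(IntegerVector lcp, int K, int tau) {
  int n = lcp.size();
  LogicalVector keep(n);
  IntegerVector newlcp(n);
  int i = 0;
  int carry = -1;              // pending min lcp since last kept record
  bool any_kept = false;
  while (i < n) {
    int j = i + 1;
    while (j < n && lcp[j] == K) ++j;  // group [i, j)
    int glcp = lcp[i];
    if (j - i < tau) {
      int first = any_kept ? std::min(carry < 0 ? glcp : carry, glcp) : 0;
      keep[i] = true;
      newlcp[i] = first;
      for (int t = i + 1; t < j; ++t) { keep[t] = true; newlcp[t] = K; }
      any_kept = true;
      carry = -1;
    } else {
      for (int t = i; t < j; ++t) keep[t] = false;
      carry = (carry < 0) ? glcp : std::min(carry, glcp);
    }
    i = j;
  }
  return List::create(_["keep"] = keep, _["lcp"] = newlcp);
}

// Check which records' first s bases pass the closed-syncmer test, given
// packed keys (used by tests to cross-check the builder against the R
// surface predicate).
// [[Rcpp::export]]
LogicalVector cpp_keys_syncmer(RawVector keys, int n, int kw, int s, int m) {
  LogicalVector out(n);
  std::vector<long long> canon;
  std::vector<int> codes(s);
  for (int i = 0; i < n; ++i) {
    const uint8_t *k = RAW(keys) + (size_t)i * kw;
    for (int j = 0; j < s; ++j) codes[j] = aa_key_base(k, j);
    canon_values(codes.data(), s, m, canon);
    out[i] = syncmer_at(canon, 0, s, m);
  }
  return out;
}
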