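#include "core.h"
using namespace Rcpp;

// In-place MSD radix sort over fixed-width byte keys (one byte per digit,
// sigma = 256), computing the longest-common-prefix array with each element's
// immediate predecessor as a side effect of the partitioning.
//
// Refinements implemented (beyond the plain recursive form):
//   - when only one partition interval is non-empty the depth is advanced
//     without any data movement (a block of identical prefixes is verified,
//     not moved);
//   - elements already inside their target partition are never moved;
//   - only the non-empty partition values are iterated during permutation.
//
// In DNA mode keys are 2-bit packed sequences and the lcp is reported in
// bases: at byte depth d, the first element of partition p whose non-empty
// predecessor partition is q has lcp 4d + 3 - floor(log4(p xor q)).

namespace {

struct MsdSorter {
  uint8_t *buf;    // n records of `stride` bytes (kw key bytes + 4-byte tag)
  int n, kw, stride;
  int *lcp;        // per sorted slot
  bool dna;
  int nbases;

  inline uint8_t key_at(int rec, int d) const {
    return buf[(size_t)rec * stride + d];
  }
  inline void swap_rec(int i, int j, uint8_t *tmp) {
    uint8_t *a = buf + (size_t)i * stride, *b = buf + (size_t)j * stride;
    std::memcpy(tmp, a, stride);
    std::memcpy(a, b, stride);
    std::memcpy(b, tmp, stride);
  }
  inline int full_lcp() const { return dna ? nbases : kw; }
  inline int boundary_lcp(int d, int p, int q) const {
    if (!dna) return d;
    int x = p ^ q;                       // > 0 between distinct partitions
    int l4 = (31 - __builtin_clz((unsigned)x)) >> 1;  // floor(log4 x)
    int bases = 4 * d + 3 - l4;
    return bases < nbases ? bases : nbases;
  }

  void sort(int lo, int hi, int d, uint8_t *tmp) {
    while (true) {
      if (hi - lo <= 1) return;
      if (d >= kw) {            // identical keys: lcp is the full width
        for (int i = lo + 1; i < hi; ++i) lcp[i] = full_lcp();
        return;
      }
      int cnt[256];
      std::memset(cnt, 0, sizeof(cnt));
      for (int i = lo; i < hi; ++i) cnt[key_at(i, d)]++;
      int vals[256], nv = 0;
      for (int v = 0; v < 256; ++v)
        if (cnt[v]) vals[nv++] = v;
      if (nv == 1) { d++; continue; }   // single non-empty partition: skip

      int start[256], fing[256], bound[256];
      int off = lo;
      for (int vi = 0; vi < nv; ++vi) {
        int v = vals[vi];
        start[v] = fing[v] = off;
        off += cnt[v];
        bound[v] = off;
      }
      // in-place permutation, skipping already-placed records
      for (int vi = 0; vi < nv; ++vi) {
        int v = vals[vi];
        int i = fing[v];
        while (i < bound[v]) {
          int y = key_at(i, d);
          if (y == v) {
            ++i;                         // already in its partition
          } else {
            swap_rec(i, fing[y], tmp);
            fing[y]++;
          }
        }
        fing[v] = i;
      }
      // lcp at partition boundaries, then recurse per partition
      for (int vi = 1; vi < nv; ++vi)
        lcp[start[vals[vi]]] = boundary_lcp(d, vals[vi], vals[vi - 1]);
      for (int vi = 0; vi < nv; ++vi)
        sort(start[vals[vi]], bound[vals[vi]], d + 1, tmp);
      return;
    }
  }
};

}  // namespace

// keys: flat raw vector, record i occupies bytes [i*kw, (i+1)*kw).
// Returns the sorted keys, the 1-based order permutation, and the lcp array
// (bytes, or bases when dna = TRUE with nbases real bases per key).
// [[Rcpp::export]]
List cpp_msd_sort(RawVector keys, int n, int kw, bool dna, int nbases) {
  if ((R_xlen_t)n * kw != keys.size()) stop("keys length is not n * kw");
  int stride = kw + 4;
  std::vector<uint8_t> buf((size_t)n * stride);
  for (int i = 0; i < n; ++i) {
    std::memcpy(&buf[(size_t)i * stride], RAW(keys) + (size_t)i * kw, kw);
    std::memcpy(&buf[(size_t)i * stride + kw], &i, 4);
  }
  std::vector<int> lcp(n, 0);
  if (n > 0) {
    MsdSorter s{buf.data(), n, kw, stride, lcp.data(), dna, nbases};
    std::vector<uint8_t> tmp(stride);
    s.sort(0, n, 0, tmp.data());
  }
  RawVector sorted((R_xlen_t)n * kw);
  IntegerVector order(n), lcpv(n);
  for (int i = 0; i < n; ++i) {
    std::memcpy(RAW(sorted) + (size_t)i * kw, &buf[(size_t)i * stride], kw);
    int tag;
    std::memcpy(&tag, &buf[(size_t)i * stride + kw], 4);
    order[i] = tag + 1;
    lcpv[i] = lcp[i];
  }
  return List::create(_["keys"] = sorted, _["order"] = order,
                      _["lcp"] = lcpv);
}
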