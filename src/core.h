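#ifndef ADAPTALIGN_CORE_H
#define ADAPTALIGN_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

// Shared helpers for 2-bit DNA codes (a=0, c=1, g=2, t=3).

static inline int aa_base_code(char c) {
  switch (c) {
    case 'a': case 'A': return 0;
    case 'c': case 'C': return 1;
    case 'g': case 'G': return 2;
    case 't': case 'T': return 3;
    default: return -1;
  }
}

static const char AA_BASES[4] = {'a', 'c', 'g', 't'};

// base j (0-based) of a packed key: byte j>>2, big-endian within the byte
static inline int aa_key_base(const uint8_t *key, int j) {
  return (key[j >> 2] >> (2 * (3 - (j & 3)))) & 3;
}

static inline void aa_pack_kmer(const int *codes, int K, uint8_t *out, int kw) {
  std::memset(out, 0, kw);
  for (int j = 0; j < K; ++j)
    out[j >> 2] |= (uint8_t)(codes[j] << (2 * (3 - (j & 3))));
}

// Path op codes shared with the R side:
//   0 = diagonal step (match or substitution, consumes one base of A and B)
//   1 = consumes one base of B only (insertion in B / dash in A)
//   2 = consumes one base of A only (deletion from B / dash in B)
#define OP_DIAG 0
#define OP_INSB 1
#define OP_DELB 2

#endif
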