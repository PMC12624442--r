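#include "core.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_seq_to_codes(std::string seq) {
  int n = (int)seq.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = aa_base_code(seq[i]);
    if (c < 0)
      stop("invalid DNA base '%c' at position %d", seq[i], i + 1);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_codes_to_seq(IntegerVector codes) {
  std::string out(codes.size(), 'a');
  for (int i = 0; i < (int)codes.size(); ++i) out[i] = AA_BASES[codes[i] & 3];
  return out;
}

// [[Rcpp::export]]
RawVector cpp_pack_codes(IntegerVector codes) {
  int n = codes.size(), nb = (n + 3) / 4;
  RawVector out(nb);
  std::memset(RAW(out), 0, nb);
  for (int i = 0; i < n; ++i)
    out[i >> 2] |= (Rbyte)((codes[i] & 3) << (2 * (3 - (i & 3))));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_codes(RawVector packed, int n) {
  IntegerVector out(n);
  const uint8_t *p = RAW(packed);
  for (int i = 0; i < n; ++i) out[i] = aa_key_base(p, i);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  int n = (int)seq.size();
  std::string out(n, 'a');
  for (int i = 0; i < n; ++i) {
    int c = aa_base_code(seq[i]);
    if (c < 0)
      stop("invalid DNA base '%c' at position %d", seq[i], i + 1);
    out[n - 1 - i] = AA_BASES[3 - c];
  }
  return out;
}
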