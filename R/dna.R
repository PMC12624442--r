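#' Reverse complement of a DNA string
#'
#' Complements (`a<->t`, `c<->g`) and reverses a sequence over the alphabet
#' `{a,c,g,t}` (case-insensitive; output is lower case).  The operation is
#' an involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq a single DNA string over `{a,c,g,t}` (upper or lower case).
#' @return the reverse-complemented string, lower case.
#' @examples
#' reverse_complement("aaac")  # "gttt"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_revcomp(seq)
}

#' Pack and unpack DNA as 2-bit codes
#'
#' `dna_pack()` stores a DNA string at 2 bits per base (a=0, c=1, g=2, t=3,
#' four bases per byte, big-endian within the byte); `dna_unpack()` inverts
#' it given the length in bases.  Packing is lossless for `{a,c,g,t}` but
#' forgets case.
#'
#' @param seq DNA string over `{a,c,g,t}`.
#' @param packed raw vector from `dna_pack()`.
#' @param n sequence length in bases.
#' @return `dna_pack()`: a raw vector of `ceiling(n/4)` bytes;
#'   `dna_unpack()`: the DNA string, lower case.
#' @export
dna_pack <- function(seq) {
  cpp_pack_codes(cpp_seq_to_codes(seq))
}

#' @rdname dna_pack
#' @export
dna_unpack <- function(packed, n) {
  cpp_codes_to_seq(cpp_unpack_codes(packed, n))
}

#' Random DNA string
#'
#' Uniform i.i.d. DNA of a given length, drawn from the current R RNG
#' stream (call `set.seed()` for reproducibility).
#'
#' @param n length in bases.
#' @return a DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
}

# internal: string -> integer codes / back
seq_codes <- function(seq) cpp_seq_to_codes(seq)
codes_seq <- function(codes) cpp_codes_to_seq(codes)
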