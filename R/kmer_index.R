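#' Index parameters
#'
#' Parameters of the truncated-suffix-array genome index: K-mer length `K`,
#' syncmer window `s` and minimizer-length `m` (a K-mer is indexed only if
#' its first `s` bases form a closed (s,m) syncmer), and the repetitiveness
#' threshold `tau` (K-mers occurring `tau` or more times in genome +
#' complement are excluded; adaptamer ranges covering more than `tau`
#' positions are suppressed at merge time).
#'
#' @param K K-mer length in bases (default 40).
#' @param s syncmer window length, `m < s <= K` (default 12).
#' @param m syncmer m-mer length (default 8).
#' @param tau maximum occurrence count (default 10).
#' @return a list of class `IndexParams`.
#' @export
index_params <- function(K = 40L, s = 12L, m = 8L, tau = 10L) {
  K <- as.integer(K); s <- as.integer(s); m <- as.integer(m)
  tau <- as.integer(tau)
  stopifnot(m < s, s <= K, tau >= 1L, m >= 1L)
  structure(list(K = K, s = s, m = m, tau = tau), class = "IndexParams")
}

#' Integer value of a DNA string
#'
#' `phi_value()` evaluates a DNA string as a big-endian base-4 number with
#' a=0, c=1, g=2, t=3; it is order-isomorphic to lexicographic order.
#' `canonical_value()` is the smaller of the value of the string and of its
#' reverse complement, making the result strand-symmetric.
#'
#' @param seq DNA string over `{a,c,g,t}` (case-insensitive).
#' @return a non-negative numeric value (exact for strings up to 26 bases).
#' @examples
#' phi_value("acgt")        # 27
#' canonical_value("ttgc")  # phi_value("gcaa") == 144
#' @export
phi_value <- function(seq) {
  codes <- cpp_seq_to_codes(seq)
  n <- length(codes)
  if (n > 26L) stop("phi_value supports strings up to 26 bases")
  sum(codes * 4^((n - 1L):0))
}

#' @rdname phi_value
#' @export
canonical_value <- function(seq) {
  min(phi_value(seq), phi_value(reverse_complement(seq)))
}

#' Closed syncmer test
#'
#' A k-mer is a closed (k,m) syncmer when the minimum canonical m-mer value
#' over all its m-mer windows is attained at the first or last window.  For
#' K-mer indexing the test is applied to the first `s` bases of each K-mer,
#' so `kmer` may be longer than `s`; only its `s`-prefix is examined.
#'
#' @param kmer DNA string of length at least `s`.
#' @param s window length.
#' @param m m-mer length, `m < s`.
#' @return logical.
#' @examples
#' is_closed_syncmer("aaaat", 5, 3)  # TRUE
#' is_closed_syncmer("caaat", 5, 3)  # FALSE (interior minimum)
#' @export
is_closed_syncmer <- function(kmer, s, m) {
  if (nchar(kmer) < s || s <= m)
    stop("need length(kmer) >= s > m")
  pre <- substr(kmer, 1L, s)
  vals <- vapply(1L:(s - m + 1L),
                 function(q) canonical_value(substr(pre, q, q + m - 1L)),
                 numeric(1))
  min(vals[1L], vals[length(vals)]) == min(vals)
}

#' Syncmer-retained positions of a sequence
#'
#' Positions (0-based) whose `s`-mer is a closed (s,m) syncmer, computed
#' with vectorised canonical m-mer values.  Used to study the density and
#' spacing of the syncmer subsample.
#'
#' @param seq DNA string.
#' @inheritParams is_closed_syncmer
#' @return integer vector of 0-based positions, in increasing order.
#' @export
syncmer_positions <- function(seq, s, m) {
  codes <- as.numeric(cpp_seq_to_codes(seq))
  n <- length(codes)
  if (n < s) return(integer(0))
  nw <- n - m + 1L
  # big-endian phi of each m-window via rolling evaluation
  v <- numeric(nw); w <- numeric(nw)
  v[1L] <- sum(codes[1:m] * 4^((m - 1L):0))
  w[1L] <- sum((3 - codes[1:m]) * 4^(0:(m - 1L)))
  if (nw > 1L) {
    hi <- 4^(m - 1L)
    for (q in 2L:nw) {
      v[q] <- (v[q - 1L] - codes[q - 1L] * hi) * 4 + codes[q + m - 1L]
      w[q] <- (w[q - 1L] - (3 - codes[q - 1L])) / 4 +
        (3 - codes[q + m - 1L]) * hi
    }
  }
  canon <- pmin(v, w)
  nwin <- s - m + 1L
  npos <- n - s + 1L
  mins <- canon[1:npos]
  for (o in 1L:(nwin - 1L)) mins <- pmin(mins, canon[(1L + o):(npos + o)])
  ends <- pmin(canon[1:npos], canon[(1L + nwin - 1L):(npos + nwin - 1L)])
  which(ends == mins) - 1L
}

#' MSD radix sort with lcp side-computation
#'
#' Sorts equal-width byte strings with a most-significant-digit in-place
#' radix sort (one byte per digit) and returns, for every element, the
#' length of its longest common prefix with its immediate predecessor in
#' the sorted order.  The sort skips recursion when only one partition is
#' non-empty and never moves an element already inside its partition.
#'
#' @param items a raw matrix with one column per item (equal byte width),
#'   or a character vector of equal-length strings.
#' @return a list with `sorted` (same shape as the input), `order` (1-based
#'   permutation such that `items[, order]` is sorted) and `lcp` (integer,
#'   in bytes; `lcp[1] == 0`).
#' @export
msd_radix_sort_with_lcp <- function(items) {
  if (is.character(items)) {
    widths <- unique(nchar(items, type = "bytes"))
    if (length(widths) > 1L) stop("items must have equal width")
    mat <- vapply(items, charToRaw, raw(if (length(widths)) widths else 0L))
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = max(widths, 1L))
    res <- msd_radix_sort_with_lcp(mat)
    res$sorted <- apply(res$sorted, 2L, rawToChar)
    return(res)
  }
  stopifnot(is.raw(items), is.matrix(items))
  kw <- nrow(items); n <- ncol(items)
  out <- cpp_msd_sort(as.vector(items), n, kw, FALSE, 0L)
  list(sorted = matrix(out$keys, nrow = kw), order = out$order,
       lcp = out$lcp)
}

#' Sort 2-bit packed DNA keys, lcp in bases
#'
#' Same sort as [msd_radix_sort_with_lcp()] over 2-bit packed DNA keys,
#' with the lcp reported in bases.  At byte depth `d` the lcp of the first
#' element of partition `p` with its predecessor in partition `q < p` is
#' `4d + 3 - floor(log4(xor(p, q)))` bases, computed during partitioning.
#'
#' @param keys raw matrix, one packed key per column.
#' @param nbases number of bases per key.
#' @return list with `sorted`, `order`, `lcp` (bases).
#' @export
msd_sort_dna <- function(keys, nbases) {
  stopifnot(is.raw(keys), is.matrix(keys), nrow(keys) >= ceiling(nbases / 4))
  kw <- nrow(keys); n <- ncol(keys)
  out <- cpp_msd_sort(as.vector(keys), n, kw, TRUE, as.integer(nbases))
  list(sorted = matrix(out$keys, nrow = kw), order = out$order,
       lcp = out$lcp)
}

#' Build a genome index
#'
#' Builds the truncated-suffix-array index of a genome: every K-mer of the
#' genome and its complement whose first `s` bases are a closed (s,m)
#' syncmer and whose total occurrence count (both strands) is below `tau`,
#' sorted by K-mer with the lcp array computed during the sort.  Reverse-
#' strand K-mers are the K-mers of the reverse complement of each contig,
#' with positions recorded as offsets on that strand and a strand flag.
#'
#' @param gdb a [fasta_to_gdb()] `GenomeDB`.
#' @param params an [index_params()] object.
#' @return an object of class `GenomeIndex` with `n` records, packed sorted
#'   `keys`, parallel vectors `contig`, `pos`, `strand` (+1/-1), the `lcp`
#'   array (bases), `params` and the source contig lengths.
#' @export
build_index <- function(gdb, params = index_params()) {
  stopifnot(inherits(gdb, "GenomeDB"), inherits(params, "IndexParams"))
  K <- params$K
  short <- gdb$contigs$length < K
  if (any(short))
    warning(sum(short), " contig(s) shorter than K = ", K, " skipped")
  codes <- lapply(seq_len(nrow(gdb$contigs)),
                  function(i) cpp_seq_to_codes(contig_seq(gdb, i)))
  rec <- cpp_build_records(codes, K, params$s, params$m)
  kw <- as.integer(ceiling(K / 4))
  srt <- cpp_msd_sort(rec$keys, rec$n, kw, TRUE, K)
  flt <- cpp_tau_filter(srt$lcp, K, params$tau)
  keep <- flt$keep
  ord <- srt$order[keep]
  kmat <- matrix(srt$keys, nrow = kw)
  structure(list(
    n = sum(keep),
    keys = as.vector(kmat[, keep, drop = FALSE]),
    contig = rec$contig[ord],
    pos = rec$pos[ord],
    strand = rec$strand[ord],
    lcp = flt$lcp[keep],
    params = params,
    contig_len = gdb$contigs$length
  ), class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  p <- x$params
  cat("GenomeIndex:", x$n, "records (K =", p$K, ", s =", p$s, ", m =", p$m,
      ", tau =", p$tau, ")\n")
  invisible(x)
}

#' K-mer string of an index record
#' @param index a [build_index()] `GenomeIndex`.
#' @param i record number (1-based, sorted order).
#' @return the K-mer as a DNA string.
#' @export
index_kmer <- function(index, i) {
  K <- index$params$K
  kw <- as.integer(ceiling(K / 4))
  off <- (i - 1L) * kw
  dna_unpack(index$keys[(off + 1L):(off + kw)], K)
}

#' Read and write a genome index as an ASCII document
#'
#' The index is persisted as an ONEcode-style ASCII document: a header with
#' provenance, schema and count lines, then one `R` line per record
#' (contig, position, strand, lcp) and `K` lines carrying the packed K-mer
#' bytes in hex.  `read_gix()` restores the `GenomeIndex` losslessly.
#'
#' @param index a `GenomeIndex`.
#' @param path file path.
#' @return `write_gix()`: invisibly `path`; `read_gix()`: a `GenomeIndex`.
#' @export
write_gix <- function(index, path) {
  p <- index$params
  kw <- as.integer(ceiling(p$K / 4))
  hdr <- c("1 gix 1 0",
           paste("!", "adaptalign", as.character(utils::packageVersion("adaptalign"))),
           "~ P 4 INT INT INT INT",
           "~ L 1 INT_LIST",
           "~ R 4 INT INT INT INT",
           "~ K 1 HEX",
           paste("# R", index$n),
           paste("# K", index$n),
           paste("P", p$K, p$s, p$m, p$tau),
           paste("L", length(index$contig_len),
                 paste(index$contig_len, collapse = " ")))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (index$n > 0L) {
    kmat <- matrix(index$keys, nrow = kw)
    hex <- apply(kmat, 2L, function(x) paste(format(x), collapse = ""))
    writeLines(paste("R", index$contig, index$pos, index$strand, index$lcp),
               con)
    writeLines(paste("K", hex), con)
  }
  invisible(path)
}

#' @rdname write_gix
#' @export
read_gix <- function(path) {
  lines <- readLines(path)
  code <- substr(lines, 1L, 1L)
  pv <- scan(text = sub("^P ", "", lines[code == "P"]), quiet = TRUE)
  lv <- scan(text = sub("^L ", "", lines[code == "L"]), quiet = TRUE)
  contig_len <- as.integer(lv[-1L])
  rl <- lines[code == "R"]
  km <- lines[code == "K"]
  n <- length(rl)
  params <- index_params(pv[1L], pv[2L], pv[3L], pv[4L])
  kw <- as.integer(ceiling(params$K / 4))
  if (n > 0L) {
    rm <- matrix(scan(text = sub("^R ", "", rl), quiet = TRUE),
                 ncol = 4L, byrow = TRUE)
    hex <- sub("^K ", "", km)
    keys <- as.vector(vapply(hex, function(h)
      as.raw(strtoi(substring(h, seq(1L, 2L * kw, 2L),
                              seq(2L, 2L * kw, 2L)), 16L)), raw(kw)))
  } else {
    rm <- matrix(integer(0), ncol = 4L)
    keys <- raw(0)
  }
  structure(list(n = n, keys = keys, contig = as.integer(rm[, 1L]),
                 pos = as.integer(rm[, 2L]), strand = as.integer(rm[, 3L]),
                 lcp = as.integer(rm[, 4L]), params = params,
                 contig_len = contig_len),
            class = "GenomeIndex")
}
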