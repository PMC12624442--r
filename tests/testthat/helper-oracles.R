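# Independent oracles used across the suite.  All are deliberately naive
# re-derivations (string comparisons, dense DP, enumeration), kept separate
# from the code paths they check.

# longest common prefix of two strings, in characters
lcp_chars <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  l <- 0L
  while (l < n && substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L))
    l <- l + 1L
  l
}

# pairwise-lcp array of a sorted character vector
lcp_array_oracle <- function(sorted) {
  n <- length(sorted)
  if (n == 0L) return(integer(0))
  c(0L, vapply(seq_len(n - 1L) + 1L,
               function(i) lcp_chars(sorted[i - 1L], sorted[i]),
               integer(1)))
}

# all K-mer strings of one index, in sorted record order
index_kmers <- function(ix) {
  if (ix$n == 0L) return(character(0))
  vapply(seq_len(ix$n), function(i) index_kmer(ix, i), character(1))
}

# brute-force adaptamer merge: for every forward record of G, the longest
# prefix of its K-mer present as a prefix of any H K-mer, all matching H
# records, subject to the repetitiveness threshold and the length floor
merge_oracle <- function(G, H, tau, min_len) {
  K <- G$params$K
  gk <- index_kmers(G)
  hk <- index_kmers(H)
  hpre <- lapply(seq_len(K), function(l) substr(hk, 1L, l))
  out <- list()
  for (gi in which(G$strand > 0L)) {
    L <- 0L
    while (L < K && any(hpre[[L + 1L]] == substr(gk[gi], 1L, L + 1L)))
      L <- L + 1L
    if (L < min_len) next
    mt <- which(hpre[[L]] == substr(gk[gi], 1L, L))
    if (length(mt) > tau) next
    ph <- H$pos[mt]
    neg <- H$strand[mt] < 0L
    ph[neg] <- H$contig_len[H$contig[mt[neg]]] - ph[neg] - L
    out[[length(out) + 1L]] <- data.frame(
      contig_g = G$contig[gi], pos_g = G$pos[gi], contig_h = H$contig[mt],
      pos_h = ph, strand = ifelse(H$strand[mt] > 0L, "+", "-"), t = L,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# canonical string form of a hit set for comparison
hit_key <- function(h) {
  if (is.null(h) || nrow(h) == 0L) return(character(0))
  sort(paste(h$contig_g, h$pos_g, h$contig_h, h$pos_h, h$strand, h$t))
}

# dense insertion-only DP minimising gaps + mismatches over a trapezoid
# (gap-open 1, gap-extend 0, mismatch 1); independent of the wave path
refine_dp_oracle <- function(Aseg, Bseg) {
  ac <- strsplit(Aseg, "")[[1L]]
  bc <- strsplit(Bseg, "")[[1L]]
  L <- length(ac)
  D <- length(bc) - L
  INF <- 1e9
  C <- matrix(INF, L + 1L, D + 1L)   # arrived on a diagonal edge
  I <- matrix(INF, L + 1L, D + 1L)   # arrived on an insertion edge
  C[1L, 1L] <- 0
  for (i in 0:L) {
    for (g in 0:D) {
      if (g > 0L) I[i + 1L, g + 1L] <- min(C[i + 1L, g] + 1, I[i + 1L, g])
      if (i > 0L) {
        mis <- as.integer(ac[i] != bc[i + g])
        C[i + 1L, g + 1L] <- min(C[i, g + 1L], I[i, g + 1L]) + mis
      }
      if (i == 0L && g > 0L) C[i + 1L, g + 1L] <- INF
    }
  }
  min(C[L + 1L, D + 1L], I[L + 1L, D + 1L])
}

# exhaustive enumeration over all monotone placements of D insertions
# (feasible for small L, D): minimum of gaps + mismatches
refine_enum_oracle <- function(Aseg, Bseg) {
  ac <- strsplit(Aseg, "")[[1L]]
  bc <- strsplit(Bseg, "")[[1L]]
  L <- length(ac)
  D <- length(bc) - L
  combs <- utils::combn(L + D, D)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    ins_at <- combs[, ci] - seq_len(D)   # non-decreasing values in 0..L
    gaps <- length(unique(ins_at))
    nins <- tabulate(ins_at + 1L, nbins = L + 1L)
    bi <- 0L
    mism <- 0L
    for (col in seq_len(L)) {
      bi <- bi + nins[col] + 1L
      if (ac[col] != bc[bi]) mism <- mism + 1L
    }
    best <- min(best, gaps + mism)
  }
  best
}

# differences of a path recomputed against the sequences
path_diffs_oracle <- function(ops, a, b, ab = 0L, bb = 0L) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  i <- ab; j <- bb; d <- 0L
  for (op in ops) {
    if (op == 0L) {
      i <- i + 1L; j <- j + 1L
      if (ac[i] != bc[j]) d <- d + 1L
    } else if (op == 1L) {
      j <- j + 1L; d <- d + 1L
    } else {
      i <- i + 1L; d <- d + 1L
    }
  }
  d
}

# parse a CIGAR string back into op runs
cigar_runs <- function(cg) {
  m <- gregexpr("[0-9]+[MIDX=]", cg)[[1L]]
  toks <- regmatches(cg, list(m))[[1L]]
  data.frame(len = as.integer(sub("[MIDX=]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}
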