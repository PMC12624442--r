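#' Chaining parameters
#'
#' @param D diagonal band width (default 64).  Chains are sought in merged
#'   pairs of adjacent bands, so chains up to width `2D` are admitted.
#' @param A maximum anti-diagonal gap between consecutive seeds of a chain
#'   (default 1000).
#' @param min_chain_seeds minimum number of seeds per chain (default 1).
#' @return a list of class `ChainParams`.
#' @export
chain_params <- function(D = 64L, A = 1000L, min_chain_seeds = 1L) {
  D <- as.integer(D); A <- as.integer(A)
  stopifnot(D >= 1L, A >= 1L, min_chain_seeds >= 1L)
  structure(list(D = D, A = A,
                 min_chain_seeds = as.integer(min_chain_seeds)),
            class = "ChainParams")
}

#' Convert seed hits to sorted diagonal-band records
#'
#' Each seed hit `(pi, pj, t)` in the matrix of contig_g versus contig_h
#' becomes the sextuple `(contig_g, contig_h, b, a, r, t)` with band
#' `b = floor((pi - pj)/D)`, anti-diagonal `a = pi + pj` and remainder
#' `r = (pi - pj) mod D`, from which `pi = (a + (D b + r))/2` and
#' `pj = (a - (D b + r))/2` are reconstructed exactly.  Reverse-strand hits
#' are first mapped to the complement coordinates of contig_h
#' (`pj = len_h - pos_h - t`) so that diagonals are consistent, and the
#' strand is part of the sort key: the records come back ordered on
#' (contig_g, contig_h, strand, b, a).
#'
#' @param hits seed-hit data.frame from [merge_indices()] or
#'   [symmetric_merge()].
#' @param params a [chain_params()] object.
#' @return a data.frame of band records with columns `contig_g`,
#'   `contig_h`, `strand`, `b`, `a`, `r`, `t`.
#' @export
hits_to_band_records <- function(hits, params = chain_params()) {
  D <- params$D
  if (nrow(hits) == 0L)
    return(data.frame(contig_g = integer(0), contig_h = integer(0),
                      strand = character(0), b = integer(0), a = integer(0),
                      r = integer(0), t = integer(0)))
  pj <- ifelse(hits$strand == "-", hits$len_h - hits$pos_h - hits$t,
               hits$pos_h)
  pi <- hits$pos_g
  diag <- pi - pj
  rec <- data.frame(contig_g = hits$contig_g, contig_h = hits$contig_h,
                    strand = hits$strand, b = diag %/% D, a = pi + pj,
                    r = diag %% D, t = hits$t, stringsAsFactors = FALSE)
  rec[order(rec$contig_g, rec$contig_h, rec$strand, rec$b, rec$a), ,
      drop = FALSE]
}

#' Find seed chains and their tubes
#'
#' Merges the seeds of each pair of adjacent bands (b, b+1) in anti-diagonal
#' order and cuts chains wherever the anti-diagonal gap from the end of one
#' seed to the start of the next exceeds `A`.  Every seed therefore belongs
#' to at least one chain (via the band pairs (b-1,b) and (b,b+1)); chains
#' discovered twice with the same seed set are deduplicated.  Each chain is
#' returned as its tube: the rectangle bounded by the chain's extreme
#' diagonals and anti-diagonals, both seed ends included.
#'
#' @param records sorted band records from [hits_to_band_records()].
#' @param params a [chain_params()] object.
#' @return a data.frame of tubes: `contig_g`, `contig_h`, `strand`,
#'   `d_low`, `d_high`, `a_low`, `a_high`, `n_seeds`.
#' @export
find_chains <- function(records, params = chain_params()) {
  empty <- data.frame(contig_g = integer(0), contig_h = integer(0),
                      strand = character(0), d_low = integer(0),
                      d_high = integer(0), a_low = integer(0),
                      a_high = integer(0), n_seeds = integer(0))
  if (nrow(records) == 0L) return(empty)
  A <- params$A
  diag0 <- params$D * records$b + records$r
  # duplicate each seed into the band pairs (b-1, b) and (b, b+1)
  idx <- rep(seq_len(nrow(records)), 2L)
  p <- c(records$b - 1L, records$b)
  g <- records$contig_g[idx]; h <- records$contig_h[idx]
  s <- records$strand[idx]; a <- records$a[idx]; t <- records$t[idx]
  d <- diag0[idx]; seed <- idx
  o <- order(g, h, s, p, a, seed)
  g <- g[o]; h <- h[o]; s <- s[o]; p <- p[o]; a <- a[o]; t <- t[o]
  d <- d[o]; seed <- seed[o]
  n2 <- length(g)
  newgrp <- c(TRUE, g[-1L] != g[-n2] | h[-1L] != h[-n2] |
                s[-1L] != s[-n2] | p[-1L] != p[-n2])
  gap <- c(0L, a[-1L] - (a[-n2] + 2L * t[-n2]))
  brk <- newgrp | gap > A
  starts <- which(brk)
  ends <- c(starts[-1L] - 1L, n2)
  nc <- length(starts)
  size <- ends - starts + 1L
  d_low <- d_high <- a_low <- a_high <- integer(nc)
  sig <- character(nc)
  sing <- size == 1L
  ss <- starts[sing]
  d_low[sing] <- d[ss]; d_high[sing] <- d[ss]
  a_low[sing] <- a[ss]; a_high[sing] <- a[ss] + 2L * t[ss]
  sig[sing] <- as.character(seed[ss])
  for (ci in which(!sing)) {
    ii <- starts[ci]:ends[ci]
    d_low[ci] <- min(d[ii]); d_high[ci] <- max(d[ii])
    a_low[ci] <- a[ii[1L]]; a_high[ci] <- max(a[ii] + 2L * t[ii])
    sig[ci] <- paste(sort(seed[ii]), collapse = ",")
  }
  # deduplicate chains reported from both adjacent band pairs
  keep <- !duplicated(paste(g[starts], h[starts], s[starts], sig)) &
    size >= params$min_chain_seeds
  out <- data.frame(contig_g = g[starts], contig_h = h[starts],
                    strand = s[starts], d_low = d_low, d_high = d_high,
                    a_low = a_low, a_high = a_high, n_seeds = size,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
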