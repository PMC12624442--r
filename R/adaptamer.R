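#' Adaptamer seed matches by linear index merge
#'
#' Merges two genome indices in sorted K-mer order and reports, for every
#' forward-strand K-mer of the first index, its adaptamer in the second
#' genome: the longest prefix (capped at K) that occurs in the second index,
#' together with every position at which it occurs.  Ranges covering more
#' than `tau` positions are repetitive and suppressed; the range end is
#' capped at `fst + tau + 1` during the sweep, which marks such ranges
#' without affecting correctness.  The sweep carries its state (`fst`,
#' `lst`, `L`, `cur`, `wall`) from one K-mer to the next using only the two
#' lcp chains, so the whole merge is a single linear scan.
#'
#' @param G,H `GenomeIndex` objects built with the same `K` ([build_index()]).
#'   `G` contributes forward-strand records only; `H` contributes both
#'   strands.
#' @param tau repetitiveness threshold; defaults to the indices' `tau`.
#' @param min_len minimum reported adaptamer length in bases; defaults to
#'   the syncmer window `s` (shorter matches are lost by syncmer
#'   subsampling anyway and a floor guards the degenerate empty-prefix
#'   range).
#' @param debug if `TRUE`, attach the per-K-mer sweep state (`fst`, `lst`,
#'   `L` over H K-mer groups) as attribute `"debug"` for inspection.
#' @return a data.frame of seed hits: `contig_g`, `pos_g` (forward strand),
#'   `contig_h`, `pos_h` (forward-strand coordinates of contig_h), `strand`
#'   (`"+"`/`"-"`, orientation of the H occurrence), `t` (match length in
#'   bases), and `len_h` (contig_h length, carried for later coordinate
#'   conversions).  Attribute `"char_cmps"` counts symbol comparisons spent
#'   by the sweep.
#' @seealso [symmetric_merge()], [hits_to_band_records()]
#' @export
merge_indices <- function(G, H, tau = NULL, min_len = NULL, debug = FALSE) {
  stopifnot(inherits(G, "GenomeIndex"), inherits(H, "GenomeIndex"))
  if (G$params$K != H$params$K)
    stop("indices were built with different K (", G$params$K, " vs ",
         H$params$K, ")")
  K <- G$params$K
  if (is.null(tau)) tau <- H$params$tau
  if (is.null(min_len)) min_len <- G$params$s
  kw <- as.integer(ceiling(K / 4))
  res <- cpp_merge_indices(G$keys, G$lcp, G$contig, G$pos, G$strand,
                           H$keys, H$lcp, H$contig, H$pos, H$strand,
                           K, kw, as.integer(tau), as.integer(min_len),
                           debug)
  strand <- ifelse(res$strand > 0L, "+", "-")
  pos_h <- res$pos_h
  neg <- res$strand < 0L
  if (any(neg)) {
    clen <- H$contig_len[res$contig_h[neg]]
    pos_h[neg] <- clen - res$pos_h[neg] - res$t[neg]
  }
  hits <- data.frame(contig_g = res$contig_g, pos_g = res$pos_g,
                     contig_h = res$contig_h, pos_h = pos_h,
                     strand = strand, t = res$t,
                     len_h = H$contig_len[res$contig_h],
                     stringsAsFactors = FALSE)
  attr(hits, "char_cmps") <- res$char_cmps
  if (debug) attr(hits, "debug") <- res$debug
  hits
}

#' Symmetric adaptamer merge
#'
#' Adaptamers are maximal only on the first-genome side, so the directed
#' merge of G versus H need not find the adaptamers of H.  The symmetric
#' mode runs both directed merges and takes the union of the seed
#' locations, deduplicated on (contig_g, contig_h, pos_g, pos_h, strand).
#'
#' @inheritParams merge_indices
#' @return a seed-hit data.frame as in [merge_indices()].
#' @export
symmetric_merge <- function(G, H, tau = NULL, min_len = NULL) {
  fwd <- merge_indices(G, H, tau = tau, min_len = min_len)
  rev <- merge_indices(H, G, tau = tau, min_len = min_len)
  # map H->G hits into (G, H) orientation: merge_indices() reports both
  # positions in forward coordinates, so the roles simply swap; a hit whose
  # G occurrence was reverse-strand stays a "-" hit in (G fwd, H rc) form
  if (nrow(rev)) {
    rev2 <- data.frame(contig_g = rev$contig_h, pos_g = rev$pos_h,
                       contig_h = rev$contig_g, pos_h = rev$pos_g,
                       strand = rev$strand, t = rev$t,
                       len_h = H$contig_len[rev$contig_g],
                       stringsAsFactors = FALSE)
  } else {
    rev2 <- fwd[0, ]
  }
  all <- rbind(fwd, rev2)
  key <- paste(all$contig_g, all$contig_h, all$pos_g, all$pos_h, all$strand)
  out <- all[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
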