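#' Alignment search parameters
#'
#' @param min_length minimum A-span of a reported alignment, bases
#'   (default 100).
#' @param max_divergence maximum `diffs / (ae - ab)` of a reported
#'   alignment (default 0.3).
#' @param max_gap largest single gap tolerated inside an alignment, bases
#'   (default 40); a larger gap is treated as a break in similarity and the
#'   alignment is split there.
#' @param delta trace-point spacing (default 100; keeps panel entries in
#'   one byte).
#' @param xdrop score-drop allowance of the wave extension (default
#'   `(2 - max_divergence) * max_gap + 30`).  Extension waves are scored
#'   `max_divergence * anti - 2k` (zero slope exactly at the divergence
#'   ceiling); extension stops when the wave's best score falls `xdrop`
#'   below the best seen, which is a trailing-identity stop rule with an
#'   adaptive window.  The default is sized so a single gap of `max_gap`
#'   bases can be crossed, while unrelated sequence (score slope about
#'   -1.2 per difference) terminates the extension quickly.
#' @param min_score significance floor of the local trim, in net matches
#'   (matches minus `(1 - max_divergence)/max_divergence` per difference;
#'   default 20).  A candidate segment scoring at or below the floor is
#'   reported as a length-0 alignment: chance exact runs between unrelated
#'   sequences stay well under it, while any region of `min_length` bases
#'   comfortably inside the divergence ceiling scores far above it.
#' @return a list of class `AlignParams`.
#' @export
align_params <- function(min_length = 100L, max_divergence = 0.3,
                         max_gap = 40L, delta = 100L, xdrop = NULL,
                         min_score = 20) {
  stopifnot(max_divergence > 0, max_divergence < 1, min_length >= 1L)
  if (is.null(xdrop)) xdrop <- (2 - max_divergence) * max_gap + 30
  structure(list(min_length = as.integer(min_length),
                 max_divergence = max_divergence,
                 max_gap = as.integer(max_gap), delta = as.integer(delta),
                 xdrop = xdrop, min_score = min_score),
            class = "AlignParams")
}

# internal alignment constructor
new_alignment <- function(contig_g, contig_h, strand, ab, ae, bb, be,
                          diffs, ops = NULL, tracepoints = NULL) {
  structure(list(contig_g = contig_g, contig_h = contig_h, strand = strand,
                 ab = as.integer(ab), ae = as.integer(ae),
                 bb = as.integer(bb), be = as.integer(be),
                 diffs = as.integer(diffs), ops = ops,
                 tracepoints = tracepoints),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: A[%d,%d) x B[%d,%d) %s  diffs=%d  eps=%.3f\n",
              x$ab, x$ae, x$bb, x$be, x$strand, x$diffs,
              alignment_epsilon(x)))
  invisible(x)
}

#' Divergence of an alignment
#' @param aln an `Alignment`.
#' @return `diffs / (ae - ab)`, or 0 for a length-0 alignment.
#' @export
alignment_epsilon <- function(aln) {
  if (aln$ae == aln$ab) return(0)
  aln$diffs / (aln$ae - aln$ab)
}

#' Local alignment through an anti-diagonal
#'
#' Finds the best local alignment of `Aseq` versus `Bseq` whose path
#' crosses the given anti-diagonal between the diagonal bounds.  The finder
#' anchors on the longest exact match run crossing the anti-diagonal inside
#' the bounds, extends it in both directions with greedy unit-cost
#' furthest-reaching waves (stopping when a trailing window of
#' anti-diagonals falls below identity `1 - max_divergence`), recovers the
#' optimal unit-cost path between the extended endpoints, and trims it to
#' the maximal-scoring local segment.  The reported `diffs` equals the
#' unit-cost edit distance of the reported segment pair.  An alignment is
#' always returned; length 0 signals no similarity.
#'
#' @param Aseq,Bseq sequences (DNA strings or integer code vectors).
#' @param anti anti-diagonal `i + j` the alignment must cross.
#' @param d_low,d_high diagonal bounds (`d = i - j`).
#' @param params an [align_params()] object.
#' @return an `Alignment` (with `ops`; no contig ids).
#' @export
la_finder <- function(Aseq, Bseq, anti, d_low, d_high,
                      params = align_params()) {
  A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
  B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
  r <- cpp_la_finder(A, B, as.integer(anti), as.integer(d_low),
                     as.integer(d_high), params$max_divergence,
                     params$max_gap, params$xdrop, 100000L,
                     params$min_score)
  aln <- new_alignment(NA_integer_, NA_integer_, "+", r$ab, r$ae, r$bb,
                       r$be, r$diffs, ops = r$ops)
  attr(aln, "atop") <- r$atop
  aln
}

#' Sweep a chain tube for local alignments
#'
#' Repeatedly calls the local-alignment finder inside a tube: first on the
#' anti-diagonal `a_low + 2D` (or the tube midpoint when `a_low + D >=
#' a_high`), then, as long as the far end `a_top` of the returned alignment
#' is below `a_high`, again on the truncated tube starting at `a_top`.
#' Returned alignments are split at single gaps above `max_gap`, filtered
#' by `min_length` and `max_divergence`, and given trace-point encodings.
#'
#' @param tube one row of a [find_chains()] tube data.frame (or a list with
#'   `d_low`, `d_high`, `a_low`, `a_high`).
#' @param Aseq,Bseq contig sequences (strings or code vectors); for a
#'   reverse-strand tube pass the reverse complement of contig_h.
#' @param params an [align_params()] object.
#' @param D band width used in chaining (for the sweep step).
#' @return list of retained `Alignment` objects (coordinates in the frame
#'   of the sequences passed in).
#' @export
sweep_tube <- function(tube, Aseq, Bseq, params = align_params(), D = 64L) {
  A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
  B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
  res <- cpp_sweep_tubes(A, B, as.integer(tube$d_low),
                         as.integer(tube$d_high), as.integer(tube$a_low),
                         as.integer(tube$a_high), as.integer(D),
                         params$max_divergence, params$max_gap,
                         params$xdrop, 100000L, params$min_score,
                         params$min_length)
  wrap_sweep_result(res, params)
}

# turn a cpp_sweep_tubes() result into Alignment objects with trace points
wrap_sweep_result <- function(res, params) {
  lapply(seq_along(res$ab), function(p) {
    tp <- tryCatch(
      encode_tracepoints(res$ops[[p]], res$ab[p], res$ae[p], res$bb[p],
                         res$be[p], params$delta),
      adaptalign_tracepoint_overflow = function(e) NULL)
    new_alignment(NA_integer_, NA_integer_, "+", res$ab[p], res$ae[p],
                  res$bb[p], res$be[p], res$diffs[p], ops = res$ops[[p]],
                  tracepoints = tp)
  })
}

#' Remove redundant alignments
#'
#' Within one (contig_g, contig_h, strand) group, alignments that are exact
#' duplicates, or whose bounding box (the smallest rectangle containing the
#' whole path) lies inside the bounding box of another alignment, are
#' dropped; only one instance of mutually identical boxes is kept.  This
#' removes prefix/suffix re-discoveries from disjoint chain tubes and the
#' off-diagonal echo alignments that satellite repeats produce.  Output is
#' sorted by start coordinate in the first genome.
#'
#' @param alignments list of `Alignment` objects for one contig pair and
#'   strand.
#' @return filtered, sorted list.
#' @export
remove_redundant <- function(alignments) {
  n <- length(alignments)
  if (n <= 1L) return(alignments)
  ab <- vapply(alignments, `[[`, integer(1), "ab")
  ae <- vapply(alignments, `[[`, integer(1), "ae")
  bb <- vapply(alignments, `[[`, integer(1), "bb")
  be <- vapply(alignments, `[[`, integer(1), "be")
  span <- (ae - ab) + (be - bb)
  drop <- logical(n)
  ord <- order(-span)
  for (u in seq_len(n - 1L)) {
    i <- ord[u]
    if (drop[i]) next
    for (v in (u + 1L):n) {
      j <- ord[v]
      if (drop[j]) next
      if (ab[j] >= ab[i] && ae[j] <= ae[i] && bb[j] >= bb[i] &&
          be[j] <= be[i])
        drop[j] <- TRUE
    }
  }
  kept <- alignments[!drop]
  kept[order(vapply(kept, `[[`, integer(1), "ab"))]
}

#' Align two genomes
#'
#' The full pipeline: build a syncmer-filtered K-mer index for each genome,
#' merge the indices to enumerate all non-repetitive adaptamer seeds, sort
#' the seeds into diagonal bands, chain them into tubes, sweep every tube
#' with the wave-based local-alignment finder, and remove redundant
#' alignments.  Deterministic given the inputs and parameters.
#'
#' @param gdbG,gdbH `GenomeDB` objects ([fasta_to_gdb()]).
#' @param index_par [index_params()].
#' @param chain_par [chain_params()].
#' @param align_par [align_params()].
#' @param symmetric take the union of the G-vs-H and H-vs-G seed merges
#'   (adaptamers are not symmetric); default `FALSE`.
#' @return list of `Alignment` objects with contig ids set; reverse-strand
#'   alignments carry B coordinates on the reverse complement of contig_h
#'   (converted to forward coordinates by the PAF/PSL writers).
#' @export
align_genomes <- function(gdbG, gdbH, index_par = index_params(),
                          chain_par = chain_params(),
                          align_par = align_params(), symmetric = FALSE) {
  G <- build_index(gdbG, index_par)
  H <- build_index(gdbH, index_par)
  hits <- if (symmetric) symmetric_merge(G, H) else merge_indices(G, H)
  recs <- hits_to_band_records(hits, chain_par)
  tubes <- find_chains(recs, chain_par)
  align_tubes(tubes, gdbG, gdbH, align_par, chain_par$D)
}

# internal: sweep all tubes, grouping by contig pair and strand
align_tubes <- function(tubes, gdbG, gdbH, align_par, D) {
  out <- list()
  if (nrow(tubes) == 0L) return(out)
  codesG <- new.env(parent = emptyenv())
  codesH <- new.env(parent = emptyenv())
  get_seq <- function(env, gdb, i, rc = FALSE) {
    key <- paste0(i, if (rc) "r" else "f")
    if (is.null(env[[key]])) {
      sq <- contig_seq(gdb, i)
      if (rc) sq <- reverse_complement(sq)
      env[[key]] <- cpp_seq_to_codes(sq)
    }
    env[[key]]
  }
  dlo <- tubes$d_low; dhi <- tubes$d_high
  alo <- tubes$a_low; ahi <- tubes$a_high
  grp <- paste(tubes$contig_g, tubes$contig_h, tubes$strand)
  for (gk in unique(grp)) {
    rows <- which(grp == gk)
    cg <- tubes$contig_g[rows[1L]]
    ch <- tubes$contig_h[rows[1L]]
    st <- tubes$strand[rows[1L]]
    A <- get_seq(codesG, gdbG, cg)
    B <- get_seq(codesH, gdbH, ch, rc = st == "-")
    res <- cpp_sweep_tubes(A, B, dlo[rows], dhi[rows], alo[rows],
                           ahi[rows], as.integer(D),
                           align_par$max_divergence, align_par$max_gap,
                           align_par$xdrop, 100000L, align_par$min_score,
                           align_par$min_length)
    alns <- lapply(wrap_sweep_result(res, align_par), function(a) {
      a$contig_g <- cg; a$contig_h <- ch; a$strand <- st
      a
    })
    out <- c(out, remove_redundant(alns))
  }
  out
}
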