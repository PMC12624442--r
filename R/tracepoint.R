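# Alignment paths are integer op vectors:
#   0 = diagonal step (match or substitution; consumes one base of A and B)
#   1 = consumes one base of B only (insertion in B, dash in A)
#   2 = consumes one base of A only (deletion from B, dash in B)
OP_DIAG <- 0L
OP_INSB <- 1L
OP_DELB <- 2L

# panel boundaries of the A interval [ab, ae) at spacing delta
panel_boundaries <- function(ab, ae, delta) {
  lo <- ab %/% delta + 1L
  hi <- (ae - 1L) %/% delta
  if (hi < lo) integer(0) else delta * (lo:hi)
}

#' Encode an alignment path as a trace-point array
#'
#' The A sequence is implicitly partitioned into panels of `delta` bases
#' (the first and last panel of an alignment may be shorter).  The
#' trace-point array records, for each A-panel, the number of B bases the
#' alignment puts opposite it; B symbols inserted exactly at a panel
#' boundary are placed in the left interval.  Together with the four
#' endpoints and `delta`, the array determines a set of lattice points the
#' alignment passes through, from which the path can be reconstructed panel
#' by panel.  With `delta = 100` each entry fits in one byte, so a 10 kb
#' alignment costs 100 bytes regardless of its divergence.
#'
#' @param ops integer op vector (0 diagonal, 1 consumes B, 2 consumes A).
#' @param ab,ae aligned A interval, 0-based half-open.
#' @param bb,be aligned B interval.
#' @param delta panel spacing in bases (default 100).
#' @return an object of class `TracePointArray`: list with `delta` and the
#'   integer panel-length vector `b` (`sum(b) == be - bb`).
#' @section Errors: a panel length above 255 cannot be stored in one byte
#'   and raises a condition of class `adaptalign_tracepoint_overflow`; the
#'   caller is expected to split the alignment at its widest gap.
#' @export
encode_tracepoints <- function(ops, ab, ae, bb, be, delta = 100L) {
  stopifnot(ae > ab, be >= bb)
  dA <- as.integer(ops != OP_INSB)
  dB <- as.integer(ops != OP_DELB)
  if (sum(dA) != ae - ab || sum(dB) != be - bb)
    stop("path does not consume the stated intervals")
  bounds <- panel_boundaries(ab, ae, delta)
  if (length(bounds)) {
    icum <- ab + cumsum(dA)
    jcum <- bb + cumsum(dB)
    jx <- jcum[findInterval(bounds, icum)]
    b <- diff(c(bb, jx, be))
  } else {
    b <- be - bb
  }
  if (any(b > 255L))
    stop(structure(class = c("adaptalign_tracepoint_overflow", "error",
                             "condition"),
                   list(message = "trace-point panel length exceeds 255; split the alignment",
                        call = sys.call())))
  structure(list(delta = as.integer(delta), b = as.integer(b)),
            class = "TracePointArray")
}

#' Reconstruct an alignment path from trace points
#'
#' Solves one optimal unit-cost global alignment per `delta`-panel between
#' the recorded trace points, in O(n + delta * d) time overall.  The
#' reconstructed path passes through every trace point; its total number of
#' differences can only be less than or equal to that of the originally
#' encoded path (each panel is re-solved optimally).
#'
#' @param tpa a [encode_tracepoints()] `TracePointArray`.
#' @param ab,ae,bb,be alignment endpoints (0-based half-open intervals).
#' @param Aseq,Bseq the full A and B sequences (DNA strings or integer code
#'   vectors) the endpoints refer to.
#' @return list with `ops` (the reconstructed path) and `diffs` (its
#'   unit-cost difference count).
#' @export
decode_tracepoints <- function(tpa, ab, ae, bb, be, Aseq, Bseq) {
  stopifnot(inherits(tpa, "TracePointArray"))
  if (sum(tpa$b) != be - bb)
    stop("trace-point array is inconsistent with the B interval")
  A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
  B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
  xs <- c(ab, panel_boundaries(ab, ae, tpa$delta), ae)
  ys <- bb + c(0L, cumsum(tpa$b))
  if (length(xs) != length(ys))
    stop("trace-point array has the wrong number of panels")
  ops <- vector("list", length(tpa$b))
  diffs <- 0L
  for (k in seq_along(tpa$b)) {
    pa <- A[seq2(xs[k] + 1L, xs[k + 1L])]
    pb <- B[seq2(ys[k] + 1L, ys[k + 1L])]
    r <- cpp_align_global(pa, pb)
    ops[[k]] <- r$ops
    diffs <- diffs + r$diffs
  }
  list(ops = unlist(ops), diffs = diffs)
}

# 1-based inclusive sequence that is empty when from > to
seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Indel array of an alignment path
#'
#' Encodes where dashes must be placed to display the alignment: a positive
#' entry `+i` puts a dash before A symbol `i` (an inserted B base), a
#' negative entry `-j` puts a dash before B symbol `j` (a deleted base).
#' Entries appear in path order, with magnitudes non-decreasing for paths
#' produced by the aligners here.
#'
#' @param ops integer op vector.
#' @return integer vector of signed dash positions (1-based; empty for a
#'   gap-free path).  Attribute `"op_index"` maps each entry to its op.
#' @export
extract_indel_array <- function(ops) {
  ia <- cumsum(ops != OP_INSB)  # A consumed after each op
  jb <- cumsum(ops != OP_DELB)
  ins <- which(ops == OP_INSB)
  del <- which(ops == OP_DELB)
  entries <- integer(length(ins) + length(del))
  opi <- sort(c(ins, del))
  val <- ifelse(ops[opi] == OP_INSB, ia[opi] + 1L, -(jb[opi] + 1L))
  # ia[opi] is A consumed including this op; for an insertion the op does
  # not consume A, so the dash precedes A symbol ia+1; for a deletion jb
  # excludes B, so the dash precedes B symbol jb+1
  structure(as.integer(val), op_index = opi)
}

#' Maximal refinable indel segments
#'
#' Scans an indel array for the maximal segments worth re-aligning: all
#' entries of the same sign (a run of pure insertions or pure deletions),
#' at least two entries, and consecutive entries less than `R` apart in
#' magnitude.  Found in one linear sweep.
#'
#' @param o integer indel array ([extract_indel_array()]).
#' @param R separation parameter in bases (default 50).
#' @return a list of integer index pairs `c(x, y)` into `o` (1-based,
#'   inclusive).
#' @export
find_refinable_segments <- function(o, R = 50L) {
  n <- length(o)
  segs <- list()
  x <- 1L
  while (x < n) {
    y <- x
    while (y < n && sign(o[y + 1L]) == sign(o[x]) &&
           abs(abs(o[y + 1L]) - abs(o[y])) < R)
      y <- y + 1L
    if (y > x) segs[[length(segs) + 1L]] <- c(x, y)
    x <- y + 1L
  }
  segs
}

#' Build a refinement trapezoid
#'
#' The region of the alignment matrix between the first and last indel of a
#' same-sign run: `Dgaps + 1` diagonals by `Lspan + 1` columns, where
#' `Dgaps` is the number of indels and `Lspan` the span of the run on the
#' gapped-into sequence.  Deletion runs are mirrored (roles of A and B
#' swapped) so that refinement always works on insertions.
#'
#' @param Aseg segment of the sequence receiving the dashes (length
#'   `Lspan`), as string or code vector.
#' @param Bseg opposite segment (length `Lspan + Dgaps`).
#' @return list of class `Trapezoid` with `Aseg`, `Bseg`, `Dgaps`, `Lspan`.
#' @export
trapezoid <- function(Aseg, Bseg) {
  A <- if (is.character(Aseg)) cpp_seq_to_codes(Aseg) else as.integer(Aseg)
  B <- if (is.character(Bseg)) cpp_seq_to_codes(Bseg) else as.integer(Bseg)
  D <- length(B) - length(A)
  stopifnot(D >= 1L)
  structure(list(Aseg = A, Bseg = B, Dgaps = D, Lspan = length(A)),
            class = "Trapezoid")
}

#' Minimum-gap re-alignment of a trapezoid
#'
#' Re-aligns an insertion-only region under gap-open cost 1, gap-extend
#' cost 0 and mismatch cost 1 (the unit-cost recurrence with the insertion
#' lower bound compressed away), using furthest-reaching waves with Snake
#' (longest-common-prefix) extensions.  The result is a path with the
#' minimum `k = G + S` (gaps plus mismatches) over all insertion-only
#' paths; with this scoring a gap is eliminated whenever it costs at most
#' one extra mismatch.  All waves are kept and the path is recovered by
#' traceback, preferring larger single gaps so the gap count stays minimal.
#'
#' @param trap a [trapezoid()] object.
#' @return list with `ops` (path over the region: diagonal and
#'   consume-B ops), `k` (= gaps + mismatches), `gaps`, `mismatches`.
#' @export
refine_segment <- function(trap) {
  stopifnot(inherits(trap, "Trapezoid"))
  r <- cpp_refine_wave(trap$Aseg, trap$Bseg, trap$Dgaps)
  list(ops = r$ops, k = r$k, gaps = r$gaps, mismatches = r$mismatches)
}

#' Gap-refine an alignment path
#'
#' Rewrites an alignment path so that the number of gaps is reduced, as
#' under a unit-cost model with an infinitesimal gap-open charge: every
#' maximal same-sign indel run whose entries are less than `R` apart is
#' re-aligned with [refine_segment()] (deletion runs by mirroring A and B)
#' and spliced back between the unchanged path vertices.  Endpoints are
#' preserved; the difference count is recomputed from the revised path.
#'
#' @param ops alignment path ops.
#' @param Aseq,Bseq full sequences (strings or code vectors).
#' @param ab,bb alignment start coordinates (0-based).
#' @param R separation parameter (default 50).
#' @return list with `ops` (revised path), `diffs`, `gaps_before`,
#'   `gaps_after`.
#' @export
refine_path <- function(ops, Aseq, Bseq, ab, bb, R = 50L) {
  A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
  B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
  o <- extract_indel_array(ops)
  opi <- attr(o, "op_index")
  segs <- find_refinable_segments(o, R = R)
  gaps_before <- count_gaps(ops)
  if (length(segs)) {
    ia <- c(0L, cumsum(ops != OP_INSB))  # A consumed before op k is ia[k]
    jb <- c(0L, cumsum(ops != OP_DELB))
    # splice from the back so op indices stay valid
    for (sg in rev(segs)) {
      op_lo <- opi[sg[1L]]
      op_hi <- opi[sg[2L]]
      i0 <- ia[op_lo]      # A consumed before the first indel of the run
      j0 <- jb[op_lo]
      i1 <- ia[op_hi + 1L]
      j1 <- jb[op_hi + 1L]
      if (o[sg[1L]] > 0L) {        # insertion run: dashes in A
        tr <- trapezoid(A[seq2(ab + i0 + 1L, ab + i1)],
                        B[seq2(bb + j0 + 1L, bb + j1)])
        new_ops <- refine_segment(tr)$ops
      } else {                     # deletion run: mirror roles
        tr <- trapezoid(B[seq2(bb + j0 + 1L, bb + j1)],
                        A[seq2(ab + i0 + 1L, ab + i1)])
        new_ops <- refine_segment(tr)$ops
        new_ops[new_ops == OP_INSB] <- OP_DELB
      }
      ops <- c(ops[seq2(1L, op_lo - 1L)], new_ops,
               ops[seq2(op_hi + 1L, length(ops))])
    }
  }
  diffs <- path_diffs(ops, A, B, ab, bb)
  list(ops = ops, diffs = diffs, gaps_before = gaps_before,
       gaps_after = count_gaps(ops))
}

# number of gap runs in a path
count_gaps <- function(ops) {
  ind <- ops != OP_DIAG
  if (!length(ind)) return(0L)
  # a gap is a maximal run of equal indel ops
  r <- rle(ops)
  sum(r$values != OP_DIAG)
}

# unit-cost differences of a path against the sequences
path_diffs <- function(ops, A, B, ab, bb) {
  ia <- ab + cumsum(ops != OP_INSB)
  jb <- bb + cumsum(ops != OP_DELB)
  dg <- ops == OP_DIAG
  sum(!dg) + sum(A[ia[dg]] != B[jb[dg]])
}

#' Gap-refine an Alignment object
#'
#' Applies [refine_path()] to an alignment's path (decoded from its trace
#' points when no path is attached), preserving the endpoints, updating
#' the difference count, and re-encoding the trace points.
#'
#' @param aln an `Alignment` ([la_finder()], [align_genomes()]).
#' @param Aseq,Bseq the sequences the alignment refers to (for a
#'   reverse-strand alignment, the reverse complement of the target
#'   contig).
#' @param R separation parameter (default 50).
#' @return the refined `Alignment`.
#' @export
refine_alignment <- function(aln, Aseq, Bseq, R = 50L) {
  stopifnot(inherits(aln, "Alignment"))
  A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
  B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
  ops <- if (!is.null(aln$ops)) aln$ops
         else decode_tracepoints(aln$tracepoints, aln$ab, aln$ae, aln$bb,
                                 aln$be, A, B)$ops
  rf <- refine_path(ops, A, B, aln$ab, aln$bb, R = R)
  aln$ops <- rf$ops
  aln$diffs <- rf$diffs
  delta <- if (!is.null(aln$tracepoints)) aln$tracepoints$delta else 100L
  aln$tracepoints <- encode_tracepoints(rf$ops, aln$ab, aln$ae, aln$bb,
                                        aln$be, delta)
  aln
}

#' CIGAR string of an alignment path
#'
#' Converts a path to a CIGAR string with A as the query: `I` consumes A
#' only, `D` consumes B only.  The `"M"` dialect reports diagonal runs as
#' `M`; the `"=X"` dialect distinguishes matches (`=`) from substitutions
#' (`X`).  The CIGAR consumes exactly `ae - ab` of A and `be - bb` of B.
#'
#' @param ops alignment path.
#' @param Aseq,Bseq sequences (needed for the `"=X"` dialect).
#' @param ab,bb start coordinates of the alignment (0-based).
#' @param dialect `"=X"` (default) or `"M"`.
#' @return a CIGAR string.
#' @export
alignment_to_cigar <- function(ops, Aseq = NULL, Bseq = NULL, ab = 0L,
                               bb = 0L, dialect = c("=X", "M")) {
  dialect <- match.arg(dialect)
  if (!length(ops)) return("")
  if (dialect == "M") {
    sym <- c("M", "D", "I")[ops + 1L]
  } else {
    A <- if (is.character(Aseq)) cpp_seq_to_codes(Aseq) else as.integer(Aseq)
    B <- if (is.character(Bseq)) cpp_seq_to_codes(Bseq) else as.integer(Bseq)
    ia <- ab + cumsum(ops != OP_INSB)
    jb <- bb + cumsum(ops != OP_DELB)
    sym <- character(length(ops))
    dg <- ops == OP_DIAG
    sym[dg] <- ifelse(A[ia[dg]] == B[jb[dg]], "=", "X")
    sym[ops == OP_INSB] <- "D"
    sym[ops == OP_DELB] <- "I"
  }
  r <- rle(sym)
  paste0(r$lengths, r$values, collapse = "")
}
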