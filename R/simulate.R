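#' Benchmark simulation parameters
#'
#' The benchmark genome pair is composed of fixed-size blocks, one per
#' (region length, divergence, replicate) triple.  Each block of genome A
#' starts with a planted similarity region followed by random filler; the
#' corresponding block of genome B carries a mutated copy of the region
#' (edits: 80% substitutions, 10% single-base insertions, 10% single-base
#' deletions) with its own filler.  Block orders are randomized
#' independently in the two genomes so there are no long-range alignments.
#' With the defaults (6 lengths x 14 divergences x 100 replicates x 10 kb
#' blocks) each genome is 84,000,000 bp.
#'
#' @param block_len block size in bases (default 10,000).
#' @param region_lengths planted region lengths (default 100, 200, 500,
#'   1000, 2000, 5000).
#' @param divergences divergence levels as fractions (default 14 levels
#'   1%-65%: 0.01 and 0.05 to 0.65 in steps of 0.05).
#' @param replicates replicates per (length, divergence) cell (default
#'   100).
#' @param edit_mix probabilities of substitution, insertion, deletion
#'   (default 0.8, 0.1, 0.1; must sum to 1).
#' @return a list of class `SimParams`.
#' @export
sim_params <- function(block_len = 10000L,
                       region_lengths = c(100L, 200L, 500L, 1000L, 2000L,
                                          5000L),
                       divergences = c(0.01, seq(0.05, 0.65, by = 0.05)),
                       replicates = 100L,
                       edit_mix = c(sub = 0.8, ins = 0.1, del = 0.1)) {
  stopifnot(abs(sum(edit_mix) - 1) < 1e-9, all(region_lengths < block_len))
  structure(list(block_len = as.integer(block_len),
                 region_lengths = as.integer(region_lengths),
                 divergences = divergences,
                 replicates = as.integer(replicates),
                 edit_mix = edit_mix),
            class = "SimParams")
}

#' Total genome length implied by simulation parameters
#' @param params a [sim_params()] object.
#' @return numeric: blocks x block length in bases.
#' @export
sim_genome_length <- function(params = sim_params()) {
  length(params$region_lengths) * length(params$divergences) *
    params$replicates * as.numeric(params$block_len)
}

#' Mutate a sequence to a target divergence
#'
#' Applies `round(divergence * nchar(seq))` edits at distinct positions of
#' the input, with types drawn from `mix` (substitutions never rewrite the
#' original base; insertions and deletions are single-base).  Edits are
#' applied right to left so that the logged positions refer to the original
#' coordinates; replaying the log onto the input reproduces the output.
#' Randomness comes from the current R RNG stream (`set.seed()` first for
#' reproducibility).
#'
#' @param seq DNA string.
#' @param divergence fraction of positions to edit, in (0, 1); 0 returns
#'   the input unchanged.
#' @param mix length-3 probability vector (substitution, insertion,
#'   deletion).
#' @return the mutated string, with attribute `"edit_log"`: a data.frame
#'   of `pos` (1-based original coordinate), `op` (`"sub"/"ins"/"del"`) and
#'   `base` (written base, `NA` for deletions).  Insertions place `base`
#'   before `pos`.
#' @export
mutate_sequence <- function(seq, divergence,
                            mix = c(sub = 0.8, ins = 0.1, del = 0.1)) {
  seq <- tolower(seq)
  n <- nchar(seq)
  stopifnot(divergence >= 0, divergence < 1)
  nedit <- round(divergence * n)
  if (nedit == 0L) {
    attr(seq, "edit_log") <- data.frame(pos = integer(0),
                                        op = character(0),
                                        base = character(0),
                                        stringsAsFactors = FALSE)
    return(seq)
  }
  bases <- c("a", "c", "g", "t")
  pos <- sort(sample.int(n, nedit))
  op <- sample(c("sub", "ins", "del"), nedit, replace = TRUE, prob = mix)
  ch <- strsplit(seq, "")[[1L]]
  base <- rep(NA_character_, nedit)
  sub_i <- which(op == "sub")
  if (length(sub_i)) {
    cur <- match(ch[pos[sub_i]], bases)
    repl <- (cur - 1L + sample.int(3L, length(sub_i), replace = TRUE)) %% 4L
    base[sub_i] <- bases[repl + 1L]
  }
  ins_i <- which(op == "ins")
  if (length(ins_i))
    base[ins_i] <- bases[sample.int(4L, length(ins_i), replace = TRUE)]
  # positions are distinct original coordinates, so all edits can be
  # applied in one vectorised pass
  out <- ch
  out[pos[sub_i]] <- base[sub_i]
  keep <- rep(TRUE, n)
  keep[pos[op == "del"]] <- FALSE
  vals <- c(out[keep], base[ins_i])
  keys <- c(seq_len(n)[keep], pos[ins_i] - 0.5)  # insertion goes before pos
  res <- paste(vals[order(keys)], collapse = "")
  attr(res, "edit_log") <- data.frame(pos = pos, op = op, base = base,
                                      stringsAsFactors = FALSE)
  res
}

#' Simulate a benchmark genome pair with planted truth
#'
#' One block per (region length, divergence, replicate) triple: genome A
#' blocks start with the planted region, genome B blocks with its mutated
#' copy, both padded to `block_len` with independent random filler, and the
#' block orders shuffled independently.  Deterministic given the RNG state
#' (`set.seed()` first).
#'
#' @param params a [sim_params()] object.
#' @return list with `A`, `B` (named character vectors of one scaffold
#'   each) and `truth`: a data.frame per planted region with global 0-based
#'   half-open intervals `a_start`, `a_end`, `b_start`, `b_end`, plus
#'   `length`, `divergence`, `replicate`.
#' @export
simulate_genome_pair <- function(params = sim_params()) {
  grid <- expand.grid(replicate = seq_len(params$replicates),
                      divergence = params$divergences,
                      length = params$region_lengths)
  nb <- nrow(grid)
  blockA <- character(nb)
  blockB <- character(nb)
  blen_mut <- integer(nb)
  for (i in seq_len(nb)) {
    reg <- random_dna(grid$length[i])
    mut <- mutate_sequence(reg, grid$divergence[i], params$edit_mix)
    blen_mut[i] <- nchar(mut)
    fillA <- params$block_len - grid$length[i]
    fillB <- params$block_len - nchar(mut)
    if (fillB < 0L) stop("mutated region exceeds the block length")
    blockA[i] <- paste0(reg, random_dna(fillA))
    blockB[i] <- paste0(mut, random_dna(fillB))
  }
  permA <- sample.int(nb)
  permB <- sample.int(nb)
  posA <- order(permA)   # posA[i]: rank of block i in genome A
  posB <- order(permB)
  truth <- data.frame(
    a_start = (posA - 1L) * params$block_len,
    a_end = (posA - 1L) * params$block_len + grid$length,
    b_start = (posB - 1L) * params$block_len,
    b_end = (posB - 1L) * params$block_len + blen_mut,
    length = grid$length, divergence = grid$divergence,
    replicate = grid$replicate)
  list(A = c(genomeA = paste(blockA[permA], collapse = "")),
       B = c(genomeB = paste(blockB[permB], collapse = "")),
       truth = truth)
}

#' Evaluate alignments against planted truth
#'
#' Scores a PAF-style alignment table against the simulator's truth table:
#' \itemize{
#'   \item complete recoveries, per (length, divergence) cell: planted
#'     regions for which a single alignment covers at least 95% of the
#'     region on both genomes;
#'   \item falsely aligned bases: genome-A positions covered by alignments
#'     outside every planted region (counted per position);
#'   \item false positives: alignments that span more than one planted
#'     region, or whose aligned span is more than 95% outside the planted
#'     regions on either genome.
#' }
#'
#' @param paf alignment data.frame ([read_paf()] or [write_paf()] output
#'   passed through `read_paf(text = )`); intervals 0-based half-open in
#'   genome A (`qstart`,`qend`) and genome B (`tstart`,`tend`).
#' @param truth truth data.frame from [simulate_genome_pair()].
#' @return list with `cells` (data.frame: `length`, `divergence`,
#'   `n_regions`, `complete`), `false_bases` (count), `false_positives`
#'   (count), and `n_alignments`.
#' @export
evaluate_alignments <- function(paf, truth) {
  na <- nrow(paf)
  nt <- nrow(truth)
  compl <- logical(nt)
  span_multi <- integer(na)
  ov_a <- numeric(na)   # aligned-base overlap with planted regions, A side
  ov_b <- numeric(na)
  for (i in seq_len(nt)) {
    oa <- pmax(0L, pmin(paf$qend, truth$a_end[i]) -
                 pmax(paf$qstart, truth$a_start[i]))
    ob <- pmax(0L, pmin(paf$tend, truth$b_end[i]) -
                 pmax(paf$tstart, truth$b_start[i]))
    la <- truth$a_end[i] - truth$a_start[i]
    lb <- truth$b_end[i] - truth$b_start[i]
    compl[i] <- any(oa >= 0.95 * la & ob >= 0.95 * lb)
    span_multi <- span_multi + as.integer(oa > 0L | ob > 0L)
    ov_a <- ov_a + oa
    ov_b <- ov_b + ob
  }
  spans_a <- paf$qend - paf$qstart
  spans_b <- paf$tend - paf$tstart
  fp <- span_multi > 1L |
    (spans_a > 0L & ov_a < 0.05 * spans_a) |
    (spans_b > 0L & ov_b < 0.05 * spans_b)
  # per-position false bases in genome A (union of alignment intervals
  # minus planted regions)
  false_bases <- interval_union_minus(paf$qstart, paf$qend,
                                      truth$a_start, truth$a_end)
  cells <- aggregate(cbind(n_regions = rep(1L, nt), complete = compl),
                     by = list(length = truth$length,
                               divergence = truth$divergence),
                     FUN = sum)
  list(cells = cells[order(cells$length, cells$divergence), ],
       false_bases = false_bases, false_positives = sum(fp),
       n_alignments = na)
}

# total length of union(a-intervals) minus union(b-intervals)
interval_union_minus <- function(as, ae, bs, be) {
  if (!length(as)) return(0L)
  ev <- rbind(data.frame(x = as, w = 1L), data.frame(x = ae, w = -1L),
              data.frame(x = bs, w = 0L), data.frame(x = be, w = 0L))
  ev$t <- rep(c(1L, 1L, 2L, 2L), c(length(as), length(ae), length(bs),
                                   length(be)))
  ev$w2 <- rep(c(0L, 0L, 1L, -1L), c(length(as), length(ae), length(bs),
                                     length(be)))
  ev <- ev[order(ev$x), ]
  cov_a <- cumsum(ev$w)
  cov_b <- cumsum(ev$w2)
  dx <- diff(ev$x)
  active <- head(cov_a, -1L) > 0L & head(cov_b, -1L) == 0L
  sum(dx[active])
}
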