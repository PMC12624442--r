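---
title: "Methods: adaptive-seed genome alignment with trace-point encoding"
author: "adaptalign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-seed genome alignment with trace-point encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given two assembled genomes, we want every statistically significant local
alignment between them: pairs of segments that align essentially across
their whole length, with gaps no larger than a few tens of bases.  We
deliberately do not chain such alignments across larger gaps — that is a
question about homology, not alignment, and is left to downstream tools.
The package is organised as a sort-and-merge pipeline whose stages are all
exposed as ordinary R functions: genome databases, syncmer-filtered K-mer
indices, an adaptamer seed merge, diagonal-band chaining, wave-based local
alignment, trace-point storage, and minimum-gap refinement.  A planted-truth
simulator and evaluator close the loop.

Throughout, position *i* of a sequence denotes the boundary between
characters *i* and *i+1*, so intervals are 0-based and half-open and the
substring `A[i,j]` has `j - i` characters.

# Genome databases

`fasta_to_gdb()` splits each scaffold into contigs at runs of Ns, packing
contig sequence at 2 bits per base and recording only the lengths of the
N-runs.  Ns are never indexed or aligned through; the recorded gap lengths
let every result be reported in scaffold coordinates.  Soft-masking
(lower-case stretches) is recorded as intervals so FASTA round-trips, but
the seeder ignores it: masking in this pipeline is handled by the
repetitiveness threshold below, not by sequence case.  Because contigs hold
pure 2-bit DNA, every N-run splits; `min_gap` only controls whether a run
shorter than the threshold warns.  We default `min_gap = 1` — a single N is
already evidence the assembler did not believe the joining sequence.

# The genome index

The index of a genome is the sorted list of all K-mers of the genome *and
its complement strand* with their signed positions, truncated to those
whose first `s` bases form a closed (s,m) syncmer, plus the
longest-common-prefix (lcp) array.  Sorted list + lcp array is exactly a
suffix array truncated at depth K, which is all the later merge needs.

Parameters, with defaults:

* `K = 40` bases — the adaptamer length cap.  Genomes are far smaller than
  $4^{40}$, so 40 bases are ample to correlate two unique regions.
* `(s, m) = (12, 8)` — a K-mer is kept only when the canonical value of the
  first or last 8-mer of its 12-base prefix is the minimum over all 8-mers
  of that prefix.  Closed syncmers of random DNA keep a little under half
  of all positions (the suite checks the fraction lies in [0.35, 0.60]),
  with consecutive kept positions at most `s - m = 4` apart and on average
  a little over 2 apart — a guaranteed-coverage subsample, unlike an
  arbitrary decimation.  The canonical value makes the retained s-mer set
  strand-closed.
* `tau = 10` — a K-mer occurring `tau` or more times in genome +
  complement is dropped at build time, and the merge additionally refuses
  to report an adaptamer whose match range covers more than `tau`
  positions.  This is the pipeline's repeat handling.

The sort is an in-place MSD radix sort over one-byte digits of the 2-bit
packed K-mers.  Three refinements matter in practice: when only one
partition of a sub-array is non-empty the depth advances with no data
movement (blocks of equal keys are verified, not moved); an element already
inside its target partition is never moved; and only non-empty partition
values are iterated.  The lcp array costs nothing extra: at byte depth $d$,
the first element of partition $p$ whose non-empty predecessor partition is
$q < p$ has, for 2-bit packed DNA,
$\mathrm{lcp} = 4d + 3 - \lfloor \log_4 (p \oplus q) \rfloor$ bases, and
elements equal to their predecessor through the full key width get lcp K.
The test suite verifies both facts against character-by-character
recomputation.

# Finding adaptamer seeds

An *adaptamer* (adaptive seed, 1/2-MEM) at a position of genome G is the
longest string starting there that also occurs in genome H or its
complement; it is maximal only on the G side.  The merge walks the two
sorted indices once.  For the current G K-mer $\alpha$ it maintains the
range `[fst, lst)` of H records whose K-mers share the maximal prefix
length `L` with $\alpha$, the merge cursor `cur`, and a `wall` vector
giving, for every prefix length below `L`, the first H record reaching that
lcp with $\alpha$.  Moving to the next G K-mer only needs the G-side lcp:
if it equals `L` the range may extend; if it is smaller the state is
rewound through `wall`.  `lst` is capped at `fst + tau + 1`, which exactly
marks ranges that the repetitiveness filter will discard anyway.  The suite
checks the sweep state against brute-force recomputation for every K-mer of
toy indices, and the whole hit set against a quadratic prefix-table oracle.

Two floors apply to reported seeds: the repetitiveness threshold, and a
minimum length `min_len` defaulting to `s` — matches shorter than the
syncmer window are lost by subsampling anyway, and the floor guards the
degenerate empty-prefix range.  When a seed's H occurrence is on the
reverse strand, the hit is reported with the H position in forward
coordinates plus an orientation flag, and mapped back to
reverse-complement coordinates at chaining time so that diagonals are
meaningful.  Adaptamers are not symmetric; `symmetric_merge()` unions both
directed merges for the rare applications (e.g. *ab initio* repeat
discovery) that need it.

# Chaining in diagonal bands

Each seed `(p_i, p_j, t)` becomes the sextuple
`(c_i, c_j, floor((p_i - p_j)/D), p_i + p_j, (p_i - p_j) mod D, t)`, from
which the pair is reconstructed exactly.  After sorting on the first four
components (strand included — mixing strands in a band would be
meaningless), the seeds of each pair of adjacent bands `(b, b+1)` are
merged in anti-diagonal order and cut wherever the end-to-start
anti-diagonal gap exceeds `A`.  This finds every chain of width up to `D`
and also admits chains up to `2D` wide; chains discovered from both band
pairs with the same seed set are deduplicated.  Defaults `D = 64`,
`A = 1000`; results are quite insensitive to `D`, and single-seed chains
are allowed (`min_chain_seeds = 1`) — the alignment stage is the real
filter.  Each chain is handed on as its *tube*: the rectangle spanned by
its extreme diagonals and anti-diagonals with both seed ends included.

# Local alignment

`la_finder()` implements the local-aligner contract: given an
anti-diagonal and diagonal bounds, return the best local alignment through
that anti-diagonal (possibly of length 0), its unit-cost difference count,
and its path.  The internals are the package's own design:

1. **Anchor**: the longest exact match run crossing the anti-diagonal
   within the bounds.
2. **Extension**: greedy unit-cost furthest-reaching waves in both
   directions, scored $\sigma = \epsilon_{\max}\,a - 2k$ where $a$ is
   anti-diagonal progress and $k$ the wave cost; the slope is zero exactly
   at divergence $\epsilon_{\max}$.  Extension stops when the wave's best
   score falls `xdrop` below the best seen — a trailing-identity rule with
   an adaptive window.  `xdrop` defaults to
   $(2 - \epsilon_{\max})\,\mathrm{max\_gap} + 30$, sized so one gap of
   `max_gap` bases can be crossed; on random sequence the score drops at
   roughly 1.2 per difference, so noise exploration is bounded.  Waves are
   confined to the tube's band plus a drift margin (`max_gap + 60`
   diagonals): an alignment path drifts off its band only by its indel
   imbalance, while an unconfined frontier maximised over an ever-growing
   diagonal set advances fast enough on random sequence to defeat any
   score-based stop.
3. **Path and trim**: an optimal unit-cost global alignment is computed
   between the extended endpoints and trimmed to its maximal-scoring local
   segment (match +1, difference $-(1-\epsilon_{\max})/\epsilon_{\max}$).
   A segment scoring at or below `min_score = 20` net matches is reported
   as length 0: chance exact runs between unrelated desk-scale sequences
   stay well below it.  Because a sub-path of an optimal path is optimal
   between its own endpoints, the reported difference count equals the
   unit-cost edit distance of the reported segments — the suite asserts
   this against `utils::adist` for every test alignment.

`sweep_tube()` probes a tube first at `a_low + 2D`, or at the tube midpoint
once less than one band-width remains; after a probe whose alignment ends
at `a_top < a_high` the truncated tube is probed again from `a_top`.  The
midpoint probe is terminal — it is issued when its extension covers the
whole remainder, and without that reading a tube yielding only length-0
alignments would be probed forever.  Returned alignments are split at any
single gap exceeding `max_gap` (a larger gap is a break in similarity, and
also what keeps trace-point panels within one byte), then filtered by
`min_length = 100` and `max_divergence = 0.3` (user-settable).  Within a
contig pair and strand, exact duplicates and alignments whose bounding box
lies inside another's are dropped — disjoint tubes rediscover prefixes and
suffixes of the same alignment, and satellite repeats produce off-diagonal
echoes inside the main box — and output is sorted by start in the first
genome.

# Trace points

An alignment of `A[ab,ae]` against `B[bb,be]` is stored as its endpoints,
its difference count, and the *trace-point array*: with A implicitly cut
into `delta`-base panels (`delta = 100` so each entry fits one byte), the
array lists how many B bases lie opposite each A panel, B symbols inserted
exactly at a boundary going to the left panel.  A 10 kb alignment costs
100 bytes regardless of divergence, where an `=X` CIGAR grows with the
difference count.  Reconstruction solves one optimal unit-cost global
alignment per panel — `O(n + delta d)` overall — and can only match or
improve the stored difference count; re-encoding the reconstruction
reproduces the array exactly (a fixed point the suite asserts).  A panel
that would exceed 255 raises a typed condition telling the caller to split
the alignment; the gap cap makes this unreachable in normal operation.

# Minimum-gap refinement

Unit-cost alignments misplace letters inside gaps.  Adding an
infinitesimal gap-open charge selects, among optimal unit-cost alignments,
one with fewest gaps; with a gap-open cost of 1 the aligner will also trade
one mismatch to remove one gap.  Before export, the path is rewritten as an
*indel array* (signed dash positions, magnitudes non-decreasing), and every
maximal same-sign run of at least two indels whose entries are less than
`R = 50` apart is re-aligned inside its trapezoid — `D+1` diagonals by
`L+1` columns where `D` is the run's indel count and `L` its span.
Deletion runs are mirrored so only insertions need handling.  The
re-alignment is a compressed wave: gap-open costs 1, gap continuation 0,
mismatch 1, furthest-reaching positions per diagonal extended by Snake
(longest common prefix) runs.  All waves are kept and the path is recovered
by traceback, preferring the largest single gap on ties so the gap count
stays minimal.  The result attains the minimum of gaps + mismatches over
all insertion-only paths; the suite checks this against both a dense
Gotoh-style DP and direct enumeration of all monotone insertion placements
at small sizes.  Refinement can only reduce the gap count, preserves
endpoints, and the difference count is recomputed from the revised path.

# Output formats

PAF (12 mandatory columns, `NM:i` and optional `cg:Z` in `M` or `=X`
dialect, mapq emitted as 255 since no mapping quality is defined), PSL
(21 columns, blocks = gap-free segments, reverse-strand query starts in
reverse-complement coordinates per the PSL convention), and an ASCII
ONEcode-style ALN document: strongly typed lines led by one-letter codes, a
header carrying provenance, a schema line per code, per-type counts and
maxima, and trace-point lists stored as first value plus forward
differences.  The binary ONEcode machinery (per-item compression, random
access) is out of scope; the self-describing header discipline is kept.
The one-letter codes are this package's own (`A` alignment, `D` diffs, `T`
trace points, `d` spacing).  Genome databases and indices persist
the same way (`write_gdb()`, `write_gix()`), the former with a packed
2-bit sequence sidecar.

# The benchmark simulator

`simulate_genome_pair()` builds block-structured genome pairs: one 10 kb
block per (region length, divergence, replicate) triple, each block of A
starting with a planted region followed by i.i.d. random filler, the
corresponding block of B starting with a mutated copy of that region with
its own filler, and the block orders shuffled independently so no
long-range alignment exists.  Edits are 80% substitutions (never rewriting
the original base), 10% single-base insertions and 10% single-base
deletions, applied at `round(divergence * length)` distinct positions; the
defaults (6 lengths 100–5000 bp, 14 divergence levels 1%–65%, 100
replicates) give 84 Mb per genome.  The 14 levels are 1% and 5%–65% in 5%
steps — the printed range and total pin the count but not the spacing, and
a uniform ladder with the 1% anchor is the obvious choice.  Single-base
indels were chosen because no indel length distribution is specified;
consequences: real structural variation, satellite arrays, and soft-masked
repeat landscapes are *not* emulated, so passing the benchmark says
nothing about, e.g., segmental-duplication handling, only about
sensitivity/specificity versus point divergence.

`evaluate_alignments()` scores a PAF table against the truth: a region is
*completely recovered* when one alignment covers at least 95% of it on
both genomes; an alignment is a *false positive* when it overlaps more
than one planted region or when over 95% of its span lies outside the
regions on either genome; *false bases* are genome-A positions covered by
alignments but by no region, counted per position.

The acceptance suite runs a scaled grid — lengths {500, 1000, 2000,
5000} bp, divergences {1, 5, 10, 15, 20}%, 10 replicates, i.e. 2 Mb per
genome — chosen as the largest grid a laptop-class single core handles
comfortably; on it the pipeline recovers essentially every region at low
divergence, degrades monotonically with divergence and improves with
length, and reports zero false positives.

# Numerical and degenerate-input choices

* All integer coordinates fit in R integers; K-mer values are compared as
  packed bytes, never as numbers, so `K = 40` needs no big integers
  (scalar `phi_value()` is capped at 26 bases, the exact range of a
  double).
* Contigs shorter than K are skipped with a warning; a genome whose every
  K-mer is repetitive yields an empty index, and merging anything with an
  empty index yields no hits.
* `la_finder()` ties in anchor selection resolve to the lowest diagonal;
  wave traceback prefers substitutions over indels, which keeps paths
  compact but is otherwise arbitrary — only the difference count is
  contractual.
* A length-0 alignment is the explicit "no similarity" signal, never an
  error.
* The evaluator counts aligned bases from alignment start/end positions
  (gaps inside an alignment count as covered), the convention used
  consistently for coverage, false-base and false-positive scoring.

# Known limitations

Single-threaded by design (the upstream engineering for threading and
cache-bucketed external sorts is out of scope); indices are held in
memory; sensitivity at divergence approaching `max_divergence` for regions
near `min_length` is limited by the `min_score` floor; and the simulator's
point-mutation model understates the difficulty of real repeat-rich
genomes.
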