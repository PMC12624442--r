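# adaptalign

Whole-genome local alignment in R, built around adaptive seeds and a
trace-point alignment encoding.

Given two assembled genomes, `adaptalign` finds all statistically
significant local alignments between them — pairs of segments that align
essentially across their whole length, with single gaps capped at a few
tens of bases.  It deliberately does not chain alignments across larger
gaps; that is a homology question left to downstream tools.

## How it works

* **Genome databases.**  Scaffolds are split into contigs at runs of Ns
  and packed at 2 bits/base; N-run lengths are kept so results come back
  in scaffold coordinates.
* **Genome index.**  Every K-mer (default K = 40) of the genome *and its
  complement strand* whose first s = 12 bases form a closed (s,m) = (12,8)
  syncmer — a strand-symmetric subsample keeping a bit under half of all
  positions, never more than s − m = 4 apart — is sorted by an in-place
  MSD radix sort that computes the longest-common-prefix (lcp) array as a
  side effect.  The sorted list plus lcp array is a suffix array truncated
  at depth K.
* **Adaptamer seeds.**  Two indices are merged in one linear sweep that
  reports, for every K-mer position of the first genome, its *adaptamer*
  (adaptive seed, 1/2-MEM): the longest prefix that occurs anywhere in the
  second genome or its complement, with all its matching positions —
  unless it occurs more than τ = 10 times (repetitive).
* **Chains and tubes.**  Seeds become records
  `(c_i, c_j, ⌊(p_i−p_j)/D⌋, p_i+p_j, (p_i−p_j) mod D, t)`; after sorting,
  chains are read off linearly from merged adjacent diagonal bands
  (D = 64), cut at anti-diagonal gaps above A = 1000, and each chain
  yields a rectangular search *tube*.
* **Wave alignment.**  Each tube is swept by a local-alignment finder:
  anchor on the best exact run through an anti-diagonal, extend with
  unit-cost furthest-reaching waves under a score-drop stop rule, recover
  the optimal unit-cost path between the endpoints, and trim to the
  maximal-scoring local segment.  Reported difference counts equal the
  unit-cost edit distance of the reported segments.
* **Trace points.**  An alignment is stored as endpoints plus one byte per
  δ = 100-base panel of the first sequence (the number of opposite bases
  in the second), independent of divergence; paths are re-derived panel by
  panel on demand.
* **Minimum-gap refinement.**  Before export, same-sign indel runs are
  re-aligned under an infinitesimal gap-open cost (gap-open 1, extension
  0, mismatch 1, compressed wave with Snake extensions), yielding the
  fewest-gap form; one mismatch may buy the removal of one gap.
* **Benchmark.**  A block-structured simulator plants similarity regions
  of controlled length and divergence (edits: 80% substitutions, 10%
  insertions, 10% deletions) with shuffled block order, and an evaluator
  reports complete recoveries, falsely aligned bases and false positives.

## Worked example

```r
library(adaptalign)
set.seed(42)

# two in-memory genomes sharing one 2 kb region at 8% divergence
region <- random_dna(2000)
gA <- gdb_from_sequences(c(chrA = paste0(random_dna(3000), region,
                                         random_dna(3000))))
gB <- gdb_from_sequences(c(chrB = paste0(random_dna(1000),
                                         mutate_sequence(region, 0.08),
                                         random_dna(5000))))

alns <- align_genomes(gA, gB)
alns[[1]]
#> Alignment: A[2999,5020) x B[999,3028) +  diffs=162  eps=0.080

writeLines(write_paf(alns, gA, gB, cigar = "none"))
#> chrA  8000  2999  5020  +  chrB  8006  999  3028  1878  2040  255  NM:i:162
```

The single reported alignment covers the planted region (A interval
[2999, 5020) against B interval [999, 3028), plus-strand): 1878 of its
2040 columns are matches and its 162 unit-cost differences over 2021
A-bases give the divergence `eps = 0.080`, matching the simulated 8%.
Its trace-point encoding is 22 bytes (`alns[[1]]$tracepoints$b` starts
`1 103 100 99 ...`), versus a CIGAR beginning `4=1D34=1D22=1X1=...`.

Genomes can equally come from (optionally gzipped) FASTA via
`fasta_to_gdb()`; `write_psl()` and `write_aln()` provide PSL and an
ASCII ONEcode-style ALN document, and `read_aln()` restores alignments
from the latter.  Thin command-line wrappers (`adaptalign`, `gixmake`,
`alnconvert`, `alnsim`) are installed under `exec/`.

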