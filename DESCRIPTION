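Package: adaptalign
Title: Whole-Genome Local Alignment with Adaptive Seeds and Trace-Point
    Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds all statistically significant local alignments between
    two genome assemblies using adaptive (1/2-MEM) seeds.  Genomes are
    decomposed into contigs and indexed as truncated suffix arrays: every
    K-mer led by a closed (s,m) syncmer, on both strands, sorted by an
    in-place MSD radix sort that computes the longest-common-prefix array
    as a side effect.  Two indices are merged in a single linear sweep to
    enumerate all non-repetitive adaptamer seed matches, which are chained
    in diagonal bands and verified with a unit-cost furthest-reaching wave
    aligner.  Alignments are stored compactly as trace-point arrays,
    refined to a minimum-gap form under an infinitesimal gap-open cost,
    and written as PAF, PSL, or an ASCII ONEcode-style ALN document.  A
    synthetic benchmark generator with planted divergent regions and a
    sensitivity/false-positive evaluator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
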