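test_that("identical sequences align end to end with zero differences", {
  set.seed(51)
  a <- random_dna(2000)
  r <- la_finder(a, a, anti = 2000, d_low = -5, d_high = 5)
  expect_equal(c(r$ab, r$ae, r$bb, r$be, r$diffs), c(0L, 2000L, 0L, 2000L,
                                                     0L))
})

test_that("reported diffs equal the unit-cost edit distance (DP oracle)", {
  set.seed(52)
  for (div in c(0.02, 0.05, 0.10)) {
    a <- random_dna(2000)
    b <- mutate_sequence(a, div)
    r <- la_finder(a, b, anti = 2000, d_low = -40, d_high = 40)
    expect_gt(r$ae - r$ab, 1700)
    expect_equal(r$diffs,
                 as.integer(adist(substr(a, r$ab + 1, r$ae),
                                  substr(b, r$bb + 1, r$be))))
  }
})

test_that("unrelated sequences give a length-0 alignment", {
  set.seed(53)
  for (i in 1:5) {
    r <- la_finder(random_dna(2000), random_dna(2000), 2000, -20, 20)
    expect_equal(r$ae, r$ab)
    expect_length(r$ops, 0L)
  }
})

test_that("a tube over a planted similarity yields one covering alignment", {
  set.seed(54)
  reg <- random_dna(1000)
  a <- paste0(random_dna(500), reg, random_dna(500))
  b <- paste0(random_dna(300), mutate_sequence(reg, 0.05), random_dna(700))
  # seeds live near diagonal 200 over anti-diagonals [1600, 3600]
  tube <- list(d_low = 150L, d_high = 250L, a_low = 1600L, a_high = 3600L)
  # successive probes can rediscover the same alignment; redundancy removal
  # collapses them to one
  alns <- remove_redundant(sweep_tube(tube, a, b, align_params(), D = 64L))
  expect_equal(length(alns), 1L)
  aln <- alns[[1L]]
  expect_lte(aln$ab, 520L); expect_gte(aln$ae, 1480L)
  expect_lte(alignment_epsilon(aln), 0.3)
  expect_false(is.null(aln$tracepoints))
})

test_that("a tube over noise yields nothing", {
  set.seed(55)
  tube <- list(d_low = -32L, d_high = 32L, a_low = 500L, a_high = 2500L)
  alns <- sweep_tube(tube, random_dna(2000), random_dna(2000),
                     align_params(), D = 64L)
  expect_length(alns, 0L)
})

test_that("two similarities split by unalignable sequence give two alignments", {
  set.seed(56)
  r1 <- random_dna(600); r2 <- random_dna(600)
  junk_a <- random_dna(300); junk_b <- random_dna(300)  # unrelated middles
  a <- paste0(r1, junk_a, r2)
  b <- paste0(mutate_sequence(r1, 0.03), junk_b, mutate_sequence(r2, 0.03))
  tube <- list(d_low = -40L, d_high = 40L, a_low = 0L, a_high = 3000L)
  alns <- sweep_tube(tube, a, b, align_params(), D = 64L)
  expect_gte(length(alns), 2L)
  # no reported alignment bridges the unalignable middle
  for (al in alns)
    expect_false(al$ab < 550 && al$ae > 950)
})

test_that("no output alignment contains a single gap above max_gap", {
  set.seed(57)
  ap <- align_params()
  for (i in 1:10) {
    reg <- random_dna(800)
    a <- paste0(random_dna(100), reg, random_dna(100))
    b <- paste0(random_dna(100), mutate_sequence(reg, 0.15),
                random_dna(100))
    tube <- list(d_low = -60L, d_high = 60L, a_low = 200L, a_high = 1800L)
    for (al in sweep_tube(tube, a, b, ap, 64L)) {
      runs <- rle(al$ops)
      gaps <- runs$lengths[runs$values != 0L]
      if (length(gaps)) expect_lte(max(gaps), ap$max_gap)
      # diffs contract holds for every reported alignment
      expect_equal(al$diffs, path_diffs_oracle(al$ops, a, b, al$ab, al$bb))
    }
  }
})

test_that("redundant alignments are removed and output is sorted", {
  mk <- function(ab, ae, bb, be)
    adaptalign:::new_alignment(1L, 1L, "+", ab, ae, bb, be, 0L)
  # exact duplicate
  out <- remove_redundant(list(mk(0, 100, 0, 100), mk(0, 100, 0, 100)))
  expect_length(out, 1L)
  # bounding-box containment (satellite echo inside the main box)
  out <- remove_redundant(list(mk(0, 1000, 0, 1000), mk(100, 300, 50, 250)))
  expect_length(out, 1L)
  expect_equal(out[[1L]]$ae, 1000L)
  # disjoint alignments all kept, sorted by ab
  out <- remove_redundant(list(mk(500, 700, 500, 700), mk(0, 100, 0, 100)))
  expect_length(out, 2L)
  expect_equal(vapply(out, `[[`, integer(1), "ab"), c(0L, 500L))
})

test_that("self-comparison recovers the identity alignment of each contig", {
  set.seed(58)
  g <- gdb_from_sequences(c(s1 = random_dna(10000),
                            s2 = random_dna(5000)))
  alns <- align_genomes(g, g)
  for (ci in 1:2) {
    len <- g$contigs$length[ci]
    hit <- Filter(function(a) a$contig_g == ci && a$contig_h == ci &&
                    a$strand == "+" && a$ab == 0 && a$ae == len &&
                    a$diffs == 0, alns)
    expect_length(hit, 1L)
  }
})

test_that("an inverted copy is found on the reverse strand", {
  set.seed(59)
  reg <- random_dna(1500)
  gA <- gdb_from_sequences(c(a = paste0(random_dna(800), reg,
                                        random_dna(700))))
  gB <- gdb_from_sequences(c(b = paste0(random_dna(500),
                                        reverse_complement(mutate_sequence(reg, 0.05)),
                                        random_dna(1000))))
  alns <- align_genomes(gA, gB)
  rev <- Filter(function(a) a$strand == "-", alns)
  expect_gte(length(rev), 1L)
  spans <- vapply(rev, function(a) a$ae - a$ab, integer(1))
  expect_gte(max(spans), 1400L)
})

test_that("alignment against an empty index yields empty output", {
  set.seed(60)
  gA <- gdb_from_sequences(c(a = random_dna(5000)))
  gB <- gdb_from_sequences(c(b = strrep("a", 5000)))  # all repetitive
  alns <- align_genomes(gA, gB)
  expect_length(alns, 0L)
})
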