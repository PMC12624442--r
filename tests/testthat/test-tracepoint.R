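test_that("panel layout follows the implicit delta-partition of A", {
  # gap-free 10 kb alignment at a panel boundary: 100 entries of 100
  tp <- encode_tracepoints(rep(0L, 10000), 0, 10000, 0, 10000, 100)
  expect_length(tp$b, 100L)
  expect_true(all(tp$b == 100L))
  # short first and last panels; conservation fixes the last at 50
  tp2 <- encode_tracepoints(rep(0L, 200), 50, 250, 0, 200, 100)
  expect_equal(tp2$b, c(50L, 100L, 50L))
  expect_equal(sum(tp2$b), 200L)
  # single-panel alignment
  tp3 <- encode_tracepoints(rep(0L, 40), 130, 170, 0, 40, 100)
  expect_equal(tp3$b, 40L)
})

test_that("B-panel sums are conserved and B-insertions go left", {
  set.seed(61)
  a <- random_dna(1200)
  b <- mutate_sequence(a, 0.1)
  r <- la_finder(a, b, 1200, -30, 30)
  tp <- encode_tracepoints(r$ops, r$ab, r$ae, r$bb, r$be, 100)
  expect_equal(sum(tp$b), r$be - r$bb)
  # insertion exactly at a boundary is charged to the left panel
  ops <- c(rep(0L, 100), 1L, 1L, rep(0L, 50))  # 2 inserted B bases at i=100
  tp2 <- encode_tracepoints(ops, 0, 150, 0, 152, 100)
  expect_equal(tp2$b, c(102L, 50L))
})

test_that("oversized panels raise the split signal", {
  ops <- c(rep(0L, 10), rep(1L, 300), rep(0L, 10))
  expect_error(encode_tracepoints(ops, 0, 20, 0, 320, 100),
               class = "adaptalign_tracepoint_overflow")
})

test_that("decode passes through every trace point with per-panel optimal diffs", {
  set.seed(62)
  a <- random_dna(5000)
  b <- mutate_sequence(a, 0.10)
  r <- la_finder(a, b, 5000, -80, 80)
  tp <- encode_tracepoints(r$ops, r$ab, r$ae, r$bb, r$be, 100)
  dec <- decode_tracepoints(tp, r$ab, r$ae, r$bb, r$be, a, b)
  # reconstruction consumes the stated intervals
  expect_equal(sum(dec$ops != 1L), r$ae - r$ab)
  expect_equal(sum(dec$ops != 2L), r$be - r$bb)
  # per-panel diffs equal the DP edit distance of each panel pair
  xs <- c(r$ab, adaptalign:::panel_boundaries(r$ab, r$ae, 100L), r$ae)
  ys <- r$bb + c(0L, cumsum(tp$b))
  dsum <- 0L
  for (k in seq_along(tp$b)) {
    pa <- substr(a, xs[k] + 1L, xs[k + 1L])
    pb <- substr(b, ys[k] + 1L, ys[k + 1L])
    dsum <- dsum + as.integer(adist(pa, pb))
  }
  expect_equal(dec$diffs, dsum)
  expect_lte(dec$diffs, r$diffs)
  # encode(decode(.)) is a fixed point of the trace-point array
  tp2 <- encode_tracepoints(dec$ops, r$ab, r$ae, r$bb, r$be, 100)
  expect_equal(tp2$b, tp$b)
  # identity alignment reconstructs identically
  tpi <- encode_tracepoints(rep(0L, 300), 0, 300, 0, 300, 100)
  deci <- decode_tracepoints(tpi, 0, 300, 0, 300, a, a)
  expect_equal(deci$diffs, 0L)
  expect_true(all(deci$ops == 0L))
})

test_that("indel arrays mark dash positions with non-decreasing magnitude", {
  expect_length(extract_indel_array(rep(0L, 10)), 0L)
  o <- extract_indel_array(c(0L, 0L, 1L, 0L, 0L, 2L, 0L))
  expect_equal(as.integer(o), c(3L, -6L))
  # A="acgt" vs B="acggt": one inserted B base
  r <- adaptalign:::cpp_align_global(adaptalign:::cpp_seq_to_codes("acgt"),
                                     adaptalign:::cpp_seq_to_codes("acggt"))
  oa <- extract_indel_array(r$ops)
  expect_length(oa, 1L)
  expect_gt(oa[1L], 0L)
  # round trip: padded rows -> path -> array -> padded rows
  set.seed(63)
  for (i in 1:20) {
    a <- random_dna(200)
    b <- mutate_sequence(a, 0.12)
    r <- adaptalign:::cpp_align_global(adaptalign:::cpp_seq_to_codes(a),
                                       adaptalign:::cpp_seq_to_codes(b))
    o <- extract_indel_array(r$ops)
    expect_true(all(diff(abs(as.integer(o))) >= 0L))
    # rebuild the path from the indel array and compare
    ops2 <- integer(0)
    i_a <- 0L; i_b <- 0L
    for (v in as.integer(o)) {
      if (v > 0L) {
        while (i_a < v - 1L) { ops2 <- c(ops2, 0L); i_a <- i_a + 1L
                               i_b <- i_b + 1L }
        ops2 <- c(ops2, 1L); i_b <- i_b + 1L
      } else {
        while (i_b < -v - 1L) { ops2 <- c(ops2, 0L); i_a <- i_a + 1L
                                i_b <- i_b + 1L }
        ops2 <- c(ops2, 2L); i_a <- i_a + 1L
      }
    }
    while (i_a < 200L) { ops2 <- c(ops2, 0L); i_a <- i_a + 1L }
    expect_equal(ops2, r$ops)
  }
})

test_that("refinable segments require same sign, length 2+, separation < R", {
  expect_length(find_refinable_segments(c(3L, 5L)), 1L)
  expect_length(find_refinable_segments(c(3L, -5L)), 0L)
  expect_length(find_refinable_segments(c(3L, 60L), R = 50L), 0L)
  segs <- find_refinable_segments(c(3L, 5L, 100L, 101L, -120L, -130L))
  expect_equal(segs, list(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
})

test_that("refine_segment attains the exhaustive minimum of gaps + mismatches", {
  # an already-contiguous gap stays one gap, k = 1
  tr <- trapezoid("acgtac", "acgGGtac")
  # (wherever the wave puts the 2-base gap, k must equal the dense-DP min)
  got <- refine_segment(tr)
  expect_equal(got$k, refine_dp_oracle("acgtac", "acgGGtac"))
  # two 1-base insertions two bases apart merge into one gap for <= 1
  # mismatch: A = "gg", B places "t g g t"-style options; enumeration decides
  set.seed(64)
  for (i in 1:60) {
    L <- sample(2:10, 1); D <- sample(2:4, 1)
    A <- random_dna(L); B <- random_dna(L + D)
    got <- refine_segment(trapezoid(A, B))
    expect_equal(got$k, refine_enum_oracle(A, B))
    expect_equal(got$k, got$gaps + got$mismatches)
    expect_equal(sum(got$ops != 1L), L)
    expect_equal(sum(got$ops == 1L), D)
  }
  # dense-DP oracle over the full advertised range
  for (i in 1:60) {
    L <- sample(2:20, 1); D <- sample(2:6, 1)
    A <- random_dna(L); B <- random_dna(L + D)
    expect_equal(refine_segment(trapezoid(A, B))$k,
                 refine_dp_oracle(A, B))
  }
})

test_that("merging two nearby 1-base gaps for one mismatch is chosen", {
  # two separated 1-base insertions can align B = "tagg" to A = "ag"
  # perfectly (2 gaps, 0 mismatches); merging them into one 2-base gap
  # costs one mismatch, the same k = 2, and the fewer-gaps form must win
  A <- "ag"
  B <- "tagg"
  got <- refine_segment(trapezoid(A, B))
  expect_equal(got$k, refine_enum_oracle(A, B))
  expect_lte(got$gaps, 1L)
  # a run that is already one contiguous gap stays one gap with k = 1
  got2 <- refine_segment(trapezoid("ca", "ttca"))
  expect_equal(got2$k, 1L)
  expect_equal(got2$gaps, 1L)
})

test_that("path refinement reduces gaps, preserves endpoints and re-encodes", {
  set.seed(65)
  worse <- 0L
  for (i in 1:40) {
    a <- random_dna(600)
    b <- mutate_sequence(a, 0.15)
    r <- la_finder(a, b, 600, -40, 40)
    if (r$ae == r$ab) next
    rf <- refine_path(r$ops, a, b, r$ab, r$bb)
    expect_lte(rf$gaps_after, rf$gaps_before)
    expect_equal(sum(rf$ops != 1L), r$ae - r$ab)
    expect_equal(sum(rf$ops != 2L), r$be - r$bb)
    expect_equal(rf$diffs, path_diffs_oracle(rf$ops, a, b, r$ab, r$bb))
    # refined panels still fit in one byte
    tp <- encode_tracepoints(rf$ops, r$ab, r$ae, r$bb, r$be, 100)
    expect_true(all(tp$b <= 255L))
    if (rf$gaps_after > rf$gaps_before) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("refine_alignment preserves endpoints and updates trace points", {
  set.seed(67)
  a <- random_dna(800)
  b <- mutate_sequence(a, 0.12)
  r <- la_finder(a, b, 800, -40, 40)
  aln <- adaptalign:::new_alignment(NA_integer_, NA_integer_, "+", r$ab,
                                    r$ae, r$bb, r$be, r$diffs, ops = r$ops,
                                    tracepoints = encode_tracepoints(
                                      r$ops, r$ab, r$ae, r$bb, r$be, 100))
  ref <- refine_alignment(aln, a, b)
  expect_equal(c(ref$ab, ref$ae, ref$bb, ref$be),
               c(aln$ab, aln$ae, aln$bb, aln$be))
  expect_equal(sum(ref$tracepoints$b), ref$be - ref$bb)
  expect_equal(ref$diffs, path_diffs_oracle(ref$ops, a, b, ref$ab, ref$bb))
  # an alignment with no refinable segments is unchanged
  s <- random_dna(300)
  ident <- adaptalign:::new_alignment(NA_integer_, NA_integer_, "+", 0L,
                                      300L, 0L, 300L, 0L,
                                      ops = rep(0L, 300))
  ref2 <- refine_alignment(ident, s, s)
  expect_equal(ref2$ops, rep(0L, 300))
  expect_equal(ref2$diffs, 0L)
})

test_that("CIGAR strings consume the intervals and round-trip the path", {
  s <- random_dna(100)
  expect_equal(alignment_to_cigar(rep(0L, 100), s, s, dialect = "M"),
               "100M")
  expect_equal(alignment_to_cigar(rep(0L, 100), s, s, dialect = "=X"),
               "100=")
  set.seed(66)
  for (i in 1:15) {
    a <- random_dna(300)
    b <- mutate_sequence(a, 0.1)
    r <- adaptalign:::cpp_align_global(adaptalign:::cpp_seq_to_codes(a),
                                       adaptalign:::cpp_seq_to_codes(b))
    cg <- alignment_to_cigar(r$ops, a, b, dialect = "=X")
    runs <- cigar_runs(cg)
    expect_equal(sum(runs$len[runs$op %in% c("=", "X", "I")]), 300L)
    expect_equal(sum(runs$len[runs$op %in% c("=", "X", "D")]), nchar(b))
    # parse back to ops: = and X are diagonal, D consumes B, I consumes A
    ops2 <- unlist(mapply(function(l, o) rep(switch(o, "=" = 0L, "X" = 0L,
                                                    "D" = 1L, "I" = 2L), l),
                          runs$len, runs$op, SIMPLIFY = FALSE))
    expect_equal(ops2, r$ops)
  }
})
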