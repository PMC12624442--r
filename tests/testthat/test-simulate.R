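test_that("zero divergence returns the sequence unchanged with empty log", {
  set.seed(81)
  s <- random_dna(500)
  m <- mutate_sequence(s, 0)
  expect_equal(as.character(m), s)
  expect_equal(nrow(attr(m, "edit_log")), 0L)
})

test_that("replaying the edit log reproduces the mutated sequence", {
  set.seed(82)
  for (i in 1:20) {
    s <- random_dna(400)
    m <- mutate_sequence(s, 0.12)
    log <- attr(m, "edit_log")
    # independent replay in original coordinates, right to left
    ch <- strsplit(s, "")[[1L]]
    for (k in rev(seq_len(nrow(log)))) {
      p <- log$pos[k]
      if (log$op[k] == "sub") ch[p] <- log$base[k]
      else if (log$op[k] == "del") ch <- ch[-p]
      else ch <- append(ch, log$base[k], after = p - 1L)
    }
    expect_equal(paste(ch, collapse = ""), as.character(m))
    # substitutions never rewrite the original base
    subs <- log[log$op == "sub", ]
    expect_true(all(substring(s, subs$pos, subs$pos) != subs$base))
  }
})

test_that("edit count and coordinates track the requested divergence", {
  set.seed(83)
  s <- random_dna(2000)
  m <- mutate_sequence(s, 0.10)
  log <- attr(m, "edit_log")
  expect_equal(nrow(log), 200L)
  expect_true(all(log$pos >= 1L & log$pos <= 2000L))
  expect_equal(anyDuplicated(log$pos), 0L)
})

test_that("the default grid implies 84 Mb genomes; scaled runs match", {
  expect_equal(sim_genome_length(sim_params()), 84e6)
  set.seed(84)
  sp <- sim_params(region_lengths = c(200L, 500L), divergences = c(0.05),
                   replicates = 3L, block_len = 2000L)
  sim <- simulate_genome_pair(sp)
  expect_equal(unname(nchar(sim$A)), sim_genome_length(sp))
  expect_equal(unname(nchar(sim$B)), sim_genome_length(sp))
  expect_equal(nrow(sim$truth), 6L)
})

test_that("generation is deterministic under a fixed seed", {
  sp <- sim_params(region_lengths = 300L, divergences = 0.1,
                   replicates = 2L, block_len = 1000L)
  set.seed(85); s1 <- simulate_genome_pair(sp)
  set.seed(85); s2 <- simulate_genome_pair(sp)
  expect_identical(s1, s2)
})

test_that("truth intervals are consistent with the emitted sequences", {
  set.seed(86)
  sp <- sim_params(region_lengths = c(300L, 600L),
                   divergences = c(0.05, 0.2), replicates = 2L,
                   block_len = 1500L)
  sim <- simulate_genome_pair(sp)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ra <- substr(sim$A, tr$a_start + 1L, tr$a_end)
    rb <- substr(sim$B, tr$b_start + 1L, tr$b_end)
    d <- as.integer(adist(ra, rb))
    expect_lte(d, ceiling(1.2 * tr$divergence * tr$length))
    if (tr$divergence > 0) expect_gt(d, 0L)
  }
})

test_that("the evaluator scores truth-matching alignments perfectly", {
  truth <- data.frame(a_start = c(0L, 10000L), a_end = c(500L, 11000L),
                      b_start = c(5000L, 0L), b_end = c(5500L, 1000L),
                      length = c(500L, 1000L), divergence = c(0.05, 0.05),
                      replicate = 1:2)
  paf <- data.frame(qstart = c(0L, 10000L), qend = c(500L, 11000L),
                    tstart = c(5000L, 0L), tend = c(5500L, 1000L))
  ev <- evaluate_alignments(paf, truth)
  expect_equal(sum(ev$cells$complete), 2L)
  expect_equal(ev$false_positives, 0L)
  expect_equal(ev$false_bases, 0L)
})

test_that("an alignment spanning two target regions is a false positive", {
  truth <- data.frame(a_start = c(0L, 10000L), a_end = c(500L, 10500L),
                      b_start = c(0L, 10000L), b_end = c(500L, 10500L),
                      length = 500L, divergence = 0.05, replicate = 1:2)
  paf <- data.frame(qstart = 0L, qend = 10500L, tstart = 0L, tend = 10500L)
  ev <- evaluate_alignments(paf, truth)
  expect_equal(ev$false_positives, 1L)
})

test_that("false bases equal a brute-force per-position count", {
  set.seed(87)
  truth <- data.frame(a_start = c(100L, 900L), a_end = c(400L, 1300L),
                      b_start = c(0L, 500L), b_end = c(300L, 900L),
                      length = c(300L, 400L), divergence = 0.1,
                      replicate = 1:2)
  paf <- data.frame(qstart = sample(0:1200, 8), tstart = 0L)
  paf$qend <- paf$qstart + sample(50:400, 8, TRUE)
  paf$tend <- paf$tstart + (paf$qend - paf$qstart)
  ev <- evaluate_alignments(paf, truth)
  covered <- logical(3000)
  for (i in seq_len(nrow(paf)))
    covered[(paf$qstart[i] + 1L):paf$qend[i]] <- TRUE
  target <- logical(3000)
  for (i in seq_len(nrow(truth)))
    target[(truth$a_start[i] + 1L):truth$a_end[i]] <- TRUE
  expect_equal(ev$false_bases, sum(covered & !target))
})
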