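mk_hits <- function(pi, pj, t = 16L, strand = "+", len_h = 100000L) {
  data.frame(contig_g = 1L, pos_g = as.integer(pi), contig_h = 1L,
             pos_h = as.integer(pj), strand = strand, t = as.integer(t),
             len_h = as.integer(len_h), stringsAsFactors = FALSE)
}

test_that("band records encode (b, a, r) with exact reconstruction", {
  cp <- chain_params(D = 64)
  br <- hits_to_band_records(mk_hits(100, 36), cp)
  expect_equal(br$b, 1L)
  expect_equal(br$r, 0L)
  expect_equal(br$a, 136L)
  # reconstruction identity on random hits, including negative diagonals
  set.seed(41)
  h <- mk_hits(sample(0:5000, 300, TRUE), sample(0:5000, 300, TRUE))
  br <- hits_to_band_records(h, cp)
  pi2 <- (br$a + (64L * br$b + br$r)) / 2L
  pj2 <- (br$a - (64L * br$b + br$r)) / 2L
  expect_setequal(paste(pi2, pj2), paste(h$pos_g, h$pos_h))
  expect_true(all(br$r >= 0L & br$r < 64L))
  expect_true(any(br$b < 0L))  # pi < pj gives negative bands
})

test_that("records come back sorted on the chain sort key", {
  set.seed(42)
  h <- mk_hits(sample(0:9999, 200, TRUE), sample(0:9999, 200, TRUE),
               strand = sample(c("+", "-"), 200, TRUE))
  br <- hits_to_band_records(h)
  key <- order(br$contig_g, br$contig_h, br$strand, br$b, br$a)
  expect_equal(key, seq_len(nrow(br)))
})

test_that("close collinear seeds chain; distant seeds split", {
  cp <- chain_params(D = 64, A = 1000)
  tb <- find_chains(hits_to_band_records(mk_hits(c(100, 300),
                                                 c(100, 300)), cp), cp)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$a_low, 200L)
  expect_equal(tb$a_high, 600L + 32L)
  tb2 <- find_chains(hits_to_band_records(mk_hits(c(100, 5000),
                                                  c(100, 5000)), cp), cp)
  expect_equal(nrow(tb2), 2L)
})

test_that("tube set equals brute-force chain construction", {
  set.seed(43)
  cp <- chain_params(D = 64, A = 1000)
  h <- mk_hits(sample(0:20000, 500, TRUE), sample(0:20000, 500, TRUE))
  br <- hits_to_band_records(h, cp)
  got <- find_chains(br, cp)
  # oracle: for every band pair (b, b+1), sort member seeds by a, cut at
  # end-to-start gaps > A, build tube extents, deduplicate by seed set
  diag <- 64L * br$b + br$r
  tubes <- list()
  for (b in sort(unique(c(br$b - 1L, br$b)))) {
    rows <- which(br$b == b | br$b == b + 1L)
    rows <- rows[order(br$a[rows], rows)]
    cur <- integer(0)
    flush <- function(cur) {
      if (!length(cur)) return(NULL)
      list(seeds = sort(cur), d_low = min(diag[cur]),
           d_high = max(diag[cur]), a_low = min(br$a[cur]),
           a_high = max(br$a[cur] + 2L * br$t[cur]))
    }
    last_end <- NULL
    for (r in rows) {
      if (length(cur) && br$a[r] - (br$a[cur[length(cur)]] +
                                    2L * br$t[cur[length(cur)]]) > 1000L) {
        tubes[[length(tubes) + 1L]] <- flush(cur)
        cur <- integer(0)
      }
      cur <- c(cur, r)
    }
    if (length(cur)) tubes[[length(tubes) + 1L]] <- flush(cur)
  }
  sig <- vapply(tubes, function(tb) paste(tb$seeds, collapse = ","),
                character(1))
  tubes <- tubes[!duplicated(sig)]
  okey <- sort(vapply(tubes, function(tb)
    paste(tb$d_low, tb$d_high, tb$a_low, tb$a_high), character(1)))
  gkey <- sort(paste(got$d_low, got$d_high, got$a_low, got$a_high))
  expect_equal(gkey, okey)
  # coverage: every seed lies in at least one tube
  for (r in seq_len(nrow(br))) {
    d <- diag[r]; a <- br$a[r]
    expect_true(any(got$d_low <= d & d <= got$d_high &
                      got$a_low <= a & a + 2L * br$t[r] <= got$a_high))
  }
})

test_that("doubling the band width barely changes aligned coverage", {
  set.seed(44)
  sp <- sim_params(region_lengths = c(500L, 2000L),
                   divergences = c(0.05, 0.15), replicates = 3L)
  sim <- simulate_genome_pair(sp)
  gA <- gdb_from_sequences(sim$A)
  gB <- gdb_from_sequences(sim$B)
  cov_for <- function(D) {
    alns <- align_genomes(gA, gB, chain_par = chain_params(D = D))
    iv <- do.call(rbind, lapply(alns, function(a) c(a$ab, a$ae)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    tot <- 0L; hi <- -1L
    for (r in seq_len(nrow(iv))) {
      s <- max(iv[r, 1L], hi); e <- iv[r, 2L]
      if (e > s) tot <- tot + (e - s)
      hi <- max(hi, e)
    }
    tot
  }
  c64 <- cov_for(64L)
  c128 <- cov_for(128L)
  expect_lt(abs(c128 - c64) / c64, 0.02)
})

test_that("strands are chained separately", {
  cp <- chain_params()
  h <- mk_hits(c(100, 300), c(100, 300), strand = c("+", "-"))
  tb <- find_chains(hits_to_band_records(h, cp), cp)
  expect_equal(nrow(tb), 2L)
  expect_setequal(tb$strand, c("+", "-"))
})
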