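make_pair <- function(seed = 71, n = 3000, div = 0.08) {
  set.seed(seed)
  a <- random_dna(n)
  b <- mutate_sequence(a, div)
  gA <- gdb_from_sequences(c(chrA = a))
  gB <- gdb_from_sequences(c(chrB = b))
  list(gA = gA, gB = gB, alns = align_genomes(gA, gB))
}

test_that("PAF records carry the 12 mandatory columns with sane values", {
  p <- make_pair()
  expect_gte(length(p$alns), 1L)
  lines <- write_paf(p$alns, p$gA, p$gB)
  paf <- read_paf(text = lines)
  expect_true(all(paf$qname == "chrA" & paf$tname == "chrB"))
  expect_true(all(paf$qstart >= 0 & paf$qend <= paf$qlen))
  expect_true(all(paf$tstart >= 0 & paf$tend <= paf$tlen))
  expect_true(all(paf$matches <= paf$blocklen))
  expect_true(all(paf$mapq == 255L))
  expect_true(all(grepl("cg:Z:", paf$tags)))
})

test_that("an identity self-alignment gives matches == block length", {
  set.seed(72)
  g <- gdb_from_sequences(c(s = random_dna(4000)))
  alns <- align_genomes(g, g)
  paf <- read_paf(text = write_paf(alns, g, g))
  full <- paf[paf$qstart == 0 & paf$qend == 4000 & paf$strand == "+", ]
  expect_gte(nrow(full), 1L)
  expect_equal(full$matches, full$blocklen)
})

test_that("reverse-strand PAF reports forward target coordinates", {
  set.seed(73)
  reg <- random_dna(2000)
  gA <- gdb_from_sequences(c(a = paste0(random_dna(400), reg,
                                        random_dna(400))))
  gB <- gdb_from_sequences(c(b = paste0(random_dna(600),
                                        reverse_complement(reg),
                                        random_dna(200))))
  alns <- align_genomes(gA, gB)
  paf <- read_paf(text = write_paf(alns, gA, gB))
  rev <- paf[paf$strand == "-", ]
  expect_gte(nrow(rev), 1L)
  expect_true(all(rev$tstart < rev$tend))
  # the reverse-complemented target interval matches the query interval
  r <- rev[which.max(rev$qend - rev$qstart), ]
  tseq <- substr(contig_seq(gB, 1L), r$tstart + 1L, r$tend)
  qseq <- substr(contig_seq(gA, 1L), r$qstart + 1L, r$qend)
  d <- as.integer(adist(qseq, reverse_complement(tseq)))
  expect_lte(d / nchar(qseq), 0.1)
  # CIGAR bookkeeping consumes exactly the two intervals
  cg <- sub(".*cg:Z:([^\t]*).*", "\\1", r$tags)
  runs <- cigar_runs(cg)
  expect_equal(sum(runs$len[runs$op %in% c("=", "X", "I")]),
               r$qend - r$qstart)
  expect_equal(sum(runs$len[runs$op %in% c("=", "X", "D")]),
               r$tend - r$tstart)
})

test_that("PSL rows have 21 columns and block counts match gap-free runs", {
  p <- make_pair(seed = 74, div = 0.1)
  psl <- write_psl(p$alns, p$gA, p$gB)
  expect_gte(length(psl), 1L)
  for (i in seq_along(psl)) {
    f <- strsplit(psl[i], "\t")[[1L]]
    expect_length(f, 21L)
    aln <- p$alns[[i]]
    pth <- adaptalign:::alignment_path(aln, p$gA, p$gB, refine = TRUE)
    runs <- rle(pth$ops)
    expect_equal(as.integer(f[18L]), sum(runs$values == 0L))
    sizes <- as.integer(strsplit(f[19L], ",")[[1L]])
    expect_equal(sum(sizes), sum(pth$ops == 0L))
  }
})

test_that("ALN documents round-trip losslessly", {
  p <- make_pair(seed = 75, n = 5000, div = 0.1)
  # add synthetic alignments to exercise many records
  set.seed(76)
  alns <- p$alns
  for (i in 1:200) {
    ab <- sample(0:2000, 1)
    len <- sample(100:900, 1)
    nb <- sample(1:9, 1)
    b <- as.integer(sample(40:160, nb, TRUE))
    tp <- structure(list(delta = 100L, b = b), class = "TracePointArray")
    alns[[length(alns) + 1L]] <- adaptalign:::new_alignment(
      1L, 1L, sample(c("+", "-"), 1), ab, ab + len, ab, ab + sum(b),
      sample(0:50, 1), tracepoints = tp)
  }
  tf <- withr::local_tempfile(fileext = ".aln")
  write_aln(alns, tf)
  back <- read_aln(tf)
  expect_length(back, length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]; b <- back[[i]]
    expect_equal(b$contig_g, a$contig_g)
    expect_equal(b$contig_h, a$contig_h)
    expect_equal(b$strand, a$strand)
    expect_equal(c(b$ab, b$ae, b$bb, b$be), c(a$ab, a$ae, a$bb, a$be))
    expect_equal(b$diffs, a$diffs)
    expect_equal(b$tracepoints$delta, a$tracepoints$delta)
    expect_equal(b$tracepoints$b, a$tracepoints$b)
  }
  # header counts match record tallies; all codes declared
  lines <- readLines(tf)
  nA <- as.integer(sub("^# A ", "", grep("^# A ", lines, value = TRUE)))
  expect_equal(nA, length(alns))
  # empty set gives a header-only valid document
  tf2 <- withr::local_tempfile(fileext = ".aln")
  write_aln(list(), tf2)
  expect_length(read_aln(tf2), 0L)
})

test_that("trace-point storage is far smaller than =X CIGAR PAF", {
  set.seed(77)
  a <- random_dna(10000)
  b <- mutate_sequence(a, 0.20)
  gA <- gdb_from_sequences(c(a = a))
  gB <- gdb_from_sequences(c(b = b))
  alns <- align_genomes(gA, gB, align_par = align_params())
  expect_gte(length(alns), 1L)
  keep <- which.max(vapply(alns, function(x) x$ae - x$ab, integer(1)))
  aln <- alns[keep]
  tf_aln <- withr::local_tempfile(fileext = ".aln")
  tf_paf <- withr::local_tempfile(fileext = ".paf")
  write_aln(aln, tf_aln)
  write_paf(aln, gA, gB, file = tf_paf, cigar = "=X")
  # compare the per-record payload (drop the ALN header)
  body <- grep("^[ADT] ", readLines(tf_aln), value = TRUE)
  expect_lt(sum(nchar(body)), file.size(tf_paf) / 5)
})
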