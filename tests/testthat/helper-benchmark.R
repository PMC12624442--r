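# Scaled planted-truth benchmark shared by the acceptance suite: region
# lengths 500-5000 bp, divergences 1-20%, 10 replicates per cell (200
# blocks of 10 kb per genome).  Built once per test run.
scaled_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4235711L)
      sp <- sim_params(region_lengths = c(500L, 1000L, 2000L, 5000L),
                       divergences = c(0.01, 0.05, 0.10, 0.15, 0.20),
                       replicates = 10L)
      sim <- simulate_genome_pair(sp)
      gA <- gdb_from_sequences(sim$A)
      gB <- gdb_from_sequences(sim$B)
      alns <- align_genomes(gA, gB)
      paf <- read_paf(text = write_paf(alns, gA, gB, cigar = "none"))
      cache <<- list(sim = sim, alns = alns, gA = gA, gB = gB,
                     eval = evaluate_alignments(paf, sim$truth))
    }
    cache
  }
})
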