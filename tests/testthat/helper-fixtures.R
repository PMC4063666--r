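# Shared fixtures, built in code at test time.

# Single-origin genome emulating an M-phase re-replication induction:
# one 4 Mb chromosome so the peak is a small fraction of the genome,
# as for a real origin on a real chromosome.
makeRerepGenome <- function(chromLen = 4e6, originPos = chromLen / 2,
                            efficiency = 0.5,
                            masked = GenomicRanges::GRanges()) {
  genomeSpec(c(chrS = chromLen),
             origins = originSpec("chrS", originPos,
                                  efficiency = efficiency),
             masked = masked)
}

# Simulate replicates and run the full profile pipeline on chrS.
# kernel 2 kb: quantification-grade smoothing, well below the 40 kb peak
# half-width so apex attenuation stays small.
runPipeline <- function(genome, cfg, kernel = 2, windowBp = 10000,
                        replicates = seq_len(cfg@nReplicates)) {
  pts <- lapply(replicates, function(r) simulateProbeTable(genome, cfg, r))
  profilePipeline(pts, "chrS", chromLen = genome@chromosomes[["chrS"]],
                  masks = genome@masked, windowBp = windowBp,
                  kernel = kernel)
}

# Path to the bundled printed spacer-insert sequences.
insertFastaPath <- function() {
  system.file("extdata", "spacing_insert_sequences.fasta",
              package = "rerepCGH", mustWork = TRUE)
}

# Brute-force circular moving median at every probe (the oracle).
bruteMovingMedian <- function(positions, values, mask, chromLen, windowBp) {
  h <- windowBp / 2
  out <- rep(NA_real_, length(positions))
  for (i in seq_along(positions)) {
    if (mask[i]) next
    d <- abs(positions - positions[i])
    d <- pmin(d, chromLen - d)
    inWin <- d <= h & !mask
    if (any(inWin)) out[i] <- stats::median(values[inWin])
  }
  out
}
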