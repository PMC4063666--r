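#' Origin rows for a genome specification
#'
#' Convenience constructor for the \code{origins} slot of a
#' [GenomeSpec-class]: one row per origin with its re-initiation
#' efficiency (fraction of cells that re-initiate it during an M-phase
#' induction) and optional S-phase kinetics.
#'
#' @param chrom chromosome name(s).
#' @param position 1-based bp position(s).
#' @param efficiency re-initiation efficiency in [0, 1].
#' @param sphaseTime S-phase firing time in minutes (optional).
#' @param sphaseEff S-phase firing efficiency in [0, 1] (optional).
#' @return data.frame suitable for [genomeSpec()].
#' @export
originSpec <- function(chrom, position, efficiency,
                       sphaseTime = NA_real_, sphaseEff = NA_real_) {
  data.frame(chrom = chrom, position = position, efficiency = efficiency,
             sphaseTime = sphaseTime, sphaseEff = sphaseEff)
}

#' Construct a genome specification
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param origins data.frame from [originSpec()] (default: none).
#' @param masked \code{GRanges} of masked repetitive intervals (1-based,
#'   inclusive; default: none).
#' @return A [GenomeSpec-class].
#' @examples
#' gs <- genomeSpec(c(chrS = 5e5),
#'                  origins = originSpec("chrS", 2.5e5, efficiency = 0.5))
#' gs
#' @export
genomeSpec <- function(chromosomes,
                       origins = originSpec(character(), numeric(), numeric()),
                       masked = GenomicRanges::GRanges()) {
  new("GenomeSpec", chromosomes = chromosomes, origins = origins,
      masked = masked)
}

#' Construct a simulation configuration
#'
#' Defaults describe a 6 hr M-phase re-replication induction sampled on a
#' 1 kb probe grid: fork speed 111 bp/min so that forks spread 40 kb over
#' the induction (yeast replication forks move on the order of 1-3 kb/min
#' in S phase; re-replication forks are slower and fire throughout the
#' induction, so the effective spreading rate is far lower), log-intensity
#' noise SD 0.1 per channel, two replicate strains, and a 2C M-arrest
#' target content.
#'
#' @param forkSpeed fork speed, bp/min.
#' @param inductionMinutes induction duration, min.
#' @param probeSpacing probe spacing, bp.
#' @param noiseSigma SD of per-channel log-intensity noise.
#' @param nReplicates number of replicate samples.
#' @param seed master integer seed.
#' @param targetContent DNA content the genome mean represents (2 for an
#'   M arrest, 1.5 for mid-S).
#' @param gainCy3,gainCy5 arbitrary positive channel gains.
#' @param rounds re-initiation rounds multiplier (1 = single round).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(forkSpeed = 40000 / 360, inductionMinutes = 360,
                      probeSpacing = 1000, noiseSigma = 0.1,
                      nReplicates = 2L, seed = 1L, targetContent = 2,
                      gainCy3 = 1, gainCy5 = 1, rounds = 1) {
  new("SimConfig", forkSpeed = forkSpeed,
      inductionMinutes = inductionMinutes, probeSpacing = probeSpacing,
      noiseSigma = noiseSigma, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed), targetContent = targetContent,
      gainCy3 = gainCy3, gainCy5 = gainCy5, rounds = rounds)
}

# Run code under a derived seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate stream seed, kept below 2^31.
replicateSeed <- function(seed, replicateIndex) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(replicateIndex) * 104729 +
                1) %% .Machine$integer.max)
}

#' Expected re-replication copy-number profile
#'
#' The generative model for an M-phase re-replication induction. Each
#' origin o re-initiates in a fraction \eqn{\epsilon_o} of cells; a
#' re-initiating cell gains one extra copy per sister chromatid (2 per
#' cell) at the origin, and bidirectional forks spread the extra copies
#' outward. With re-initiation times uniform over the induction and forks
#' moving at v bp/min for T minutes, the population-average DNA content is
#' \deqn{C(x) = 2 + 2 \sum_o \epsilon_o \max(0, 1 - d_o(x) / (vT))}
#' a triangular peak of height \eqn{2\epsilon_o} and half-width vT at each
#' origin. A \code{rounds} multiplier > 1 scales the extra copies to
#' approximate multi-round onion-skin re-replication.
#'
#' @param genome a [GenomeSpec-class].
#' @param cfg a [SimConfig-class].
#' @return A function \code{f(chrom, pos)} returning expected DNA content
#'   (C units) at 1-based positions \code{pos} on \code{chrom}.
#' @examples
#' gs <- genomeSpec(c(chrS = 5e5),
#'                  origins = originSpec("chrS", 2.5e5, efficiency = 0.5))
#' C <- expectedRerepProfile(gs, simConfig())
#' C("chrS", 2.5e5)  # 2 + 2 * 0.5 = 3 at the peak center
#' @export
expectedRerepProfile <- function(genome, cfg) {
  stopifnot(is(genome, "GenomeSpec"), is(cfg, "SimConfig"))
  ori <- genome@origins
  reach <- cfg@forkSpeed * cfg@inductionMinutes
  rounds <- cfg@rounds
  function(chrom, pos) {
    stopifnot(chrom %in% names(genome@chromosomes))
    content <- rep(2, length(pos))
    oo <- ori[ori$chrom == chrom, , drop = FALSE]
    if (nrow(oo) && reach > 0) {
      for (i in seq_len(nrow(oo))) {
        d <- abs(pos - oo$position[i])
        content <- content +
          2 * rounds * oo$efficiency[i] * pmax(0, 1 - d / reach)
      }
    }
    content
  }
}

#' Expected S-phase copy-number profile
#'
#' DNA content of a population harvested part-way through a
#' hydroxyurea-slowed S phase. Origin o fires at time \eqn{\tau_o} in a
#' fraction \eqn{e_o} of cells; a locus x is replicated in a cell if any
#' fired origin's fork has reached it by harvest, so with independent
#' origins the replicated fraction is
#' \deqn{f(x) = 1 - \prod_o (1 - e_o 1[d_o(x) \le v \max(0, t - \tau_o)])}
#' and content is \eqn{1 + f(x)}, ranging 1C (unreplicated) to 2C.
#'
#' @param genome a [GenomeSpec-class] whose origins carry
#'   \code{sphaseTime} and \code{sphaseEff}.
#' @param cfg a [SimConfig-class] (fork speed is taken from here).
#' @param harvestMinutes harvest time t in minutes after release.
#' @return A function \code{f(chrom, pos)} returning expected content in
#'   [1, 2].
#' @export
expectedSphaseProfile <- function(genome, cfg, harvestMinutes) {
  stopifnot(is(genome, "GenomeSpec"), is(cfg, "SimConfig"),
            harvestMinutes >= 0)
  ori <- genome@origins
  if (nrow(ori) && (any(is.na(ori$sphaseTime)) || any(is.na(ori$sphaseEff))))
    stop("origins lack S-phase parameters (sphaseTime / sphaseEff)")
  if (nrow(ori) && (any(ori$sphaseEff < 0) || any(ori$sphaseEff > 1)))
    stop("sphaseEff must be in [0, 1]")
  v <- cfg@forkSpeed
  function(chrom, pos) {
    stopifnot(chrom %in% names(genome@chromosomes))
    unrep <- rep(1, length(pos))
    oo <- ori[ori$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(oo))) {
      reach <- v * max(0, harvestMinutes - oo$sphaseTime[i])
      # a just-fired origin (reach 0) has copied nothing yet
      covered <- reach > 0 & abs(pos - oo$position[i]) <= reach
      unrep <- unrep * (1 - oo$sphaseEff[i] * as.numeric(covered))
    }
    1 + (1 - unrep)
  }
}

#' Simulate a two-channel probe table
#'
#' Emulates competitive hybridization of induced (Cy5) against uninduced
#' reference (Cy3) DNA on a uniform probe grid: probes every
#' \code{probeSpacing} bp, \code{cy5 = gainCy5 * C(x) * exp(N(0, sigma^2))}
#' and \code{cy3 = gainCy3 * 2 * exp(N(0, sigma^2))} with independent
#' log-normal noise per channel and probe. Probes inside the genome's
#' masked intervals are flagged. The random stream is derived
#' deterministically from \code{(cfg@seed, replicateIndex)}, so the same
#' pair always reproduces the same table, and the caller's RNG state is
#' left untouched.
#'
#' @param genome a [GenomeSpec-class].
#' @param cfg a [SimConfig-class].
#' @param replicateIndex 1-based replicate number.
#' @param profileFun expected-content function such as
#'   [expectedRerepProfile()] output; defaults to the re-replication model.
#' @return A [ProbeTable-class].
#' @examples
#' gs <- genomeSpec(c(chrS = 1e5),
#'                  origins = originSpec("chrS", 5e4, efficiency = 0.5))
#' pt <- simulateProbeTable(gs, simConfig(noiseSigma = 0), 1L)
#' pt
#' @export
simulateProbeTable <- function(genome, cfg, replicateIndex = 1L,
                               profileFun = expectedRerepProfile(genome, cfg)) {
  stopifnot(is(genome, "GenomeSpec"), is(cfg, "SimConfig"),
            replicateIndex >= 1)
  chroms <- names(genome@chromosomes)
  tabs <- lapply(chroms, function(ch) {
    L <- genome@chromosomes[[ch]]
    pos <- seq(cfg@probeSpacing, L, by = cfg@probeSpacing)
    data.frame(chrom = ch, pos = pos, content = profileFun(ch, pos))
  })
  df <- do.call(rbind, tabs)
  df <- df[order(df$chrom, df$pos), ]
  n <- nrow(df)
  noise <- withSeed(replicateSeed(cfg@seed, replicateIndex), {
    matrix(stats::rnorm(2 * n, sd = cfg@noiseSigma), ncol = 2)
  })
  probes <- data.frame(
    chrom = df$chrom, pos = df$pos,
    cy3 = cfg@gainCy3 * 2 * exp(noise[, 1]),
    cy5 = cfg@gainCy5 * df$content * exp(noise[, 2]),
    masked = maskFlags(df$chrom, df$pos, genome@masked))
  rownames(probes) <- NULL
  new("ProbeTable", probes = probes)
}

# TRUE for positions falling inside 1-based inclusive masked intervals.
maskFlags <- function(chrom, pos, masked) {
  if (!length(masked)) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, masked)
}

#' Write an expected-content track as bedGraph
#'
#' Evaluates a profile function on each chromosome's probe grid and writes
#' a bedGraph (0-based half-open) ground-truth track.
#'
#' @param genome a [GenomeSpec-class].
#' @param cfg a [SimConfig-class] (probe spacing sets the grid).
#' @param path output path.
#' @param profileFun expected-content function; defaults to the
#'   re-replication model.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruth <- function(genome, cfg, path,
                             profileFun = expectedRerepProfile(genome, cfg)) {
  rows <- lapply(names(genome@chromosomes), function(ch) {
    L <- genome@chromosomes[[ch]]
    pos <- seq(cfg@probeSpacing, L, by = cfg@probeSpacing)
    data.frame(chrom = ch, start = pos - 1, end = pos,
               value = profileFun(ch, pos))
  })
  df <- do.call(rbind, rows)
  writeLines(c(sprintf("# rerepCGH ground truth; seed=%d", cfg@seed),
               sprintf("%s\t%d\t%d\t%.10g", df$chrom, df$start, df$end,
                       df$value)),
             path)
  invisible(path)
}
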