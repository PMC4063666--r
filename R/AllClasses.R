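#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Origin-relative segment of DNA
#'
#' A segment of origin-adjacent DNA located by two origin-relative
#' coordinates. Coordinates number the T-rich strand of the ORC binding
#' site (OBS) +1..+33 in the 5' to 3' direction; positions beyond +33
#' (the B-domain side) are +34 and higher, positions 5' of +1 (the
#' C-domain side) are negative, and there is no position zero: -1 is
#' immediately followed by +1. Fragment names in the field are written
#' \code{name(hi..lo)}, e.g. \code{317(+300..-106)}.
#'
#' @slot originName character name of the origin the coordinates anchor to.
#' @slot hi integer coordinate with the larger linear index.
#' @slot lo integer coordinate with the smaller linear index.
#'
#' @seealso [segment()], [segmentLength()], [gapBetween()]
#' @export
setClass("Segment",
  representation(originName = "character", hi = "integer", lo = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@hi) != 1L || length(object@lo) != 1L)
      msg <- c(msg, "hi and lo must be single coordinates")
    if (any(c(object@hi, object@lo) == 0L))
      msg <- c(msg, "origin-relative coordinates have no position zero")
    if (coordIndex(object@hi) < coordIndex(object@lo))
      msg <- c(msg, "hi must not lie at a smaller linear index than lo")
    if (length(msg)) msg else TRUE
  }
)

#' Sequence edit specification
#'
#' Describes one of the three mutation types used to dissect origin-adjacent
#' sequence: linker substitution (fixed-length replacement, total length
#' preserved), insertion, or deletion.
#'
#' @slot kind one of \code{"linker_substitution"}, \code{"insertion"},
#'   \code{"deletion"}.
#' @slot payload DNA string (linker or insert) for substitutions and
#'   insertions; for deletions the empty string (the length lives in
#'   \code{deletionLength}).
#' @slot deletionLength integer number of nucleotides removed (deletions
#'   only; 0 otherwise).
#' @slot at integer 1-based position in the target sequence: first
#'   substituted base, the base after which an insert is placed (0 to
#'   prepend), or the first deleted base. \code{NA} when the edit is used
#'   only for spacing arithmetic.
#'
#' @seealso [mutationSpec()], [applyEdit()], [editedSpacing()]
#' @export
setClass("MutationSpec",
  representation(kind = "character", payload = "character",
                 deletionLength = "integer", at = "integer"),
  validity = function(object) {
    msg <- character()
    kinds <- c("linker_substitution", "insertion", "deletion")
    if (length(object@kind) != 1L || !object@kind %in% kinds)
      msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@kind %in% c("linker_substitution", "insertion")) {
      if (!nzchar(object@payload))
        msg <- c(msg, "substitution/insertion requires a nonempty DNA payload")
      if (grepl("[^ACGT]", object@payload))
        msg <- c(msg, "payload must contain only A, C, G, T")
    } else if (object@deletionLength < 0L) {
      msg <- c(msg, "deletion length must be >= 0")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Probe-level two-channel aCGH intensities
#'
#' The raw observable of a two-channel array CGH experiment: one row per
#' probe with chromosome, 1-based position, and strictly positive Cy3
#' (reference) and Cy5 (experimental) intensities. Probes falling in
#' repetitive regions may be flagged \code{masked} so that all downstream
#' statistics exclude them.
#'
#' @slot probes data.frame with columns \code{chrom}, \code{pos},
#'   \code{cy3}, \code{cy5}, \code{masked}.
#'
#' @seealso [probeTable()], [readProbeTable()], [simulateProbeTable()]
#' @export
setClass("ProbeTable",
  representation(probes = "data.frame"),
  validity = function(object) {
    p <- object@probes
    need <- c("chrom", "pos", "cy3", "cy5", "masked")
    if (!all(need %in% names(p)))
      return(paste("probes must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(p)) {
      if (!all(is.finite(p$cy3)) || !all(is.finite(p$cy5)) ||
          any(p$cy3 <= 0) || any(p$cy5 <= 0))
        msg <- c(msg, "intensities must be finite and strictly positive")
      if (anyDuplicated(p[, c("chrom", "pos")]))
        msg <- c(msg, "duplicated (chrom, pos) probe")
      ord <- order(p$chrom, p$pos)
      if (!identical(ord, seq_len(nrow(p))))
        msg <- c(msg, "probes must be sorted by chromosome then position")
      if (!is.logical(p$masked))
        msg <- c(msg, "masked must be logical")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Normalized per-probe DNA-content track
#'
#' Per-probe Cy5/Cy3 ratios for a single chromosome, expressed in absolute
#' DNA-content units (C) after normalization. Masked probes carry a flag
#' and are excluded from every statistic; their values may be \code{NA}
#' after filtering. The chromosome is treated as circular for the moving
#' median and Fourier smoothing, so the track carries its length.
#'
#' @slot chrom character chromosome name.
#' @slot positions numeric, strictly increasing 1-based bp.
#' @slot values numeric DNA content per probe (C units).
#' @slot mask logical per probe; \code{TRUE} = excluded.
#' @slot chromLength numeric chromosome length in bp.
#'
#' @seealso [ratioTrackFromProbes()], [normalizeTrack()], [movingMedian()]
#' @export
setClass("RatioTrack",
  representation(chrom = "character", positions = "numeric",
                 values = "numeric", mask = "logical", chromLength = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@positions)
    if (length(object@values) != n || length(object@mask) != n)
      msg <- c(msg, "positions, values and mask must have equal length")
    if (n && any(diff(object@positions) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    ok <- !object@mask
    if (n && any(!is.finite(object@values[ok]) | object@values[ok] <= 0))
      msg <- c(msg, "unmasked values must be finite and > 0")
    if (length(object@chromLength) != 1L || object@chromLength <= 0)
      msg <- c(msg, "chromLength must be a single positive number")
    if (n && object@positions[n] > object@chromLength)
      msg <- c(msg, "positions exceed chromLength")
    if (length(msg)) msg else TRUE
  }
)

#' Smoothed DNA-content profile on a uniform grid
#'
#' One chromosome's DNA-content curve after moving-median filtering and
#' Fourier convolution smoothing, resampled to uniform bins. Bin i covers
#' [(i-1)*binSize, i*binSize) in 0-based bp; values are C units. Bins with
#' no unmasked probes are \code{NA}.
#'
#' @slot chrom character chromosome name.
#' @slot binSize numeric bin width in bp.
#' @slot values numeric smoothed DNA content per bin.
#' @slot kernel numeric the convolution-kernel parameter used (kb).
#' @slot chromLength numeric chromosome length in bp.
#'
#' @seealso [fcsSmooth()], [compositeProfile()]
#' @export
setClass("SmoothProfile",
  representation(chrom = "character", binSize = "numeric", values = "numeric",
                 kernel = "numeric", chromLength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@binSize <= 0) msg <- c(msg, "binSize must be > 0")
    if (object@kernel <= 0) msg <- c(msg, "kernel must be > 0")
    nbins <- ceiling(object@chromLength / object@binSize)
    if (length(object@values) != nbins)
      msg <- c(msg, sprintf("expected %d bins, got %d", nbins,
                            length(object@values)))
    if (length(msg)) msg else TRUE
  }
)

#' Composite (replicate-averaged) profile
#'
#' Per-bin mean and sample standard deviation across replicate smoothed
#' profiles, the form in which re-replication profiles are displayed and
#' quantified (mean trace with a +/- 1 SD envelope).
#'
#' @slot chrom character chromosome name.
#' @slot binSize numeric bin width in bp.
#' @slot mean numeric per-bin mean DNA content (C units).
#' @slot sd numeric per-bin sample SD (0 when n = 1).
#' @slot n integer replicate count.
#' @slot chromLength numeric chromosome length in bp.
#'
#' @seealso [compositeProfile()], [peakHeight()], [maskChromosomeEnd()]
#' @export
setClass("CompositeProfile",
  representation(chrom = "character", binSize = "numeric", mean = "numeric",
                 sd = "numeric", n = "integer", chromLength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mean) != length(object@sd))
      msg <- c(msg, "mean and sd must have equal length")
    if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic genome specification
#'
#' Chromosome sizes, masked repetitive intervals and replication origins for
#' the re-replication simulator. Each origin carries a re-initiation
#' efficiency (the fraction of cells that re-initiate it during induction)
#' and, optionally, an S-phase firing time and efficiency.
#'
#' @slot chromosomes named numeric vector of chromosome lengths (bp).
#' @slot origins data.frame with columns \code{chrom}, \code{position},
#'   \code{efficiency} and optional \code{sphaseTime}, \code{sphaseEff}.
#' @slot masked GRanges of masked intervals (1-based, inclusive).
#'
#' @seealso [genomeSpec()], [expectedRerepProfile()]
#' @export
setClass("GenomeSpec",
  representation(chromosomes = "numeric", origins = "data.frame",
                 masked = "GRanges"),
  validity = function(object) {
    msg <- character()
    chr <- object@chromosomes
    if (!length(chr) || is.null(names(chr)) || any(!nzchar(names(chr))))
      msg <- c(msg, "chromosomes must be a named vector of lengths")
    if (any(chr <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
    o <- object@origins
    if (nrow(o)) {
      if (!all(c("chrom", "position", "efficiency") %in% names(o)))
        msg <- c(msg, "origins need columns chrom, position, efficiency")
      else {
        if (!all(o$chrom %in% names(chr)))
          msg <- c(msg, "origin chromosome not in genome")
        else if (any(o$position < 1 | o$position > chr[o$chrom]))
          msg <- c(msg, "origin position outside chromosome")
        if (any(o$efficiency < 0 | o$efficiency > 1))
          msg <- c(msg, "re-initiation efficiency must be in [0, 1]")
      }
    }
    if (length(object@masked)) {
      m <- object@masked
      bad <- !as.character(seqnames(m)) %in% names(chr)
      if (any(bad)) msg <- c(msg, "masked interval on unknown chromosome")
      else if (any(GenomicRanges::end(m) >
                   chr[as.character(seqnames(m))]))
        msg <- c(msg, "masked interval beyond chromosome end")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Simulation configuration
#'
#' Generative parameters for synthetic re-replication aCGH samples: fork
#' speed and induction time (which set the width of the triangular
#' re-replication peaks), probe spacing, per-channel multiplicative
#' log-normal noise, replicate count, channel gains, the target DNA content
#' of the arrest (2C for M phase, 1.5C for mid-S), an optional
#' re-initiation rounds multiplier, and the master seed.
#'
#' @slot forkSpeed numeric replication fork speed, bp/min.
#' @slot inductionMinutes numeric induction duration, min.
#' @slot probeSpacing numeric distance between probes, bp.
#' @slot noiseSigma numeric SD of per-channel log-intensity noise.
#' @slot nReplicates integer replicate samples to simulate.
#' @slot seed integer master seed; every random draw derives from it.
#' @slot targetContent numeric DNA content the genome-wide mean represents.
#' @slot gainCy3,gainCy5 numeric arbitrary positive channel gains.
#' @slot rounds numeric multiplier for repeated re-initiation (1 = single
#'   round; >1 approximates multi-round onion-skin amplification).
#'
#' @seealso [simConfig()], [simulateProbeTable()]
#' @export
setClass("SimConfig",
  representation(forkSpeed = "numeric", inductionMinutes = "numeric",
                 probeSpacing = "numeric", noiseSigma = "numeric",
                 nReplicates = "integer", seed = "integer",
                 targetContent = "numeric", gainCy3 = "numeric",
                 gainCy5 = "numeric", rounds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@forkSpeed <= 0) msg <- c(msg, "forkSpeed must be > 0")
    if (object@inductionMinutes < 0) msg <- c(msg, "inductionMinutes must be >= 0")
    if (object@probeSpacing < 1) msg <- c(msg, "probeSpacing must be >= 1 bp")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@gainCy3 <= 0 || object@gainCy5 <= 0)
      msg <- c(msg, "channel gains must be > 0")
    if (object@rounds <= 0) msg <- c(msg, "rounds must be > 0")
    if (length(msg)) msg else TRUE
  }
)
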