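#' Per-probe ratio track from a probe table
#'
#' Extracts one chromosome's probes and forms raw Cy5/Cy3 ratios, carrying
#' the probe mask along. The chromosome length defaults to the last probe
#' position plus half the median probe spacing, so that an evenly spaced
#' grid closes cleanly when the chromosome is circularized for filtering.
#'
#' @param pt a [ProbeTable-class].
#' @param chrom chromosome to extract.
#' @param chromLen chromosome length in bp (optional; see above).
#' @return A [RatioTrack-class] of raw (unnormalized) ratios.
#' @export
ratioTrackFromProbes <- function(pt, chrom, chromLen = NULL) {
  stopifnot(is(pt, "ProbeTable"))
  p <- pt@probes[pt@probes$chrom == chrom, , drop = FALSE]
  if (!nrow(p)) stop("no probes on chromosome ", chrom)
  if (is.null(chromLen)) {
    spacing <- if (nrow(p) > 1L) stats::median(diff(p$pos)) else p$pos[1]
    chromLen <- p$pos[nrow(p)] + spacing / 2
  }
  new("RatioTrack", chrom = chrom, positions = as.numeric(p$pos),
      values = p$cy5 / p$cy3, mask = p$masked, chromLength = chromLen)
}

#' Normalize a ratio track to absolute DNA content
#'
#' Rescales raw Cy5/Cy3 ratios so that the mean over unmasked probes
#' equals the DNA content expected for the cell-cycle point sampled: 2C
#' for M-arrested or induced samples, 1.5C for mid-S samples. This is the
#' step that converts relative hybridization ratios into C units.
#'
#' @param track a [RatioTrack-class].
#' @param targetContent DNA content assigned to the genome-wide mean.
#' @return A [RatioTrack-class] in C units; the unmasked mean equals
#'   \code{targetContent} exactly.
#' @export
normalizeTrack <- function(track, targetContent = 2) {
  stopifnot(is(track, "RatioTrack"), targetContent > 0)
  ok <- !track@mask & is.finite(track@values)
  if (!any(ok)) stop("all probes masked: nothing to normalize")
  scale <- targetContent / mean(track@values[ok])
  initialize(track, values = track@values * scale)
}

#' Flag probes inside masked intervals
#'
#' Marks probes whose position falls in any of the given intervals
#' (repetitive elements, rDNA, subtelomeric repeats...) as masked, so that
#' every downstream statistic excludes them. Intervals are 1-based
#' inclusive \code{GRanges}; see [readBedMask()] for BED input.
#'
#' @param track a [RatioTrack-class].
#' @param intervals \code{GRanges} of masked regions.
#' @return The track with the union of old and new masks.
#' @export
applyMasks <- function(track, intervals) {
  stopifnot(is(track, "RatioTrack"))
  if (!length(intervals)) return(track)
  hit <- maskFlags(rep(track@chrom, length(track@positions)),
                   track@positions, intervals)
  initialize(track, mask = track@mask | hit)
}

#' Circular moving-window median
#'
#' Robust local summary of probe ratios: the value at each unmasked probe
#' becomes the median of all unmasked values whose positions lie within
#' +/- \code{windowBp/2} (inclusive bounds). The chromosome is treated as
#' circular, so windows wrap across the ends; masked probes get \code{NA}.
#' Even window counts take the mean of the two middle values.
#'
#' @param track a [RatioTrack-class].
#' @param windowBp full window width in bp (default 10 kb).
#' @return A filtered [RatioTrack-class] on the same positions.
#' @export
movingMedian <- function(track, windowBp = 10000) {
  stopifnot(is(track, "RatioTrack"), windowBp > 0)
  L <- track@chromLength
  if (windowBp >= L)
    stop("window must be smaller than the (circularized) chromosome")
  ok <- which(!track@mask & is.finite(track@values))
  if (!length(ok)) stop("all probes masked: nothing to filter")
  posU <- track@positions[ok]
  valU <- track@values[ok]
  extPos <- c(posU - L, posU, posU + L)
  extVal <- rep(valU, 3L)
  h <- windowBp / 2
  # inclusive [c-h, c+h]; positions are bp so a half-unit guard is exact
  lo <- findInterval(track@positions - h - 0.5, extPos) + 1L
  hi <- findInterval(track@positions + h + 0.5, extPos)
  out <- rep(NA_real_, length(track@positions))
  for (j in seq_along(out)) {
    if (track@mask[j]) next
    if (hi[j] < lo[j]) next  # empty window: value undefined
    out[j] <- stats::median(extVal[lo[j]:hi[j]])
  }
  initialize(track, values = out)
}

# Per-chromosome convolution-kernel defaults (kb) tuned for re-replication
# profiles; S phase uses a tighter kernel on chromosome IV.
kernelDefaults <- c(chrIII = 9, chrIV = 11.25, chrV = 9, chrXII = 10.75)
kernelDefaultsSphase <- c(chrIV = 6.25)

#' Default convolution kernel for a chromosome
#'
#' Returns the per-chromosome smoothing kernel (kb) used for display-grade
#' re-replication profiles (III 9, IV 11.25, V 9, XII 10.75; 10 for any
#' other chromosome) or the S-phase value (IV 6.25).
#'
#' @param chrom chromosome name.
#' @param phase \code{"rerep"} or \code{"sphase"}.
#' @return Kernel parameter in kb.
#' @export
defaultKernel <- function(chrom, phase = c("rerep", "sphase")) {
  phase <- match.arg(phase)
  tab <- if (phase == "sphase")
    c(kernelDefaultsSphase, kernelDefaults[setdiff(names(kernelDefaults),
                                                   names(kernelDefaultsSphase))])
  else kernelDefaults
  if (chrom %in% names(tab)) unname(tab[chrom]) else 10
}

#' Fourier convolution smoothing
#'
#' Smooths a (median-filtered) track by circular Gaussian convolution in
#' Fourier space. The track is resampled to a uniform grid of
#' \code{binSizeBp} bins (bin value = mean of its unmasked probes; empty
#' bins filled by circular linear interpolation), the grid is treated as
#' circular, and the values are convolved with a unit-sum Gaussian kernel
#' of standard deviation \code{kernel} kb via forward/inverse FFT. The
#' operation is linear, preserves constants and preserves the grid mean;
#' larger kernels give smoother curves. Bins that contained no unmasked
#' probes are re-masked (\code{NA}) in the output.
#'
#' @param track a [RatioTrack-class].
#' @param kernel Gaussian SD in kb; see [defaultKernel()].
#' @param binSizeBp grid bin width in bp (default 1 kb).
#' @return A [SmoothProfile-class].
#' @export
fcsSmooth <- function(track, kernel = defaultKernel(chromName(track)),
                      binSizeBp = 1000) {
  stopifnot(is(track, "RatioTrack"))
  if (!is.numeric(kernel) || length(kernel) != 1L || kernel <= 0)
    stop("kernel must be a single positive number (kb)")
  nbins <- as.integer(ceiling(track@chromLength / binSizeBp))
  if (nbins < 2L) stop("chromosome shorter than two bins")
  ok <- !track@mask & is.finite(track@values)
  if (!any(ok)) stop("all probes masked: nothing to smooth")
  bin <- pmin(nbins, floor((track@positions - 1) / binSizeBp) + 1L)
  sums <- tapply(track@values[ok], factor(bin[ok], levels = seq_len(nbins)),
                 mean)
  grid <- as.numeric(sums)
  empty <- is.na(grid)
  if (all(empty)) stop("no bins contain unmasked probes")
  if (any(empty)) {
    # circular linear interpolation across empty bins
    idx <- which(!empty)
    filled <- stats::approx(x = c(idx - nbins, idx, idx + nbins),
                            y = rep(grid[idx], 3L),
                            xout = seq_len(nbins))$y
    grid[empty] <- filled[empty]
  }
  sigmaBins <- kernel * 1000 / binSizeBp
  d <- pmin(seq_len(nbins) - 1L, nbins - (seq_len(nbins) - 1L))
  w <- exp(-0.5 * (d / sigmaBins)^2)
  w <- w / sum(w)
  sm <- Re(stats::fft(stats::fft(grid) * stats::fft(w), inverse = TRUE)) / nbins
  sm[empty] <- NA_real_
  new("SmoothProfile", chrom = track@chrom, binSize = binSizeBp,
      values = sm, kernel = kernel, chromLength = track@chromLength)
}

#' Composite profile across replicates
#'
#' Averages replicate smoothed profiles bin-by-bin into the composite form
#' in which re-replication profiles are displayed and quantified: a mean
#' trace with a +/- 1 sample SD envelope (n - 1 denominator; SD 0 when
#' n = 1). Bins masked in some replicates use the remaining ones; bins
#' masked everywhere stay \code{NA}.
#'
#' @param profiles list of [SmoothProfile-class] objects on identical
#'   grids (same chromosome, bin size and bin count).
#' @return A [CompositeProfile-class].
#' @export
compositeProfile <- function(profiles) {
  if (is(profiles, "SmoothProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "SmoothProfile")))
  ref <- profiles[[1L]]
  same <- vapply(profiles, function(p) {
    p@chrom == ref@chrom && p@binSize == ref@binSize &&
      length(p@values) == length(ref@values)
  }, logical(1))
  if (!all(same)) stop("profiles are not on identical grids")
  mat <- do.call(cbind, lapply(profiles, profileValues))
  n <- ncol(mat)
  m <- rowMeans(mat, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  if (n == 1L) {
    s <- ifelse(is.na(m), NA_real_, 0)
  } else {
    s <- apply(mat, 1L, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_real_ else if (length(r) == 1L) 0 else stats::sd(r)
    })
  }
  new("CompositeProfile", chrom = ref@chrom, binSize = ref@binSize,
      mean = m, sd = s, n = as.integer(n), chromLength = ref@chromLength)
}

#' Mask the left end of a composite profile
#'
#' Circularization makes a strong peak at one chromosome end artifactually
#' raise the smoothed curve at the other end; the standard remedy is to
#' blank the affected terminal window for display (e.g. the left 20 kb of
#' chromosome III when its right-arm origin re-initiates strongly).
#' Display masking only: quantification windows that avoid the masked bins
#' are unaffected.
#'
#' @param profile a [CompositeProfile-class].
#' @param leftBp bp to blank from the left end (0 = no-op).
#' @return The profile with bins starting before \code{leftBp} set to
#'   \code{NA}.
#' @export
maskChromosomeEnd <- function(profile, leftBp) {
  stopifnot(is(profile, "CompositeProfile"), leftBp >= 0)
  if (leftBp == 0) return(profile)
  drop <- binStarts(profile) < leftBp
  initialize(profile,
             mean = replace(profile@mean, drop, NA_real_),
             sd = replace(profile@sd, drop, NA_real_))
}

#' End-to-end profile pipeline for one chromosome
#'
#' Runs the standard analysis chain on each replicate probe table --
#' ratios, repeat masking, normalization to \code{targetContent}, 10 kb
#' circular moving median, Fourier convolution smoothing -- and averages
#' the replicates into a composite profile.
#'
#' @param probeTables list of [ProbeTable-class] replicates.
#' @param chrom chromosome to profile.
#' @param chromLen chromosome length in bp (optional).
#' @param masks \code{GRanges} of masked intervals (optional).
#' @param targetContent normalization target (2C M arrest, 1.5C mid-S).
#' @param windowBp moving-median window (default 10 kb).
#' @param kernel smoothing kernel in kb (default [defaultKernel()]).
#' @param binSizeBp smoothing grid bin (default 1 kb).
#' @return A [CompositeProfile-class].
#' @export
profilePipeline <- function(probeTables, chrom, chromLen = NULL,
                            masks = GenomicRanges::GRanges(),
                            targetContent = 2, windowBp = 10000,
                            kernel = defaultKernel(chrom), binSizeBp = 1000) {
  if (is(probeTables, "ProbeTable")) probeTables <- list(probeTables)
  smooths <- lapply(probeTables, function(pt) {
    ratioTrackFromProbes(pt, chrom, chromLen) |>
      applyMasks(masks) |>
      normalizeTrack(targetContent) |>
      movingMedian(windowBp) |>
      fcsSmooth(kernel, binSizeBp)
  })
  compositeProfile(smooths)
}
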