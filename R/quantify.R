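#' Peak height above baseline at a locus
#'
#' Measures re-initiation at a known locus as the maximum of the composite
#' mean within a search window, relative to the expected copy number of
#' the arrest (2C for G2/M). The window maximum, rather than the value at
#' the nominal coordinate, is used because smoothing can shift the apex by
#' a few bins. Heights may be negative for flat, noisy profiles.
#'
#' @param profile a [CompositeProfile-class].
#' @param locusPos 1-based bp position of the locus.
#' @param searchHalfwidth half-width of the search window in bp
#'   (default 10 kb).
#' @param baseline expected background copy number (default 2C).
#' @return A list of class \code{"PeakMeasurement"} with elements
#'   \code{chrom}, \code{locus}, \code{searchHalfwidth}, \code{baseline},
#'   \code{height} (C units above baseline) and \code{peakPosition}
#'   (bp of the leftmost maximum).
#' @export
peakHeight <- function(profile, locusPos, searchHalfwidth = 10000,
                       baseline = 2) {
  stopifnot(is(profile, "CompositeProfile"),
            locusPos >= 1, locusPos <= profile@chromLength,
            searchHalfwidth >= 0)
  centers <- binCenters(profile)
  inWin <- abs(centers - locusPos) <= searchHalfwidth
  vals <- profile@mean[inWin]
  if (!length(vals) || all(is.na(vals)))
    stop("no unmasked bins within the search window")
  k <- which.max(vals)  # leftmost maximum on ties
  structure(
    list(chrom = profile@chrom, locus = locusPos,
         searchHalfwidth = searchHalfwidth, baseline = baseline,
         height = vals[k] - baseline,
         peakPosition = centers[inWin][k]),
    class = "PeakMeasurement")
}

#' @export
print.PeakMeasurement <- function(x, ...) {
  cat(sprintf(
    "Peak at %s:%.0f (searched +/- %.0f bp): %.4g C above %.2gC baseline (apex %.0f)\n",
    x$chrom, x$locus, x$searchHalfwidth, x$height, x$baseline,
    x$peakPosition))
  invisible(x)
}

#' Re-initiation efficiency with propagated error
#'
#' Normalizes the mean peak height of an experimental construct against
#' the mean peak height of a reference (full-length) construct, expressed
#' as a percentage. Replicate heights are averaged within each group
#' (\eqn{\bar x_{exp}}, \eqn{\bar x_{cont}}) with sample SDs; the SD of
#' the percentage uses first-order error propagation for a ratio of
#' independent means:
#' \deqn{s_\% = \% \sqrt{(s_{exp}/\bar x_{exp})^2 +
#'   (s_{cont}/\bar x_{cont})^2}}
#'
#' @param expHeights numeric peak heights (C units) of the experimental
#'   construct's replicates.
#' @param contHeights numeric peak heights of the reference construct.
#' @return A list of class \code{"EfficiencyEstimate"}: \code{percent},
#'   \code{sdPercent}, group means/SDs (\code{xExp}, \code{sExp},
#'   \code{xCont}, \code{sCont}) and counts (\code{nExp}, \code{nCont}).
#' @examples
#' reinitEfficiency(c(0.5, 0.55), c(1.0, 1.1))
#' @export
reinitEfficiency <- function(expHeights, contHeights) {
  stopifnot(length(expHeights) >= 1L, length(contHeights) >= 1L)
  xE <- mean(expHeights); xC <- mean(contHeights)
  sE <- if (length(expHeights) > 1L) stats::sd(expHeights) else 0
  sC <- if (length(contHeights) > 1L) stats::sd(contHeights) else 0
  if (xC <= 0)
    stop("reference mean height must be > 0 to define an efficiency")
  pct <- 100 * xE / xC
  relE <- if (xE == 0 && sE == 0) 0 else sE / xE
  relC <- sC / xC
  structure(
    list(percent = pct, sdPercent = abs(pct) * sqrt(relE^2 + relC^2),
         xExp = xE, sExp = sE, xCont = xC, sCont = sC,
         nExp = length(expHeights), nCont = length(contHeights)),
    class = "EfficiencyEstimate")
}

#' @export
print.EfficiencyEstimate <- function(x, ...) {
  cat(sprintf(
    "Re-initiation efficiency: %.3g%% +/- %.3g%% (exp n = %d, ref n = %d)\n",
    x$percent, x$sdPercent, x$nExp, x$nCont))
  invisible(x)
}

#' Welch's t-test between experimental and control heights
#'
#' Two-sample t-test with unequal variances (Welch-Satterthwaite degrees
#' of freedom), the comparison used to decide whether a strain's profile
#' height differs from the non-re-replicating negative-control baseline.
#' Significance is read at p < 0.05 per comparison, with no
#' multiple-testing correction.
#'
#' @param expValues numeric, experimental group (n >= 2).
#' @param contValues numeric, control group (n >= 2).
#' @return A list of class \code{"WelchResult"}: \code{t}, \code{df}
#'   (real-valued), \code{p} (two-sided).
#' @examples
#' welchTest(c(1, 2, 3), c(4, 5, 6))
#' @export
welchTest <- function(expValues, contValues) {
  if (length(expValues) < 2L || length(contValues) < 2L)
    stop("Welch's test needs at least 2 values per group")
  if (stats::var(expValues) == 0 && stats::var(contValues) == 0) {
    if (mean(expValues) == mean(contValues))
      return(structure(list(t = 0, df = length(expValues) +
                              length(contValues) - 2, p = 1),
                       class = "WelchResult"))
    stop("both groups have zero variance: t statistic undefined")
  }
  ht <- stats::t.test(expValues, contValues, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "WelchResult")
}

#' @export
print.WelchResult <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.3g, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Convert peak DNA content to percent of cells re-initiated
#'
#' Under the model that each re-initiating cell fires the origin once on
#' each sister chromatid, a cell that re-initiates gains 2 extra copies at
#' the peak, so a population peak content C corresponds to
#' \eqn{100 (C - 2) / 2} percent of cells having re-initiated: a 3.0C peak
#' means 50\% of cells, 2.5C means 25\%. The alternative single-extra-copy
#' model (\eqn{100 (C - 2)}) is selectable. Contents below the 2C baseline
#' clip to 0\%.
#'
#' @param peakContent numeric composite peak DNA content in C units.
#' @param model \code{"per_sister"} (2 extra copies per cell, default) or
#'   \code{"per_cell"} (1 extra copy).
#' @return Percent of cells, vectorized over \code{peakContent}.
#' @examples
#' fractionReinitiated(3.0)   # 50
#' fractionReinitiated(2.5)   # 25
#' @export
fractionReinitiated <- function(peakContent, model = c("per_sister",
                                                       "per_cell")) {
  model <- match.arg(model)
  stopifnot(is.numeric(peakContent))
  extra <- pmax(0, peakContent - 2)
  if (model == "per_sister") 100 * extra / 2 else 100 * extra
}

#' Per-locus peak table for a set of strains
#'
#' Convenience wrapper measuring [peakHeight()] for several composite
#' profiles at one locus, returning the tidy table used for bar graphs.
#'
#' @param profiles named list of [CompositeProfile-class] objects
#'   (names = strain/construct labels).
#' @param locusPos locus position in bp.
#' @param searchHalfwidth search half-width in bp.
#' @param baseline baseline copy number.
#' @return data.frame with columns \code{strain}, \code{chrom},
#'   \code{pos}, \code{height}, \code{baseline}, \code{peakPosition}.
#' @export
peakTable <- function(profiles, locusPos, searchHalfwidth = 10000,
                      baseline = 2) {
  stopifnot(length(profiles) >= 1L)
  labels <- names(profiles)
  if (is.null(labels)) labels <- paste0("strain", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    pk <- peakHeight(profiles[[i]], locusPos, searchHalfwidth, baseline)
    data.frame(strain = labels[i], chrom = pk$chrom, pos = pk$locus,
               height = pk$height, baseline = pk$baseline,
               peakPosition = pk$peakPosition)
  })
  do.call(rbind, rows)
}
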