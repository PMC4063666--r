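# Profile pipeline: normalization, masking, circular moving median,
# Fourier convolution smoothing, composites, end masking.

test_that("normalization pins the unmasked mean to the target content", {
  tr <- new("RatioTrack", chrom = "chrS", positions = c(1000, 2000),
            values = c(1, 1), mask = c(FALSE, FALSE), chromLength = 3000)
  expect_equal(trackValues(normalizeTrack(tr, 2)), c(2, 2))
  tr2 <- initialize(tr, values = c(1, 3))  # mean already 2
  expect_equal(trackValues(normalizeTrack(tr2, 2)), c(1, 3))
  set.seed(21)
  n <- 500
  tr3 <- new("RatioTrack", chrom = "chrS",
             positions = seq(1000, by = 1000, length.out = n),
             values = exp(rnorm(n, sd = 0.3)), mask = rep(FALSE, n),
             chromLength = (n + 1) * 1000)
  for (target in c(1.5, 2)) {
    out <- normalizeTrack(tr3, target)
    expect_equal(mean(trackValues(out)), target, tolerance = 1e-9)
  }
  # masked probes are excluded from the centering
  tr4 <- initialize(tr3, mask = c(rep(TRUE, 100), rep(FALSE, n - 100)))
  out4 <- normalizeTrack(tr4, 2)
  expect_equal(mean(trackValues(out4)[!trackMask(out4)]), 2,
               tolerance = 1e-9)
  expect_error(normalizeTrack(initialize(tr, mask = c(TRUE, TRUE))),
               "masked")
})

test_that("interval masking drops exactly the covered probes", {
  gs <- makeRerepGenome(chromLen = 5e5)
  pt <- simulateProbeTable(gs, simConfig(noiseSigma = 0), 1L)
  tr <- ratioTrackFromProbes(pt, "chrS", 5e5)
  expect_identical(trackMask(applyMasks(tr, GenomicRanges::GRanges())),
                   trackMask(tr))
  rdna <- GenomicRanges::GRanges("chrS", IRanges::IRanges(200001, 244000))
  masked <- applyMasks(tr, rdna)
  expect_identical(sum(trackMask(masked)) - sum(trackMask(tr)), 44L)
  everything <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 5e5))
  expect_error(normalizeTrack(applyMasks(tr, everything)), "masked")
})

test_that("moving median matches brute-force recomputation on random tracks", {
  set.seed(31)
  n <- 1e4
  chromLen <- (n + 1) * 50
  positions <- sort(sample.int(chromLen - 1, n))
  values <- exp(rnorm(n, sd = 0.4))
  mask <- runif(n) < 0.05
  tr <- new("RatioTrack", chrom = "chrS", positions = as.numeric(positions),
            values = values, mask = mask, chromLength = chromLen)
  out <- movingMedian(tr, windowBp = 2000)
  oracle <- bruteMovingMedian(positions, values, mask, chromLen, 2000)
  expect_equal(trackValues(out), oracle, tolerance = 1e-12)
  expect_true(all(is.na(trackValues(out)[mask])))
})

test_that("moving median is robust and keeps constants", {
  tr <- new("RatioTrack", chrom = "chrS",
            positions = c(1000, 2000, 3000),
            values = c(1, 2, 100), mask = rep(FALSE, 3),
            chromLength = 1e5)
  out <- movingMedian(tr, windowBp = 10000)  # one window holds all three
  expect_equal(trackValues(out), rep(2, 3))
  const <- new("RatioTrack", chrom = "chrS",
               positions = seq(1000, 5e4, by = 1000),
               values = rep(1.7, 50), mask = rep(FALSE, 50),
               chromLength = 5.05e4)
  expect_equal(trackValues(movingMedian(const)), rep(1.7, 50))
})

test_that("FCS equals direct circular convolution and is linear and mean-preserving", {
  nbins <- 512
  chromLen <- nbins * 1000
  mkTrack <- function(vals) new("RatioTrack", chrom = "chrS",
                                positions = seq(500, chromLen, by = 1000),
                                values = vals, mask = rep(FALSE, nbins),
                                chromLength = chromLen)
  # impulse on a positive pedestal (track values must be positive)
  vals <- rep(1, nbins); vals[100] <- 11
  kernel <- 4
  sm <- profileValues(fcsSmooth(mkTrack(vals), kernel = kernel))
  # oracle: direct O(n^2) circular convolution with the same Gaussian
  d <- pmin(0:(nbins - 1), nbins - (0:(nbins - 1)))
  w <- exp(-0.5 * (d / kernel)^2); w <- w / sum(w)
  direct <- sapply(seq_len(nbins), function(i)
    sum(vals[((i - 1 - (0:(nbins - 1))) %% nbins) + 1] * w))
  expect_lt(max(abs(sm - direct)), 1e-9)
  # the impulse mass (sum above pedestal) is conserved
  expect_equal(sum(sm - 1), 10, tolerance = 1e-9)
  expect_equal(mean(sm), mean(vals), tolerance = 1e-12)
  # constants pass through untouched
  expect_equal(profileValues(fcsSmooth(mkTrack(rep(2.4, nbins)), 9)),
               rep(2.4, nbins), tolerance = 1e-12)
  # linearity: smooth(a + b) = smooth(a) + smooth(b)
  set.seed(41)
  a <- exp(rnorm(nbins, sd = 0.2)); b <- exp(rnorm(nbins, sd = 0.2))
  sAB <- profileValues(fcsSmooth(mkTrack(a + b), 7))
  sA <- profileValues(fcsSmooth(mkTrack(a), 7))
  sB <- profileValues(fcsSmooth(mkTrack(b), 7))
  expect_equal(sAB, sA + sB, tolerance = 1e-10)
  expect_error(fcsSmooth(mkTrack(vals), kernel = -1), "kernel")
})

test_that("pipeline preserves the genome-wide mean near the target content", {
  gs <- makeRerepGenome(efficiency = 0.5)
  cfg <- simConfig(noiseSigma = 0.05, seed = 2L)
  cp <- runPipeline(gs, cfg)
  gridMean <- mean(profileMean(cp), na.rm = TRUE)
  # the moving median re-centers log-normal ratios at their median,
  # a factor exp(-sigma^2) below the mean-normalized target
  expect_lt(abs(gridMean - 2) / 2, 0.005)
})

test_that("composite averages replicates with sample SD", {
  gs <- makeRerepGenome(chromLen = 2e5)
  cfg <- simConfig(noiseSigma = 0.1, seed = 5L, nReplicates = 4L)
  smooths <- lapply(1:4, function(r) {
    pt <- simulateProbeTable(gs, cfg, r)
    tr <- normalizeTrack(ratioTrackFromProbes(pt, "chrS", 2e5))
    fcsSmooth(movingMedian(tr), kernel = 5)
  })
  cp <- compositeProfile(smooths)
  mat <- sapply(smooths, profileValues)
  expect_equal(profileMean(cp), rowMeans(mat), tolerance = 1e-12)
  expect_equal(profileSD(cp), apply(mat, 1, sd), tolerance = 1e-12)
  expect_identical(nReplicates(cp), 4L)
  # identical replicates: sd exactly zero; single replicate: sd zero
  cpSame <- compositeProfile(list(smooths[[1]], smooths[[1]]))
  expect_true(all(profileSD(cpSame) == 0))
  cp1 <- compositeProfile(smooths[[1]])
  expect_true(all(profileSD(cp1) == 0))
  expect_equal(profileMean(cp1), profileValues(smooths[[1]]))
  # two-point check
  expect_equal(sd(c(2, 3)), 0.7071068, tolerance = 1e-6)
  short <- initialize(smooths[[2]], values = smooths[[2]]@values[1:10],
                      chromLength = 1e4)
  expect_error(compositeProfile(list(smooths[[1]], short)), "grids")
})

test_that("circularization bleeds a terminal peak to the opposite end", {
  # strong origin near the right end: the smoothed curve rises at the
  # left end through the circular wrap (the documented edge artifact)
  gs <- makeRerepGenome(chromLen = 3e5, originPos = 2.95e5, efficiency = 1)
  cfg <- simConfig(noiseSigma = 0, seed = 1L, nReplicates = 1L)
  cp <- runPipeline(gs, cfg, kernel = 10)
  m <- profileMean(cp)
  leftEnd <- mean(m[1:5])
  middle <- mean(m[140:160])
  expect_gt(leftEnd, middle + 0.05)
  # masking the left 20 kb blanks those bins without touching the rest
  masked <- maskChromosomeEnd(cp, 20000)
  expect_true(all(is.na(profileMean(masked)[binStarts(masked) < 20000])))
  keep <- binStarts(masked) >= 20000
  expect_equal(profileMean(masked)[keep], m[keep])
  expect_identical(profileMean(maskChromosomeEnd(cp, 0)), m)
  # quantification away from the masked end is unchanged
  pkA <- peakHeight(cp, 2.95e5)
  pkB <- peakHeight(masked, 2.95e5)
  expect_equal(pkA$height, pkB$height)
})

test_that("noiseless smoothed peak height approaches 2 + 2e", {
  # apex attenuation: +/-5 kb median on a 40 kb half-width triangle reads
  # the value ~3 kb from the apex (factor ~0.925); kernel 2 kb adds ~1%.
  gs <- makeRerepGenome(efficiency = 0.5)
  cfg <- simConfig(noiseSigma = 0, nReplicates = 1L)
  cp <- runPipeline(gs, cfg, kernel = 2)
  pk <- peakHeight(cp, 2e6)
  expect_equal(pk$height, 1.0, tolerance = 0.1)
  expect_gt(pk$height, 0.88)
})

test_that("pipeline is deterministic end to end", {
  gs <- makeRerepGenome(chromLen = 3e5)
  cfg <- simConfig(noiseSigma = 0.1, seed = 11L)
  a <- runPipeline(gs, cfg)
  b <- runPipeline(gs, cfg)
  expect_identical(profileMean(a), profileMean(b))
  expect_identical(profileSD(a), profileSD(b))
})
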