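# Generative model: triangular re-replication peaks, log-normal channel
# noise, deterministic seeding, S-phase content.

test_that("expected re-replication profile is a triangle of height 2 + 2e", {
  gs <- makeRerepGenome(chromLen = 5e5, originPos = 2.5e5,
                        efficiency = 0.5)
  cfg <- simConfig()  # fork reach v*T = 40 kb
  C <- expectedRerepProfile(gs, cfg)
  reach <- cfg@forkSpeed * cfg@inductionMinutes
  expect_equal(C("chrS", 2.5e5), 3.0)                    # 2 + 2 * 0.5
  expect_equal(C("chrS", 2.5e5 + reach), 2.0)            # support boundary
  expect_equal(C("chrS", 2.5e5 + reach / 2), 2.5)        # linear flank
  expect_equal(C("chrS", 2.5e5 - reach / 4), 2.75)       # symmetric
  # full width of the triangular support is 2 v T
  pos <- seq(1, 5e5, by = 100)
  above <- pos[C("chrS", pos) > 2 + 1e-12]
  expect_lt(diff(range(above)), 2 * reach)
  expect_gt(diff(range(above)), 2 * reach - 400)
})

test_that("zero efficiency gives a flat 2C baseline", {
  gs <- makeRerepGenome(efficiency = 0)
  C <- expectedRerepProfile(gs, simConfig())
  pos <- seq(1e3, 4e6, by = 1e5)
  expect_equal(C("chrS", pos), rep(2, length(pos)))
})

test_that("noiseless tables reproduce the expected profile exactly", {
  gs <- makeRerepGenome(chromLen = 5e5, originPos = 2.5e5, efficiency = 0.5)
  cfg <- simConfig(noiseSigma = 0, gainCy3 = 0.7, gainCy5 = 3.1)
  pt <- simulateProbeTable(gs, cfg, 1L)
  p <- probes(pt)
  C <- expectedRerepProfile(gs, cfg)
  ratio <- (p$cy5 / cfg@gainCy5) / (p$cy3 / cfg@gainCy3)
  expect_equal(ratio, C("chrS", p$pos) / 2, tolerance = 1e-12)
})

test_that("same seed and replicate reproduce identical tables; replicates differ", {
  gs <- makeRerepGenome(chromLen = 2e5)
  cfg <- simConfig(noiseSigma = 0.1, seed = 7L)
  a <- simulateProbeTable(gs, cfg, 1L)
  b <- simulateProbeTable(gs, cfg, 1L)
  expect_identical(probes(a), probes(b))
  c2 <- simulateProbeTable(gs, cfg, 2L)
  expect_false(identical(probes(a)$cy5, probes(c2)$cy5))
  # simulation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateProbeTable(gs, cfg, 1L))
  expect_identical(rnorm(1), before)
})

test_that("noisy ratios match the log-normal mean formula", {
  # ratio of two independent log-normal channels: E[cy5/cy3] =
  # (C/2) * exp(sigma^2/2)^2 = (C/2) * exp(sigma^2)
  gs <- makeRerepGenome(chromLen = 1e8, efficiency = 0)  # flat, 1e5 probes
  cfg <- simConfig(noiseSigma = 0.1, probeSpacing = 1000, seed = 3L)
  p <- probes(simulateProbeTable(gs, cfg, 1L))
  r <- p$cy5 / p$cy3
  expected <- exp(cfg@noiseSigma^2)
  se <- stats::sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - expected), 2 * se + 1e-12)
})

test_that("masked intervals flag exactly the probes inside them", {
  mask <- GenomicRanges::GRanges("chrS", IRanges::IRanges(100001, 144000))
  gs <- makeRerepGenome(chromLen = 5e5, masked = mask)
  p <- probes(simulateProbeTable(gs, simConfig(noiseSigma = 0), 1L))
  expect_identical(sum(p$masked), 44L)  # 44 kb rDNA-like block, 1 kb probes
  expect_true(all(p$pos[p$masked] >= 100001 & p$pos[p$masked] <= 144000))
})

test_that("S-phase content follows independent-origin inclusion-exclusion", {
  gs <- genomeSpec(c(chrS = 2e5),
                   origins = rbind(
                     originSpec("chrS", 9e4, 0, sphaseTime = 0,
                                sphaseEff = 0.5),
                     originSpec("chrS", 1.1e5, 0, sphaseTime = 0,
                                sphaseEff = 0.5)))
  cfg <- simConfig(forkSpeed = 1000)
  f0 <- expectedSphaseProfile(gs, cfg, 0)
  expect_equal(f0("chrS", c(1, 9e4, 1.99e5)), c(1, 1, 1))  # unreplicated
  # both forks past x = 1e5 at t = 60 (reach 60 kb): 1 - 0.5^2 = 0.75
  f60 <- expectedSphaseProfile(gs, cfg, 60)
  expect_equal(f60("chrS", 1e5), 1.75)
  # single origin, full efficiency, long time: fully replicated
  gs1 <- genomeSpec(c(chrS = 2e5),
                    origins = originSpec("chrS", 1e5, 0, sphaseTime = 0,
                                         sphaseEff = 1))
  fInf <- expectedSphaseProfile(gs1, cfg, 1e4)
  expect_equal(fInf("chrS", c(1, 2e5)), c(2, 2))
  expect_error(expectedSphaseProfile(makeRerepGenome(), cfg, 10), "S-phase")
})

test_that("a mid-S harvest yields genome mean content in the 1.3-1.6C window", {
  # ten early origins, reach 25 kb of the 100 kb inter-origin spacing
  ori <- do.call(rbind, lapply(seq(5e4, 9.5e5, by = 1e5), function(p)
    originSpec("chrS", p, 0, sphaseTime = 0, sphaseEff = 0.9)))
  gs <- genomeSpec(c(chrS = 1e6), origins = ori)
  cfg <- simConfig(forkSpeed = 1000)
  f <- expectedSphaseProfile(gs, cfg, 25)
  m <- mean(f("chrS", seq(500, 1e6, by = 1000)))
  expect_gt(m, 1.3); expect_lt(m, 1.6)
})

test_that("ground-truth bedGraph matches the profile function", {
  gs <- makeRerepGenome(chromLen = 1e5, originPos = 5e4, efficiency = 0.5)
  cfg <- simConfig(probeSpacing = 5000)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeGroundTruth(gs, cfg, path)
  bg <- readBedGraph(path)
  C <- expectedRerepProfile(gs, cfg)
  expect_equal(bg$value, C("chrS", bg$end), tolerance = 1e-9)
})
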