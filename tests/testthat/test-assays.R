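# ChIP-qPCR 2^-ddCt fold enrichment and plasmid mitotic stability.

# Long-format Ct fixture: per-locus IP/WCE triplicates for one culture.
makeCtTable <- function(sample = "c1",
                        ipCt = c(target = 24, ADH1 = 25, SLH1 = 25),
                        wceCt = c(target = 25, ADH1 = 25, SLH1 = 25)) {
  rows <- expand.grid(sample = sample, fraction = c("IP", "WCE"),
                      target = names(ipCt), replicate = 1:3,
                      stringsAsFactors = FALSE)
  rows$ct <- ifelse(rows$fraction == "IP", ipCt[rows$target],
                    wceCt[rows$target])
  rows
}

test_that("ddCt fold enrichment follows the two-control averaging convention", {
  # target dCt equals the controls': no enrichment
  even <- makeCtTable(ipCt = c(target = 25, ADH1 = 25, SLH1 = 25))
  expect_equal(unname(foldEnrichment(even, "target")), 1.0)
  # one cycle below the controls' mean: fold 2
  shift <- makeCtTable()
  expect_equal(unname(foldEnrichment(shift, "target")), 2.0)
  # controls dCt {3, 5}, target dCt 3 -> ddCt = 3 - 4 = -1 -> fold 2
  mixed <- makeCtTable(ipCt = c(target = 28, ADH1 = 28, SLH1 = 30),
                       wceCt = c(target = 25, ADH1 = 25, SLH1 = 25))
  expect_equal(unname(foldEnrichment(mixed, "target")), 2.0)
  # mean-of-folds alternative: (2^0 + 2^2) / 2 = 2.5
  expect_equal(unname(foldEnrichment(mixed, "target",
                                     controlAggregation = "fold")), 2.5)
  expect_error(foldEnrichment(shift[shift$fraction == "IP", ], "target"),
               "missing")
})

test_that("ddCt is invariant to global Ct offsets and technical-replicate scatter", {
  base <- makeCtTable(ipCt = c(target = 23.7, ADH1 = 26.1, SLH1 = 25.3),
                      wceCt = c(target = 24.9, ADH1 = 25.2, SLH1 = 24.8))
  f0 <- foldEnrichment(base, "target")
  shifted <- base; shifted$ct <- shifted$ct + 3.5
  expect_equal(foldEnrichment(shifted, "target"), f0)
  # triplicates average before dCt: scatter with equal means changes nothing
  scattered <- base
  scattered$ct <- scattered$ct + rep(c(-0.2, 0, 0.2), each = 1,
                                     length.out = nrow(scattered))
  # rebalance so each (fraction, target) triple keeps its mean
  key <- interaction(scattered$fraction, scattered$target)
  for (k in levels(key)) {
    i <- which(key == k)
    scattered$ct[i] <- scattered$ct[i] - mean(scattered$ct[i]) +
      mean(base$ct[i])
  }
  expect_equal(foldEnrichment(scattered, "target"), f0, tolerance = 1e-12)
  # a single control duplicated equals the one-control formula
  dup <- makeCtTable(ipCt = c(target = 24, ADH1 = 26, SLH1 = 26),
                     wceCt = c(target = 25, ADH1 = 25, SLH1 = 25))
  dCtTarget <- 24 - 25; dCtControl <- 26 - 25
  expect_equal(unname(foldEnrichment(dup, "target")),
               2^(-(dCtTarget - dCtControl)))
})

test_that("enrichment summary reports mean and SD over cultures", {
  expect_equal(enrichmentSummary(c(2, 2, 2))$meanFold, 2)
  expect_equal(enrichmentSummary(c(2, 2, 2))$sdFold, 0)
  s <- enrichmentSummary(c(1, 3), target = "ARS317")
  expect_equal(s$meanFold, 2)
  expect_equal(s$sdFold, sqrt(2), tolerance = 1e-12)
  set.seed(19)
  folds <- exp(rnorm(3))
  s3 <- enrichmentSummary(folds)
  expect_equal(s3$meanFold, mean(folds))
  expect_equal(s3$sdFold, sd(folds))
  expect_error(enrichmentSummary(2), "at least 2")
})

test_that("mitotic stability pools plates per transformant then averages", {
  counts <- expand.grid(construct = "pRIP", transformant = 1:3, plate = 1:5,
                        stringsAsFactors = FALSE)
  counts$nonselective_cfu <- 200
  counts$selective_cfu <- rep(c(180, 90, 120), 5)  # 900/450/600 of 1000
  res <- mitoticStability(counts)
  expect_equal(res$meanStability, mean(c(0.9, 0.45, 0.6)))
  expect_equal(res$sdStability, sd(c(0.9, 0.45, 0.6)), tolerance = 1e-12)
  expect_identical(res$n, 3L)
  expect_false(res$anyOverOne)
  # invariant to redistributing colonies among plates at fixed totals
  shuffled <- counts
  shuffled$selective_cfu[shuffled$transformant == 1] <- c(900, 0, 0, 0, 0)
  res2 <- mitoticStability(shuffled)
  expect_equal(res2$meanStability, res$meanStability)
  expect_equal(res2$sdStability, res$sdStability)
  # perfect retention and zero retention
  all1 <- counts; all1$selective_cfu <- 200
  expect_equal(mitoticStability(all1)$meanStability, 1)
  expect_equal(mitoticStability(all1)$sdStability, 0)
  none <- counts; none$selective_cfu <- 0
  expect_equal(mitoticStability(none)$meanStability, 0)
  # fractions over 1 are flagged, not truncated
  over <- counts; over$selective_cfu <- 210
  resOver <- mitoticStability(over)
  expect_true(resOver$anyOverOne)
  expect_gt(resOver$meanStability, 1)
  bad <- counts; bad$nonselective_cfu <- 0
  expect_error(mitoticStability(bad), "zero total")
})

test_that("assay tables read from TSV with validation", {
  ctPath <- withr::local_tempfile(fileext = ".tsv")
  ct <- makeCtTable()
  write.table(ct, ctPath, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readQpcrTable(ctPath)
  expect_equal(unname(foldEnrichment(back, "target")), 2.0)

  stPath <- withr::local_tempfile(fileext = ".tsv")
  counts <- expand.grid(construct = "p1", transformant = 1:3, plate = 1:5)
  counts$selective_cfu <- 100; counts$nonselective_cfu <- 200
  write.table(counts, stPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(mitoticStability(readStabilityTable(stPath))$meanStability,
               0.5)
  expect_error(readQpcrTable(stPath), "columns")
})
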