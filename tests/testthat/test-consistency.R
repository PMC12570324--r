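.mkResults <- function() {
  # hand-built long table: combination A/S1 on 2 plates (5 doses),
  # B/S1 on 3 plates, C/S1 on 2 plates but with a 3-dose series
  row <- function(plate, cmp, nd, auc) {
    data.frame(
      plateId = plate, compoundId = cmp, sampleId = "S1", nDoses = nd,
      auc = auc, dss = auc - 5, ic50 = 1, ic50Reached = TRUE,
      nrfe = 4, zPrime = 0.8, tier = "acceptable"
    )
  }
  rbind(
    row("p1", "A", 5L, 60), row("p2", "A", 5L, 62),
    row("p1", "B", 5L, 40), row("p2", "B", 5L, 41), row("p3", "B", 5L, 39),
    row("p1", "C", 3L, 20), row("p2", "C", 3L, 22)
  )
}

test_that("pairReplicates keeps exactly-two-plate combinations with >3 doses", {
  pairs <- pairReplicates(.mkResults())
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$compoundId, "A")
  excl <- attr(pairs, "exclusions")
  expect_equal(unname(excl["not_two_plates"]), 1L)  # B on 3 plates
  expect_equal(unname(excl["too_few_doses"]), 1L)   # C with 3 doses
  empty <- pairReplicates(.mkResults()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("tier strata use the worst tier of the two plates", {
  res <- .mkResults()[1:2, ]
  res$tier <- c("acceptable", "poor")
  pairs <- pairReplicates(res)
  td <- tierStratifiedDeltas(pairs)
  expect_equal(td$strata, "poor")
  # a stratum with < 2 pairs is marked insufficient
  expect_true(td$summary$insufficient[td$summary$tier == "poor"])
})

test_that("identical replicate values give zero deltas throughout", {
  res <- .mkResults()[c(1:2, 6:7), ]  # A and C, each on exactly two plates
  res$nDoses <- 5L
  res$auc <- 50; res$dss <- 45
  pairs <- pairReplicates(res)
  td <- tierStratifiedDeltas(pairs)
  expect_equal(td$summary$medianAbsDAuc[td$summary$tier == "acceptable"], 0)
})

test_that("quality tiers order replicate deltas and rank-sum tests detect it", {
  b <- simulateReplicateBatch(plateSimConfig(geometry = 96), nPairs = 25, seed = 11)
  pairs <- pairReplicates(b$results)
  expect_gte(nrow(pairs), 150L)
  td <- tierStratifiedDeltas(pairs)
  med <- setNames(td$summary$medianAbsDAuc, td$summary$tier)
  expect_lt(med[["acceptable"]], med[["borderline"]])
  expect_lt(med[["borderline"]], med[["poor"]])
  expect_true(all(td$tests$pValue < 0.05))
})

test_that("threshold sweeps partition pairs and recover the baseline", {
  b <- simulateReplicateBatch(plateSimConfig(geometry = 96), nPairs = 12, seed = 31)
  pairs <- pairReplicates(b$results)
  sweep <- thresholdSweep(pairs, zGrid = c(-10, 0.5), nrfeGrid = c(1e6, 10))
  # all-inclusive cell: rho over "good" equals the whole-set baseline
  expect_equal(sweep$rhoGood[1, 1], sweep$baselineRho, tolerance = 1e-12)
  expect_equal(sweep$nGood[1, 1] + sweep$nPoor[1, 1], nrow(pairs))
  expect_true(all(sweep$nGood + sweep$nPoor == nrow(pairs)))
  # a cell with almost no qualifying pairs is masked
  tiny <- thresholdSweep(pairs, zGrid = 0.9999, nrfeGrid = 0.001)
  expect_true(is.na(tiny$rhoGood[1, 1]))
  expect_error(thresholdSweep(pairs, numeric(0), 10), class = "configError")
})

test_that("quality filtering moves correlations in the expected direction", {
  b <- simulateReplicateBatch(
    plateSimConfig(geometry = 96), nPairs = 30,
    tierMix = c(acceptable = 0.55, borderline = 0.2, poor = 0.25), seed = 71
  )
  pairs <- pairReplicates(b$results)
  rep_ <- consistencyReport(pairs, nBoot = 500, seed = 5)
  expect_gt(rep_$rhoGood, rep_$spearmanRho)
  expect_gt(rep_$spearmanRho, rep_$rhoPoor)
})

test_that("the bootstrap reference is seeded, tie-tolerant and consistent", {
  set.seed(91)
  x <- rnorm(60); y <- x + rnorm(60, 0, 0.6)
  b1 <- bootstrapReference(x, y, nBoot = 300, seed = 7)
  b2 <- bootstrapReference(x, y, nBoot = 300, seed = 7)
  expect_identical(b1, b2)
  # identical vectors: every resampled correlation is 1 (up to fp rounding)
  same <- bootstrapReference(x, x, nBoot = 100, seed = 1)
  expect_equal(as.numeric(same), rep(1, 100))
  expect_error(bootstrapReference(x, y[-1]), class = "contractViolation")
  expect_error(bootstrapReference(1:5, 1:5), class = "contractViolation")
})

test_that("bootstrap spread shrinks roughly as 1/sqrt(n)", {
  set.seed(92)
  widths <- sapply(c(50, 200, 800), function(n) {
    x <- rnorm(n); y <- x + rnorm(n)
    sd(bootstrapReference(x, y, nBoot = 400, seed = 3))
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(800 / 50), tolerance = 0.5)
})

test_that("KS comparison and standardized mean difference behave as stated", {
  set.seed(93)
  ref <- rnorm(1000)
  same <- compareToReference(ref, ref)
  expect_equal(same$ksStatistic, 0)
  shifted <- compareToReference(ref, rnorm(1000, 1, 1))
  expect_lt(shifted$ksP, 0.001)
  expect_equal(shifted$effectSize, 1, tolerance = 0.1)
  degen <- compareToReference(rep(2, 20), rep(2, 20))
  expect_true(isUndefinedMetric(degen$effectSize))
  expect_error(compareToReference(ref, 1:5), class = "contractViolation")
})

test_that("the three-sigma threshold rule matches its closed form", {
  set.seed(94)
  v <- rnorm(1000, 5, 1)
  expect_equal(deriveThreshold(v), 8, tolerance = 0.3)
  expect_equal(deriveThreshold(rep(6, 50)), 6)
  expect_equal(deriveThreshold(v, robust = TRUE), median(v) + 3 * mad(v))
  expect_error(deriveThreshold(rnorm(10)), class = "insufficientDataError")
})
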