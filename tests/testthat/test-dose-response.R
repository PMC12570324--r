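test_that("noiseless LL4 data are recovered to high precision", {
  conc <- 10^seq(-1.5, 1.5, 0.5)  # 7 half-log doses around c = 1
  truth <- c(a = 0, b = 1, c = 1, d = 100)
  s <- makeSeries(conc, ll4(conc, 0, 1, 1, 100))
  f <- fitLL4(s)
  expect_equal(fitStatus(f), "converged")
  co <- fitCoefficients(f)
  expect_equal(co[["a"]], 0, tolerance = 1e-3)
  expect_equal(co[["d"]], 100, tolerance = 1e-3)
  expect_equal(co[["b"]], 1, tolerance = 1e-3)
  expect_equal(co[["c"]], 1, tolerance = 1e-3)
  expect_lt(max(fitResiduals(f)), 1e-6)
})

test_that("flat series take the deterministic flat fallback", {
  conc <- 10^seq(-2, 1, 0.5)
  inactive <- fitLL4(makeSeries(conc, rep(0, length(conc))))
  expect_equal(fitStatus(inactive), "fallback_flat")
  expect_equal(inactive@fitted, rep(0, length(conc)))
  expect_equal(fitResiduals(inactive), rep(0, length(conc)))

  potent <- fitLL4(makeSeries(conc, rep(100, length(conc))))
  expect_equal(fitStatus(potent), "fallback_flat")
  expect_equal(fitCoefficients(potent)[["d"]], 100, tolerance = 1e-9)
  expect_lt(max(fitResiduals(potent)), 1e-9)
})

test_that("series with one distinct concentration are unfittable", {
  s <- makeSeries(rep(1, 4), c(10, 20, 30, 40))
  expect_error(fitLL4(s), class = "unfittableSeriesError")
})

test_that("few-dose series are flagged low-confidence", {
  conc <- c(0.1, 1, 10)
  f <- fitLL4(makeSeries(conc, ll4(conc, 0, 1, 1, 90)))
  expect_true(f@lowConfidence)
  conc7 <- 10^seq(-1.5, 1.5, 0.5)
  f7 <- fitLL4(makeSeries(conc7, ll4(conc7, 0, 1, 1, 90)))
  expect_false(f7@lowConfidence)
})

test_that("residuals are invariant to the order of series points", {
  set.seed(11)
  conc <- 10^seq(-2, 1.5, 0.5)
  y <- ll4(conc, 2, 1.5, 0.3, 85) + rnorm(length(conc), 0, 4)
  perm <- sample(seq_along(conc))
  f1 <- fitLL4(makeSeries(conc, y))
  f2 <- fitLL4(makeSeries(conc[perm], y[perm]))
  expect_equal(sort(fitResiduals(f1)), sort(fitResiduals(f2)), tolerance = 1e-8)
})

test_that("LL4 is scale-equivariant: doubling concentrations doubles c only", {
  set.seed(12)
  conc <- 10^seq(-2, 1.5, 0.5)
  y <- ll4(conc, 0, 1.2, 0.5, 95) + rnorm(length(conc), 0, 3)
  f1 <- fitLL4(makeSeries(conc, y))
  f2 <- fitLL4(makeSeries(conc * 2, y))
  expect_equal(f1@fitted, f2@fitted, tolerance = 1e-5)
  expect_equal(fitCoefficients(f2)[["c"]] / fitCoefficients(f1)[["c"]], 2, tolerance = 1e-4)
})

test_that("parameters are recovered under realistic noise", {
  # seeded recovery sweep (a lighter version of the acceptance benchmark)
  set.seed(1)
  conc <- 10^seq(-3.5, 1, 0.5)
  relErrC <- relErrD <- numeric(100)
  for (i in 1:100) {
    tr <- c(a = runif(1, -2, 5), d = runif(1, 40, 100),
            b = runif(1, 0.5, 3), c = 10^runif(1, -2.75, 0))
    y <- ll4(conc, tr["a"], tr["b"], tr["c"], tr["d"]) + rnorm(length(conc), 0, 5)
    f <- fitLL4(makeSeries(conc, y))
    co <- fitCoefficients(f)
    relErrC[i] <- abs(co[["c"]] - tr[["c"]]) / tr[["c"]]
    relErrD[i] <- abs(co[["d"]] - tr[["d"]]) / tr[["d"]]
  }
  expect_lt(median(relErrC), 0.15)
  expect_lt(median(relErrD), 0.05)
})

test_that("response metrics match closed-form expectations", {
  conc <- 10^seq(-2, 2, 0.5)  # symmetric in log10 around c = 1
  flat100 <- fitLL4(makeSeries(conc, rep(100, length(conc))))
  m100 <- computeResponseMetrics(flat100, makeSeries(conc, rep(100, length(conc))))
  expect_equal(m100$auc, 100, tolerance = 1e-9)

  flat0 <- fitLL4(makeSeries(conc, rep(0, length(conc))))
  m0 <- computeResponseMetrics(flat0, makeSeries(conc, rep(0, length(conc))))
  expect_equal(m0$auc, 0, tolerance = 1e-12)
  expect_equal(m0$dss, 0)

  s <- makeSeries(conc, ll4(conc, 0, 1, 1, 100))
  f <- fitLL4(s)
  m <- computeResponseMetrics(f, s)
  expect_equal(m$auc, 50, tolerance = 0.5)  # symmetric sigmoid, c at log-center
  expect_true(m$ic50Reached)
  expect_equal(m$ic50, 1, tolerance = 1e-3)
})

test_that("AUC is monotone non-decreasing in the maximum asymptote d", {
  conc <- 10^seq(-2, 1.5, 0.5)
  s <- makeSeries(conc, ll4(conc, 0, 1, 1, 80))
  aucs <- sapply(seq(40, 120, 10), function(d) {
    fit <- new("LL4Fit",
      a = 0, b = 1, c = 1, d = d,
      fitted = ll4(conc, 0, 1, 1, d), residuals = rep(0, length(conc)),
      status = "converged", lowConfidence = FALSE
    )
    computeResponseMetrics(fit, s)$auc
  })
  expect_true(all(diff(aucs) >= 0))
})

test_that("an IC50 outside the tested range is marked not reached", {
  conc <- 10^seq(-2, 0, 0.5)  # top dose 1 uM
  y <- ll4(conc, 0, 1, 100, 90)  # c = 100 uM, far above range
  f <- new("LL4Fit",
    a = 0, b = 1, c = 100, d = 90, fitted = y, residuals = rep(0, length(y)),
    status = "converged", lowConfidence = FALSE
  )
  m <- computeResponseMetrics(f, makeSeries(conc, y))
  expect_false(m$ic50Reached)
})

test_that("failed fits propagate undefined metric markers", {
  f <- new("LL4Fit",
    a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
    fitted = rep(NA_real_, 3), residuals = rep(NA_real_, 3),
    status = "failed", lowConfidence = TRUE
  )
  m <- computeResponseMetrics(f, makeSeries(c(0.1, 1, 10), c(0, 50, 100)))
  expect_true(isUndefinedMetric(m$auc))
  expect_true(isUndefinedMetric(m$ic50))
})

test_that("opt-in outlier down-weighting tames a single corrupted point", {
  conc <- 10^seq(-3, 1, 0.25)  # dense series: the spike has low leverage
  y <- ll4(conc, 0, 1.5, 0.1, 90)
  y[4] <- y[4] + 60
  fRaw <- fitLL4(makeSeries(conc, y))
  fRob <- fitLL4(makeSeries(conc, y), outlierHandling = TRUE)
  expect_lt(sum(fitResiduals(fRob)[-4]), sum(fitResiduals(fRaw)[-4]))
})
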