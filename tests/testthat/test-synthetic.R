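test_that("the generator is a pure function of config and seed", {
  cfg <- plateSimConfig(geometry = 96, noiseSd = 5, seed = 123)
  a <- simulatePlate(cfg)
  b <- simulatePlate(cfg)
  expect_identical(wellData(a$plate), wellData(b$plate))
  expect_identical(a$truth$params, b$truth$params)
  c_ <- simulatePlate(cfg, seed = 124)
  expect_false(identical(wellData(a$plate)$response, wellData(c_$plate)$response))
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulatePlate(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated layouts respect geometry and control placement", {
  sim <- simulatePlate(plateSimConfig(geometry = 384, seed = 1))
  w <- wellData(sim$plate)
  expect_true(all(w$col[w$wellType == "neg_ctrl"] %in% 1:2))
  expect_true(all(w$col[w$wellType == "pos_ctrl"] %in% 23:24))
  expect_true(all(w$col[w$wellType == "compound"] %in% 3:22))
  expect_equal(nDoseSeries(sim$plate), 32L)
  expect_error(
    simulatePlate(plateSimConfig(geometry = 96, nCompounds = 99)),
    class = "configError"
  )
})

test_that("control-well statistics land where the noise model predicts", {
  zp <- sapply(1:25, function(s) {
    sim <- simulatePlate(plateSimConfig(geometry = 384, noiseSd = 5), seed = 4000 + s)
    as.numeric(zPrime(summarizeControls(sim$plate)))
  })
  expect_true(all(zp > 0.5 & zp < 0.95))
})

test_that("artifact injection changes exactly the targeted region", {
  sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 2))
  spec <- artifactSpec("column_striping", 25, columns = c(3, 5))
  shifted <- injectArtifact(sim$plate, spec)
  w0 <- wellData(sim$plate)
  w1 <- wellData(shifted)
  inside <- w0$col %in% c(3, 5) & w0$wellType == "compound"
  expect_identical(w1$response[!inside], w0$response[!inside])
  expect_equal(w1$response[inside], w0$response[inside] + 25)
  # zero magnitude: bit-identical output
  same <- injectArtifact(sim$plate, artifactSpec("column_striping", 0, columns = c(3, 5)))
  expect_identical(wellData(same)$response, w0$response)
})

test_that("gradients ramp linearly and edge effects ring the plate", {
  sim <- simulatePlate(plateSimConfig(geometry = 96, noiseSd = 0, seed = 3))
  w0 <- wellData(sim$plate)
  grad <- injectArtifact(sim$plate, artifactSpec("linear_gradient", 24, axis = "col",
                                                 target = "all_wells"))
  delta <- wellData(grad)$response - w0$response
  expect_equal(delta, 24 * (w0$col - 1) / 11, tolerance = 1e-12)

  edge <- injectArtifact(sim$plate, artifactSpec("edge_effect", 30, depth = 1L,
                                                 target = "all_wells"))
  de <- wellData(edge)$response - w0$response
  onEdge <- w0$row %in% c(1, 8) | w0$col %in% c(1, 12)
  expect_equal(de[onEdge], rep(30, sum(onEdge)))
  expect_true(all(de[!onEdge] == 0))
})

test_that("edge effects that hit controls degrade Z-prime", {
  sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 6))
  z0 <- as.numeric(zPrime(summarizeControls(sim$plate)))
  hit <- injectArtifact(sim$plate, artifactSpec("edge_effect", -35, depth = 2L,
                                                target = "all_wells"))
  z1 <- as.numeric(zPrime(summarizeControls(hit)))
  expect_lt(z1, z0)
})

test_that("an empty artifact region warns and leaves the plate unchanged", {
  sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 4))
  # column 1 holds only negative controls; compound_only targeting misses it
  expect_warning(
    out <- injectArtifact(sim$plate, artifactSpec("column_striping", 40, columns = 1L)),
    "unchanged"
  )
  expect_identical(wellData(out), wellData(sim$plate))
  expect_error(
    injectArtifact(sim$plate, artifactSpec("column_striping", 40, columns = 99L)),
    class = "configError"
  )
})

test_that("replicate batches share truth within a pair and hit their tiers", {
  b <- simulateReplicateBatch(plateSimConfig(geometry = 96), nPairs = 8,
                              tierMix = c(acceptable = 0.5, borderline = 0.25, poor = 0.25),
                              seed = 21)
  expect_equal(nrow(b$pairTable), 8L)
  expect_length(b$plates, 16L)
  # measured tier of the degraded plate matches the target
  for (i in seq_len(nrow(b$pairTable))) {
    r2 <- b$results[b$results$pairId == i & b$results$replicate == 2, ]
    expect_equal(unique(r2$tier), b$pairTable$targetTier[i])
  }
  # clean sides stay acceptable in the vast majority of pairs
  r1 <- b$results[b$results$replicate == 1, ]
  expect_gte(mean(r1$tier == "acceptable"), 0.8)
  # empty batch contract
  empty <- simulateReplicateBatch(plateSimConfig(geometry = 96), nPairs = 0)
  expect_equal(nrow(empty$results), 0L)
})

test_that("batch generation is deterministic under the master seed", {
  cfg <- plateSimConfig(geometry = 96)
  b1 <- simulateReplicateBatch(cfg, nPairs = 3, seed = 9)
  b2 <- simulateReplicateBatch(cfg, nPairs = 3, seed = 9)
  expect_identical(b1$results$auc, b2$results$auc)
  expect_identical(b1$pairTable$magnitude, b2$pairTable$magnitude)
})

test_that("tierMix proportions must sum to one", {
  expect_error(
    simulateReplicateBatch(plateSimConfig(geometry = 96), nPairs = 2,
                           tierMix = c(acceptable = 0.5, poor = 0.2)),
    class = "configError"
  )
})
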