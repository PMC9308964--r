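test_that("pinball loss evaluates its defining cases", {
  expect_equal(pinballLoss(3, 3, 0.5), 0)
  expect_equal(pinballLoss(5, 3, 0.9), 1.8)
  expect_equal(pinballLoss(3, 5, 0.9), 0.2)
  expect_error(pinballLoss(1, 1, 0), "tau")
  expect_error(pinballLoss(1, 1, 1), "tau")
})

test_that("the total loss is the sum of the per-head batch means", {
  set.seed(1)
  y <- rlnorm(200)
  taus <- c(0.25, 0.5, 0.75, 0.9, 0.95)
  qmat <- sapply(taus, function(tau) quantile(y, tau))
  qmat <- matrix(qmat, nrow = 200, ncol = 5, byrow = TRUE)
  parts <- sapply(seq_along(taus),
                  function(k) pinballLoss(y, qmat[, k], taus[k]))
  expect_equal(totalLoss(y, qmat, taus), sum(parts))
  expect_equal(totalLoss(y, matrix(y, 200, 5), taus), 0)
  expect_error(totalLoss(y, qmat[, 1:4], taus), "per percentile")
})

test_that("constant minimizers of the pinball loss are empirical quantiles", {
  set.seed(42)
  y <- rlnorm(1001, meanlog = 0.4, sdlog = 0.5)
  for (tau in c(0.25, 0.5, 0.75, 0.9, 0.95)) {
    argmin <- bruteForceQuantile(y, tau)
    expect_equal(argmin, unname(quantile(y, tau, type = 1)), tolerance = 1e-12)
    # no small perturbation of the argmin improves the loss
    for (eps in c(-0.05, 0.05)) {
      expect_gte(pinballLoss(y, argmin + eps, tau), pinballLoss(y, argmin, tau))
    }
  }
})

test_that("splitting holds out the right fraction with a disjoint test set", {
  cfg <- syntheticConfig(nSites = 1000, seed = 5)
  samples <- generateSites(cfg)
  sp <- splitData(samples, testFraction = 0.05, seed = 1)
  expect_equal(nrow(sp$test), 50)
  expect_equal(nrow(sp$pool), 950)
  expect_length(intersect(sp$test$site_id, sp$pool$site_id), 0)
  expect_error(splitData(samples[1:10, ]), "20")
})

test_that("out-of-bag fraction matches bootstrap theory", {
  cfg <- syntheticConfig(nSites = 10000, seed = 6)
  samples <- generateSites(cfg)
  sp <- splitData(samples, testFraction = 0.05, seed = 2)
  oobFrac <- length(sp$resamples[[1]]$validation) / nrow(sp$pool)
  # P(row never drawn) = (1 - 1/n)^n -> e^-1, the 0.632-rule complement
  expect_lt(abs(oobFrac - (1 - 1 / nrow(sp$pool))^nrow(sp$pool)), 0.02)
  expect_lt(abs(oobFrac - exp(-1)), 0.02)
})

test_that("training reduces the loss and is seed-deterministic", {
  cfg <- syntheticConfig(nSites = 2000, seed = 9)
  samples <- generateSites(cfg)
  tc <- trainingConfig(epochs = 30, seed = 4)
  m1 <- trainQuantileModel(samples, config = tc)
  expect_lt(tail(lossHistory(m1), 1), lossHistory(m1)[1])
  m2 <- trainQuantileModel(samples, config = tc)
  grid <- generateGrid(6, 6, cfg, seed = 1)
  expect_identical(predictQuantiles(m1, grid), predictQuantiles(m2, grid))
})

test_that("predictions are ordered, floored, and row-order invariant", {
  m <- sharedModel()
  cfg <- sharedConfig()
  newdata <- generateSites(syntheticConfig(nSites = 300, seed = 77))
  q <- predictQuantiles(m, newdata)
  expect_true(all(q$q25 <= q$q50 & q$q50 <= q$q75 &
                  q$q75 <= q$q90 & q$q90 <= q$q95))
  expect_true(all(as.matrix(q) >= 0))
  perm <- sample(nrow(newdata))
  qPerm <- predictQuantiles(m, newdata[perm, ])
  expect_equal(as.matrix(qPerm), as.matrix(q)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(predictQuantiles(m, newdata[, c("mat", "tap")]), "missing")
})

test_that("a single-cell grid predicts end-to-end", {
  m <- sharedModel()
  g <- generateGrid(1, 1, sharedConfig(), seed = 2)
  q <- predictQuantiles(m, g)
  expect_equal(nrow(q), 1)
  expect_equal(attr(q, "grid_dim"), c(1L, 1L))
})

test_that("the model recovers the land-cover effect at matched climate", {
  m <- sharedModel()
  rows <- generateSites(syntheticConfig(nSites = 400, seed = 31))
  qCrop <- predictQuantiles(m, rows, landcover = "cropland")
  qPast <- predictQuantiles(m, rows, landcover = "pasture_natural")
  expect_gt(mean(qPast$q75), mean(qCrop$q75))
  expect_gt(mean(qPast$q90), mean(qCrop$q90))
})

test_that("the trained median beats the constant-median baseline", {
  m <- sharedModel()
  test <- m@test
  baseline <- sqrt(mean((test$soc_pct - median(test$soc_pct))^2))
  expect_lt(rmseQ50(m), baseline)
  expect_equal(socpotential:::.rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(socpotential:::.rmse(c(3, 4), c(3, 4)), 0)
})

test_that("per-land-cover mode trains a model per group and predicts", {
  cfg <- syntheticConfig(nSites = 3000, seed = 15)
  samples <- generateSites(cfg)
  m <- trainQuantileModel(samples, config = trainingConfig(epochs = 25, seed = 2),
                          mode = "per_landcover")
  q <- predictQuantiles(m, samples[1:50, ])
  expect_equal(nrow(q), 50)
  expect_true(all(q$q25 <= q$q95))
})

test_that("models round-trip through JSON with identical predictions", {
  m <- sharedModel()
  path <- withr::local_tempfile(fileext = ".json")
  saveQuantileModel(m, path)
  m2 <- loadQuantileModel(path)
  rows <- generateSites(syntheticConfig(nSites = 40, seed = 61))
  expect_equal(predictQuantiles(m2, rows), predictQuantiles(m, rows),
               tolerance = 1e-12)
  expect_equal(rmseQ50(m2), rmseQ50(m), tolerance = 1e-12)
})

test_that("bootstrap model selection picks the lowest validation loss", {
  cfg <- syntheticConfig(nSites = 1500, seed = 23)
  samples <- generateSites(cfg)
  m <- trainQuantileModel(samples,
                          config = trainingConfig(epochs = 15, seed = 5,
                                                  nBootstrap = 3))
  expect_true(is.finite(m@validationLoss))
})
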