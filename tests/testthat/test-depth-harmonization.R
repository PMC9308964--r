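test_that("a single layer yields the constant spline at the observed value", {
  prof <- data.frame(top = 0, bottom = 30, value = 2.0)
  for (lambda in c(0, 0.1, 10)) {
    fit <- fitEqualAreaSpline(prof, lambda)
    expect_equal(depthAverage(fit, 0, 30), 2.0, tolerance = 1e-8)
    expect_equal(socpotential:::.splineValue(fit, c(0, 7.3, 15, 29.9)),
                 rep(2.0, 4), tolerance = 1e-6)
  }
})

test_that("equal observed values give a constant fit", {
  prof <- data.frame(top = c(0, 10), bottom = c(10, 30), value = c(3.0, 3.0))
  fit <- fitEqualAreaSpline(prof, 0.1)
  expect_equal(socpotential:::.splineValue(fit, seq(0, 30, 1)), rep(3.0, 31),
               tolerance = 1e-6)
})

test_that("layer means converge to observations as lambda shrinks", {
  prof <- data.frame(top = c(0, 10), bottom = c(10, 30), value = c(4.0, 1.0))
  layerMean <- function(fit, top, bottom) depthAverage(fit, top, bottom)
  errAt <- function(lambda) {
    fit <- fitEqualAreaSpline(prof, lambda)
    max(abs(c(layerMean(fit, 0, 10) - 4, layerMean(fit, 10, 30) - 1)))
  }
  e <- vapply(c(1e-1, 1e-3, 1e-6), errAt, numeric(1))
  expect_true(all(diff(e) < 0))  # strictly improving fidelity
  expect_lt(e[3], 1e-3)          # near-interpolation of layer means
})

test_that("the analytic fit matches the discretized QP oracle", {
  profiles <- list(
    data.frame(top = c(0, 10), bottom = c(10, 30), value = c(4.0, 1.0)),
    data.frame(top = c(0, 5, 15, 30), bottom = c(5, 15, 30, 60),
               value = c(5.2, 3.1, 1.4, 0.6)),
    data.frame(top = c(0, 20), bottom = c(10, 40), value = c(2.5, 1.0)),  # gap
    data.frame(top = c(0, 10, 30), bottom = c(10, 30, 100),
               value = c(3.8, 2.0, 0.4))
  )
  for (prof in profiles) {
    for (lambda in c(0.01, 0.1)) {
      fit <- fitEqualAreaSpline(prof, lambda)
      oracle <- qpSplineOracle(prof, lambda, h = 0.05)
      grid <- seq(min(prof$top) + 1, max(prof$bottom) - 1, by = 1)
      expect_lt(max(abs(socpotential:::.splineValue(fit, grid) - oracle(grid))),
                1e-3)
    }
  }
})

test_that("adding a constant to all layers shifts the 0-30 cm value exactly", {
  prof <- data.frame(top = c(0, 5, 15), bottom = c(5, 15, 30),
                     value = c(4.1, 2.2, 1.3))
  fit0 <- fitEqualAreaSpline(prof, 0.1)
  profC <- transform(prof, value = value + 2.5)
  fitC <- fitEqualAreaSpline(profC, 0.1)
  expect_equal(depthAverage(fitC, 0, 30), depthAverage(fit0, 0, 30) + 2.5,
               tolerance = 1e-9)
})

test_that("malformed profiles are rejected", {
  expect_error(fitEqualAreaSpline(data.frame(top = numeric(),
                                             bottom = numeric(),
                                             value = numeric())), "no layers")
  expect_error(fitEqualAreaSpline(data.frame(top = c(0, 5),
                                             bottom = c(10, 20),
                                             value = c(1, 2))), "overlap")
  fit <- fitEqualAreaSpline(data.frame(top = 0, bottom = 30, value = 1), 0.1)
  expect_error(depthAverage(fit, 20, 10), "top < bottom")
})

test_that("harmonization filters shallow profiles and recovers the truth", {
  cfg <- syntheticConfig(nSites = 100, seed = 21)
  sites <- generateSites(cfg)
  prof <- generateProfiles(sites, layersPerSite = 4, seed = 2)
  harm <- harmonizeDataset(prof, lambda = 0.1)
  expect_equal(nrow(harm), 100)
  expect_equal(attr(harm, "report")[["dropped"]], 0)
  merged <- merge(harm, sites[, c("site_id", "soc_pct")], by = "site_id",
                  suffixes = c("", "_true"))
  relErr <- abs(merged$soc_pct - merged$soc_pct_true) / merged$soc_pct_true
  expect_lt(median(relErr), 0.05)
})

test_that("profiles shallower than the depth rule are dropped and counted", {
  layers <- rbind(
    data.frame(site_id = "deep", top = c(0, 10), bottom = c(10, 30),
               value = c(3, 1)),
    data.frame(site_id = "shallow", top = 0, bottom = 10, value = 5)
  )
  prof <- new("SoilProfileSet", layers = layers, sites = data.frame())
  harm <- harmonizeDataset(prof, minDepth = 20)
  expect_equal(harm$site_id, "deep")
  expect_equal(attr(harm, "report"),
               c(retained = 1L, dropped = 1L))
})
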