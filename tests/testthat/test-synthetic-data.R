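test_that("site generation is deterministic and respects the config", {
  cfg <- syntheticConfig(nSites = 500, seed = 7)
  a <- generateSites(cfg)
  b <- generateSites(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_true(all(a$soc_pct >= 0))
  expect_true(all(a$landcover %in% LANDCOVER_LEVELS))
  expect_true(all(a$mat >= -10 & a$mat <= 30))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(nSites = 0), "nSites")
  expect_error(syntheticConfig(landcoverProbs = c(0.5, 0.4, 0.2)), "summing")
  expect_error(syntheticConfig(sigmaLog = 0), "sigmaLog")
  expect_error(syntheticConfig(matRange = c(5, 5)), "interval")
})

test_that("true quantiles strictly increase in tau and match the median law", {
  cfg <- syntheticConfig(nSites = 200, seed = 3)
  sites <- generateSites(cfg)
  q50 <- trueQuantile(sites, 0.5, cfg)
  q75 <- trueQuantile(sites, 0.75, cfg)
  q90 <- trueQuantile(sites, 0.9, cfg)
  expect_true(all(q75 > q50))
  expect_true(all(q90 > q75))
  # the median of a lognormal does not depend on its scale parameter
  cfgWide <- syntheticConfig(nSites = 200, seed = 3, sigmaLog = 1.5)
  expect_equal(q50, trueQuantile(sites, 0.5, cfgWide))
  # degenerate-dispersion limit: all quantiles collapse onto exp(mu)
  cfgTight <- syntheticConfig(nSites = 200, seed = 3, sigmaLog = 1e-9,
                              sigmaMult = c(1, 1, 1))
  expect_equal(trueQuantile(sites, 0.25, cfgTight),
               trueQuantile(sites, 0.95, cfgTight), tolerance = 1e-6)
  expect_error(trueQuantile(sites, 1.2, cfg), "tau")
})

test_that("generated SOC is consistent with the closed-form quantiles", {
  cfg <- syntheticConfig(nSites = 100000, seed = 19)
  sites <- generateSites(cfg)
  # over the whole sample the fraction below the per-site true tau-quantile
  # must be tau; this exercises generator and oracle through different paths
  for (tau in c(0.25, 0.5, 0.75, 0.9, 0.95)) {
    frac <- mean(sites$soc_pct <= trueQuantile(sites, tau, cfg))
    expect_equal(frac, tau, tolerance = 0.02)
  }
})

test_that("true quantile matches a Monte-Carlo draw at a fixed site", {
  cfg <- syntheticConfig(nSites = 10, seed = 5)
  site <- generateSites(cfg)[1, ]
  # independent reconstruction of the documented location/scale
  zs <- function(x, r) (x - mean(r)) / (diff(r) / 4)
  mu <- cfg@mu0 + cfg@effectWeights[["mat"]] * zs(site$mat, cfg@matRange) +
    cfg@effectWeights[["tap"]] * zs(site$tap, cfg@tapRange) +
    cfg@effectWeights[["elevation"]] * zs(site$elevation, cfg@elevRange) +
    cfg@landcoverOffsets[[site$landcover]]
  sigma <- cfg@sigmaLog * cfg@sigmaMult[[site$landcover]]
  set.seed(99)
  draws <- exp(mu + sigma * rnorm(1e6))
  expect_equal(trueQuantile(site, 0.9, cfg),
               unname(quantile(draws, 0.9)), tolerance = 0.01)
  expect_equal(trueQuantile(site, 0.5, cfg), exp(mu), tolerance = 1e-12)
})

test_that("upper quantiles under pasture and forest exceed cropland's", {
  cfg <- syntheticConfig(nSites = 50, seed = 2)
  sites <- generateSites(cfg)
  for (tau in c(0.75, 0.9)) {
    crop <- trueQuantile(transform(sites, landcover = "cropland"), tau, cfg)
    past <- trueQuantile(transform(sites, landcover = "pasture_natural"), tau, cfg)
    forst <- trueQuantile(transform(sites, landcover = "forest"), tau, cfg)
    expect_true(all(past > crop))
    expect_true(all(forst > crop))
  }
})

test_that("profiles partition depth and preserve the 0-30 cm mean", {
  cfg <- syntheticConfig(nSites = 120, seed = 13)
  sites <- generateSites(cfg)
  prof <- generateProfiles(sites, layersPerSite = 4, seed = 1)
  layers <- profileLayers(prof)
  for (p in split(layers, layers$site_id)) {
    p <- p[order(p$top), ]
    expect_equal(p$top[1], 0)
    expect_equal(p$top[-1], p$bottom[-nrow(p)])  # contiguous, no overlap
    expect_true(30 %in% c(p$top, p$bottom))
  }
  # depth-weighted 0-30 cm mean of the layer values recovers the site truth
  truth <- setNames(sites$soc_pct, sites$site_id)
  for (p in split(layers, layers$site_id)) {
    w <- pmax(pmin(p$bottom, 30) - pmin(p$top, 30), 0)
    expect_equal(sum(p$value * w) / 30, unname(truth[p$site_id[1]]),
                 tolerance = 1e-6)
  }
})

test_that("single-layer profiles are exactly the 0-30 cm value", {
  cfg <- syntheticConfig(nSites = 20, seed = 4)
  sites <- generateSites(cfg)
  prof <- generateProfiles(sites, layersPerSite = 1, seed = 1)
  layers <- profileLayers(prof)
  expect_equal(layers$top, rep(0, 20))
  expect_equal(layers$bottom, rep(30, 20))
  expect_equal(layers$value, sites$soc_pct)
})

test_that("bulk-density pairs sit on the curve and carry calibrated noise", {
  exact <- generateBdPairs(200, noiseSd = 0, seed = 1)
  expect_equal(exact$bd_gcm3, evaluatePtf(exact$oc_gkg), tolerance = 1e-12)
  expect_lt(min(exact$oc_gkg), 5)
  expect_gt(max(exact$oc_gkg), 145)
  noisy <- generateBdPairs(5000, noiseSd = 0.25, seed = 2)
  sampleRmse <- sqrt(mean((noisy$bd_gcm3 - evaluatePtf(noisy$oc_gkg))^2))
  expect_equal(sampleRmse, 0.25, tolerance = 0.1)
  expect_error(generateBdPairs(5), "10")
  expect_error(generateBdPairs(100, noiseSd = -1), "noiseSd")
})

test_that("covariate grids are reproducible, in range, and work at 1 cell", {
  cfg <- syntheticConfig(nSites = 10, seed = 1)
  g1 <- generateGrid(16, 12, cfg, seed = 8)
  g2 <- generateGrid(16, 12, cfg, seed = 8)
  expect_identical(gridTable(g1), gridTable(g2))
  expect_true(all(g1@mat >= cfg@matRange[1] & g1@mat <= cfg@matRange[2]))
  expect_true(all(g1@tap >= cfg@tapRange[1] & g1@tap <= cfg@tapRange[2]))
  expect_true(all(g1@landcover %in% LANDCOVER_LEVELS))
  expect_equal(length(g1), 192L)
  single <- generateGrid(1, 1, cfg, seed = 3)
  expect_equal(nrow(gridTable(single)), 1)
})

test_that("grids round-trip through the CSV dialect", {
  g <- generateGrid(7, 5, syntheticConfig(nSites = 10, seed = 1), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeGridCsv(g, path)
  g2 <- readGridCsv(path)
  expect_equal(gridTable(g2), gridTable(g), tolerance = 1e-12)
})
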