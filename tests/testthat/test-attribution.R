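set.seed(123)
.bg4 <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60),
                   x4 = rnorm(60))
.w4 <- c(2, -1, 0.5, 3)
.lin4 <- function(df) as.matrix(df[, c("x1", "x2", "x3", "x4")]) %*% .w4
.inst4 <- data.frame(x1 = 1.2, x2 = -0.4, x3 = 2.0, x4 = 0.3)

test_that("a constant model receives zero contributions", {
  att <- shapleySample(function(df) rep(7, nrow(df)), .inst4, .bg4,
                       features = paste0("x", 1:4), nPermutations = 50)
  expect_equal(unname(att$contributions[, 1]), rep(0, 4))
  expect_equal(unname(att$baseValue), 7)
})

test_that("linear-model attributions match the closed form and enumeration", {
  att <- shapleySample(.lin4, .inst4, .bg4, features = paste0("x", 1:4),
                       nPermutations = 2000, seed = 5)
  closedForm <- .w4 * (as.numeric(.inst4) - colMeans(.bg4))
  enumerated <- exactShapley(function(df) as.numeric(.lin4(df)), .inst4, .bg4,
                             paste0("x", 1:4))
  # for a linear model the exact Shapley value is the closed form...
  expect_equal(unname(enumerated), unname(closedForm), tolerance = 1e-10)
  # ...and the sampled estimate agrees within Monte-Carlo error
  err <- abs(att$contributions[, 1] - enumerated)
  expect_true(all(err <= pmax(3 * att$se[, 1], 1e-10)))
})

test_that("local accuracy holds within sampling error", {
  att <- shapleySample(.lin4, .inst4, .bg4, features = paste0("x", 1:4),
                       nPermutations = 2000, seed = 9)
  gap <- att$baseValue + sum(att$contributions[, 1]) - att$prediction
  expect_lt(abs(gap), 3 * sqrt(sum(att$se[, 1]^2)) + 1e-10)
})

test_that("symmetric covariates receive equal contributions", {
  set.seed(7)
  bg <- data.frame(x1 = rnorm(80))
  bg$x2 <- bg$x1  # identical background columns
  f <- function(df) df$x1 + df$x2
  att <- shapleySample(f, data.frame(x1 = 1.5, x2 = 1.5), bg,
                       features = c("x1", "x2"), nPermutations = 1500, seed = 2)
  expect_equal(att$contributions["x1", 1], att$contributions["x2", 1],
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("attribution is seed-deterministic", {
  a <- shapleySample(.lin4, .inst4, .bg4, features = paste0("x", 1:4),
                     nPermutations = 100, seed = 11)
  b <- shapleySample(.lin4, .inst4, .bg4, features = paste0("x", 1:4),
                     nPermutations = 100, seed = 11)
  expect_identical(a$contributions, b$contributions)
})

test_that("errors on empty background and unknown features", {
  expect_error(shapleySample(.lin4, .inst4, .bg4[0, ]), "non-empty")
  expect_error(shapleySample(.lin4, .inst4, .bg4, features = "zz"),
               "mismatch")
})

test_that("contribution percent change normalizes head growth", {
  long <- data.frame(
    instance = rep(1:10, each = 4),
    covariate = rep(c("mat", "tap", "elevation", "landcover"), 10),
    percentile = "q50",
    contribution = rep(c(1, 2, 0.5, 0.25), 10))
  doubled <- transform(long, percentile = "q75",
                       contribution = contribution * 2)
  both <- rbind(long, doubled)
  ch <- contributionChange(both, "q50", "q75")
  expect_equal(unname(ch), rep(100, 4))
  same <- rbind(long, transform(long, percentile = "q75"))
  expect_equal(unname(contributionChange(same, "q50", "q75")), rep(0, 4))
  zero <- transform(long, contribution = 0)
  expect_error(contributionChange(rbind(zero, doubled), "q50", "q75"), "zero")
})

test_that("the model's land-cover influence grows toward upper percentiles", {
  m <- sharedModel()
  pool <- generateSites(syntheticConfig(nSites = 400, seed = 55))
  inst <- pool[1:12, ]
  bg <- pool[101:180, ]
  long <- attributeDataset(m, inst, bg, nPermutations = 80, seed = 8)
  ch <- contributionChange(long, "q50", "q90")
  expect_gt(ch[["landcover"]], 0)
  # by construction the land-cover effect widens with the percentile faster
  # than the (homoscedastic-in-log) climate effects
  expect_gt(ch[["landcover"]], ch[["mat"]])
  expect_gt(ch[["landcover"]], ch[["tap"]])
})

test_that("temperature tagging uses the 10 / 17.5 degree thresholds", {
  expect_equal(temperatureGroups(c(-5, 10, 15, 17.5, 25)),
               c("cold", "intermediate", "intermediate", "warm", "warm"))
})
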