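#' @include socpotential-package.R
NULL

#' Configuration of the synthetic soil-landscape generator
#'
#' Parameters of the data-generating process that stands in for the global
#' soil databases. SOC at a site is lognormal: log SOC has location
#' \eqn{\mu(x) = \mu_0 + w \cdot z(x) + \delta_{lc}} where \eqn{z(x)} are
#' covariates standardized to the configured ranges, \eqn{\delta_{lc}} a
#' land-cover offset, and scale \eqn{\sigma_{lc} = \sigma \cdot m_{lc}}.
#' Because the conditional law is fully parametric, every conditional quantile
#' is available in closed form (see [trueQuantile()]), which downstream model
#' tests use as ground truth.
#'
#' @slot nSites number of sites to generate
#' @slot seed integer seed governing all draws
#' @slot matRange,tapRange,elevRange ranges of mean annual temperature
#'   (degrees C), total annual precipitation (mm) and elevation (m)
#' @slot landcoverProbs probabilities of the three land-cover groups
#' @slot sigmaLog baseline dispersion of log-SOC
#' @slot sigmaMult per-land-cover multiplier of `sigmaLog`; values above 1 for
#'   pasture/forest widen their upper quantiles, so the land-cover influence
#'   grows with the percentile
#' @slot effectWeights coefficients of the standardized covariates in
#'   \eqn{\mu(x)}: negative for temperature (faster turnover), positive for
#'   precipitation and elevation
#' @slot landcoverOffsets additive land-cover offsets in \eqn{\mu(x)};
#'   pasture/natural and forest sit above cropland
#' @slot mu0 baseline log-SOC (log percent) at range midpoints under cropland
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nSites = "integer", seed = "integer",
    matRange = "numeric", tapRange = "numeric", elevRange = "numeric",
    landcoverProbs = "numeric", sigmaLog = "numeric", sigmaMult = "numeric",
    effectWeights = "numeric", landcoverOffsets = "numeric", mu0 = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSites < 1L) msg <- c(msg, "nSites must be positive")
  for (r in c("matRange", "tapRange", "elevRange")) {
    v <- slot(object, r)
    if (length(v) != 2L || !(v[2] > v[1])) {
      msg <- c(msg, paste(r, "must be a non-degenerate (lo, hi) interval"))
    }
  }
  if (length(object@landcoverProbs) != 3L ||
      abs(sum(object@landcoverProbs) - 1) > 1e-9 ||
      any(object@landcoverProbs < 0)) {
    msg <- c(msg, "landcoverProbs must be 3 nonnegative values summing to 1")
  }
  if (object@sigmaLog <= 0) msg <- c(msg, "sigmaLog must be > 0")
  if (length(object@sigmaMult) != 3L || any(object@sigmaMult <= 0)) {
    msg <- c(msg, "sigmaMult must be 3 positive multipliers")
  }
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-data configuration
#'
#' Defaults emulate the shape of the compiled global SOC databases: a median
#' cropland SOC near 1.5 percent at mid-range climate, right-skewed
#' heteroscedastic SOC, depth-decaying profiles, and three land-cover groups
#' whose upper quantiles (pasture/natural, forest) exceed cropland's.
#'
#' @param nSites positive number of sites
#' @param seed integer seed
#' @param matRange,tapRange,elevRange covariate ranges (degrees C, mm, m)
#' @param landcoverProbs probabilities over cropland, pasture_natural, forest
#' @param sigmaLog baseline log-SOC dispersion
#' @param sigmaMult per-land-cover dispersion multipliers
#' @param effectWeights named coefficients for mat, tap, elevation
#' @param landcoverOffsets named additive offsets on log-SOC
#' @param mu0 baseline log-SOC
#' @return a validated [SyntheticConfig-class] object
#' @examples
#' cfg <- syntheticConfig(nSites = 100, seed = 1)
#' @export
syntheticConfig <- function(nSites = 5000L, seed = 42L,
                            matRange = c(-10, 30), tapRange = c(50, 3000),
                            elevRange = c(0, 3000),
                            landcoverProbs = c(cropland = 0.4,
                                               pasture_natural = 0.35,
                                               forest = 0.25),
                            sigmaLog = 0.5,
                            sigmaMult = c(cropland = 1, pasture_natural = 1.1,
                                          forest = 1.2),
                            effectWeights = c(mat = -0.4, tap = 0.3,
                                              elevation = 0.1),
                            landcoverOffsets = c(cropland = 0,
                                                 pasture_natural = 0.25,
                                                 forest = 0.35),
                            mu0 = log(1.5)) {
  new("SyntheticConfig",
      nSites = as.integer(nSites), seed = as.integer(seed),
      matRange = matRange, tapRange = tapRange, elevRange = elevRange,
      landcoverProbs = setNames(as.numeric(landcoverProbs), LANDCOVER_LEVELS),
      sigmaLog = sigmaLog,
      sigmaMult = setNames(as.numeric(sigmaMult), LANDCOVER_LEVELS),
      effectWeights = effectWeights,
      landcoverOffsets = setNames(as.numeric(landcoverOffsets),
                                  LANDCOVER_LEVELS),
      mu0 = mu0)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nSites, "sites, seed", object@seed, "\n")
  cat("  MAT", paste(object@matRange, collapse = ".."), "degC; TAP",
      paste(object@tapRange, collapse = ".."), "mm; elev",
      paste(object@elevRange, collapse = ".."), "m\n")
  cat("  sigmaLog", object@sigmaLog, "; land-cover probs",
      paste(sprintf("%s=%.2f", names(object@landcoverProbs),
                    object@landcoverProbs), collapse = ", "), "\n")
})

# standardize a raw covariate to roughly [-2, 2] over its configured range;
# deterministic in x so the conditional quantiles stay closed-form
.zscale <- function(x, range) (x - mean(range)) / (diff(range) / 4)

# location and scale of log-SOC for covariate rows
.mu_sigma <- function(sites, config) {
  w <- config@effectWeights
  mu <- config@mu0 +
    w[["mat"]] * .zscale(sites$mat, config@matRange) +
    w[["tap"]] * .zscale(sites$tap, config@tapRange) +
    w[["elevation"]] * .zscale(sites$elevation, config@elevRange) +
    config@landcoverOffsets[as.character(sites$landcover)]
  sigma <- config@sigmaLog * config@sigmaMult[as.character(sites$landcover)]
  list(mu = unname(mu), sigma = unname(sigma))
}

#' Generate synthetic site observations
#'
#' Draws covariates uniformly over the configured ranges, assigns land cover
#' by the configured probabilities, and draws a 0-30 cm SOC concentration from
#' the lognormal conditional law. Identical config (including seed) yields
#' identical tables.
#'
#' @param config a [SyntheticConfig-class]
#' @return a data.frame with columns site_id, lon, lat, mat, tap, elevation,
#'   landcover, soc_pct, year
#' @examples
#' sites <- generateSites(syntheticConfig(nSites = 50, seed = 7))
#' @export
generateSites <- function(config) {
  validObject(config)
  n <- config@nSites
  set.seed(config@seed)
  sites <- data.frame(
    site_id = sprintf("site_%05d", seq_len(n)),
    lon = runif(n, -180, 180),
    lat = runif(n, -60, 75),
    mat = runif(n, config@matRange[1], config@matRange[2]),
    tap = runif(n, config@tapRange[1], config@tapRange[2]),
    elevation = runif(n, config@elevRange[1], config@elevRange[2]),
    landcover = sample(LANDCOVER_LEVELS, n, replace = TRUE,
                       prob = config@landcoverProbs),
    year = sample(1980:2020, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ms <- .mu_sigma(sites, config)
  sites$soc_pct <- exp(ms$mu + ms$sigma * rnorm(n))
  sites
}

#' Closed-form conditional SOC quantile of the generator
#'
#' The analytic oracle: under the generating lognormal law the tau-quantile at
#' covariates x is \eqn{\exp(\mu(x) + \sigma_{lc} z_\tau)}.
#'
#' @param sites data.frame of covariate rows (mat, tap, elevation, landcover)
#' @param tau probability in (0, 1)
#' @param config the [SyntheticConfig-class] that generated (or would
#'   generate) the sites
#' @return numeric vector of SOC concentrations (percent mass)
#' @export
trueQuantile <- function(sites, tau, config) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must be a single probability in (0, 1)")
  }
  ms <- .mu_sigma(sites, config)
  exp(ms$mu + ms$sigma * qnorm(tau))
}

#' Generate layered soil profiles from site values
#'
#' Each site's 0-30 cm SOC value is expanded into a depth profile following an
#' exponential decay \eqn{f(d) = A e^{-kd}} scaled so the 0-30 cm mean of f
#' equals the site's soc_pct exactly. Layer values are exact layer means of f.
#' With one layer per site the single layer is 0-30 cm; with more, the 0-100
#' cm column is partitioned with a boundary fixed at 30 cm so the stored truth
#' is recoverable by depth-weighted averaging.
#'
#' @param sites data.frame from [generateSites()]
#' @param layersPerSite layers per profile (>= 1)
#' @param seed integer seed for the random layer boundaries
#' @param decayRate exponential decay rate k (per cm), default 0.03
#' @return a [SoilProfileSet-class]
#' @export
generateProfiles <- function(sites, layersPerSite = 4L, seed = 42L,
                             decayRate = 0.03) {
  layersPerSite <- as.integer(layersPerSite)
  if (layersPerSite < 1L) stop("layersPerSite must be >= 1")
  set.seed(seed)
  k <- decayRate
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    soc <- sites$soc_pct[i]
    # A such that (1/30) * int_0^30 A e^{-kd} dd = soc
    A <- soc * 30 * k / (1 - exp(-30 * k))
    if (layersPerSite == 1L) {
      bounds <- c(0, 30)
    } else {
      nTop <- max(1L, min(layersPerSite - 1L, round(layersPerSite * 0.4)))
      nBot <- layersPerSite - nTop
      topCuts <- if (nTop > 1L) sort(sample(seq(5, 25, by = 5), nTop - 1L)) else numeric()
      botCuts <- if (nBot > 1L) sort(sample(seq(40, 90, by = 10), nBot - 1L)) else numeric()
      bounds <- c(0, topCuts, 30, botCuts, if (nBot > 0L) 100)
    }
    top <- bounds[-length(bounds)]
    bottom <- bounds[-1]
    # exact layer means of A e^{-kd}
    val <- A * (exp(-k * top) - exp(-k * bottom)) / (k * (bottom - top))
    out[[i]] <- data.frame(site_id = sites$site_id[i], top = top,
                           bottom = bottom, value = val,
                           stringsAsFactors = FALSE)
  }
  new("SoilProfileSet", layers = do.call(rbind, out), sites = sites)
}

#' Generate (SOC, bulk density) calibration pairs
#'
#' Pairs lie on the rational bulk-density pedotransfer curve plus Gaussian
#' noise, truncated below at 0.05 g/cm^3. SOC values are stratified over
#' 0-150 g/kg so the rational fit is identifiable.
#'
#' @param n number of pairs (>= 10)
#' @param noiseSd Gaussian noise standard deviation (g/cm^3)
#' @param seed integer seed
#' @param coeffs generating curve, default the packaged [ptfCoefficients()]
#' @param ocMax upper end of the SOC span (g/kg), default 150
#' @return data.frame with columns oc_gkg, bd_gcm3
#' @export
generateBdPairs <- function(n, noiseSd = 0.1, seed = 42L,
                            coeffs = ptfCoefficients(), ocMax = 150) {
  if (n < 10) stop("need at least 10 pairs")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  set.seed(seed)
  # stratified draw guarantees the span
  oc <- (seq_len(n) - runif(n)) / n * ocMax
  bd <- evaluatePtf(oc, coeffs) + rnorm(n, 0, noiseSd)
  data.frame(oc_gkg = oc, bd_gcm3 = pmax(bd, 0.05))
}
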