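#' @include socpotential-package.R
NULL

#' End-to-end pipeline configuration
#'
#' One seed governs the whole run; stage seeds are derived from it by fixed
#' offsets so stages stay individually reproducible.
#'
#' @param nSites sites for the synthetic survey
#' @param nx,ny prediction grid dimensions
#' @param seed master seed
#' @param layersPerSite profile layers per site
#' @param lambda spline smoothing weight
#' @param nBdPairs,bdNoiseSd bulk-density calibration sample
#' @param epochs,batchSize,learningRate,testFraction network training settings
#' @param nAttributionInstances instances explained in the attribution stage
#' @param config optional [SyntheticConfig-class] overriding the generator
#'   defaults (its nSites/seed are replaced by the run's)
#' @return a list with class "pipelineConfig"
#' @export
pipelineConfig <- function(nSites = 5000L, nx = 32L, ny = 32L, seed = 42L,
                           layersPerSite = 4L, lambda = 0.1,
                           nBdPairs = 2000L, bdNoiseSd = 0.25,
                           epochs = 100L, batchSize = 32L,
                           learningRate = 0.001, testFraction = 0.05,
                           nAttributionInstances = 20L, config = NULL) {
  structure(list(nSites = as.integer(nSites), nx = as.integer(nx),
                 ny = as.integer(ny), seed = as.integer(seed),
                 layersPerSite = as.integer(layersPerSite), lambda = lambda,
                 nBdPairs = as.integer(nBdPairs), bdNoiseSd = bdNoiseSd,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, testFraction = testFraction,
                 nAttributionInstances = as.integer(nAttributionInstances),
                 config = config),
            class = "pipelineConfig")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in dependency order: generate sites and profiles,
#' harmonize to 0-30 cm, fit the bulk-density pedotransfer on noisy pairs,
#' train the quantile network, predict over a covariate grid, aggregate
#' stocks and potentials by zone, run the 4-per-mille / debt / climate
#' scenarios (+2 degrees C uniform warming for the sensitivity stage), and
#' attribute a subsample of predictions. If `dir` is given, stage artifacts
#' (CSV tables and a JSON summary) are written there.
#'
#' @param config a [pipelineConfig()]
#' @param dir optional output directory for artifacts
#' @param verbose print stage progress
#' @return list with the per-stage artifacts and a `summary` list holding the
#'   headline numbers (global stocks, potentials, median years, debt range,
#'   climate percent change)
#' @export
runPipeline <- function(config = pipelineConfig(), dir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  gen <- config$config
  if (is.null(gen)) gen <- syntheticConfig(nSites = config$nSites, seed = seed)
  else { gen@nSites <- config$nSites; gen@seed <- seed; validObject(gen) }

  say("stage synth: ", config$nSites, " sites")
  sites <- generateSites(gen)
  profiles <- generateProfiles(sites, config$layersPerSite, seed = seed + 1L)

  say("stage harmonize")
  harmonized <- harmonizeDataset(profiles, lambda = config$lambda)

  say("stage fit-ptf")
  bdPairs <- generateBdPairs(config$nBdPairs, config$bdNoiseSd,
                             seed = seed + 2L)
  ptf <- fitPtf(bdPairs, seed = seed + 3L)

  say("stage train")
  model <- trainQuantileModel(
    harmonized, modelSpec(),
    trainingConfig(epochs = config$epochs, batchSize = config$batchSize,
                   learningRate = config$learningRate,
                   testFraction = config$testFraction, seed = seed + 4L))

  say("stage predict: ", config$nx, "x", config$ny, " grid")
  grid <- generateGrid(config$nx, config$ny, gen, seed = seed + 5L)
  cells <- gridTable(grid)
  quantiles <- predictQuantiles(model, grid)

  say("stage stocks")
  cropMask <- cells$landcover == "cropland"
  report <- additionalPotential(
    aggregateStocks(quantiles, cells$area_km2, cells$zone, mask = cropMask,
                    coeffs = ptf$coefficients))
  globalRow <- report[report$zone == "Global", ]

  say("stage scenarios")
  s0 <- .stockFromConcentration(quantiles$q50[cropMask], ptf$coefficients)
  s75 <- .stockFromConcentration(quantiles$q75[cropMask], ptf$coefficients)
  s90 <- .stockFromConcentration(quantiles$q90[cropMask], ptf$coefficients)
  years75 <- suppressWarnings(yearsToTarget(s0, s75))
  years90 <- suppressWarnings(yearsToTarget(s0, s90))
  debt <- substitutionDebt(model, grid, coeffs = ptf$coefficients)
  climate <- climateProjection(model, grid, grid@mat + 2, grid@tap,
                               mask = cropMask, coeffs = ptf$coefficients)

  say("stage attribute")
  nAttr <- min(config$nAttributionInstances, nrow(harmonized))
  set.seed(seed + 6L)
  inst <- harmonized[sample.int(nrow(harmonized), nAttr), , drop = FALSE]
  bg <- harmonized[sample.int(nrow(harmonized), min(100L, nrow(harmonized))), ,
                   drop = FALSE]
  attributions <- attributeDataset(model, inst, bg, nPermutations = 50L,
                                   seed = seed + 7L)

  summary <- list(
    n_sites = config$nSites,
    n_harmonized = nrow(harmonized),
    ptf_rmse_gcm3 = ptf$rmse,
    rmse_q50_pct = rmseQ50(model),
    global_q50_pg = globalRow$q50_pg,
    global_q75_pg = globalRow$q75_pg,
    global_q90_pg = globalRow$q90_pg,
    pot_intermediate_pg = globalRow$pot_intermediate,
    pot_maximum_pg = globalRow$pot_maximum,
    median_years_q75 = unname(median(years75)),
    median_years_q90 = unname(median(years90)),
    debt_range_pg = debt$range,
    debt_mean_pg = debt$mean,
    climate_percent_change = climate$percent_change
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeSiteCsv(harmonized, file.path(dir, "harmonized.csv"))
    writeGridCsv(grid, file.path(dir, "grid.csv"))
    write.csv(cbind(cells, quantiles), file.path(dir, "quantiles.csv"),
              row.names = FALSE)
    write.csv(report, file.path(dir, "zone_report.csv"), row.names = FALSE)
    write.csv(attributions, file.path(dir, "attributions.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(sites = sites, harmonized = harmonized, ptf = ptf, model = model,
       grid = grid, quantiles = quantiles, report = report,
       debt = debt, climate = climate, attributions = attributions,
       summary = summary)
}

#' Verify the published in-table arithmetic
#'
#' Recomputes, from the packaged ecoregion stock table and the published
#' premises, every derived headline number: global stocks and potentials, the
#' two-ecoregion share, the 4-per-mille capture rate and its emission share,
#' the fractional-loss debt bounds, the substitution-debt midpoint, and the
#' recoup percentages. Returns computed next to printed values; the computed
#' column is produced entirely by the package's accounting functions.
#'
#' @param path optional alternative stock table (see [readTable1()])
#' @param medianYearsQ75 published median years to the 75th percentile under
#'   4 per mille (an input, not recomputable without the global maps)
#' @return data.frame: quantity, computed, printed
#' @export
reportTable1Arithmetic <- function(path = NULL, medianYearsQ75 = 86) {
  tbl <- readTable1(path)
  report <- additionalPotential(tbl)
  zones <- report$zone[report$zone != "Global"]
  glob <- report[report$zone == "Global", ]

  temperate <- c("Temperate broadleaf and mixed forests",
                 "Temperate grasslands, savannas and shrublands")
  sh75 <- zoneShare(report, temperate, "intermediate")
  capture <- averageCaptureRate(glob$pot_intermediate, medianYearsQ75)
  lossDebt <- boundedDebtFromLossFraction(62, 0.25, 0.75)
  midpoint <- mean(c(10, 160))

  rows <- rbind(
    c("zone q50 sum (Pg)", sum(report$q50_pg[report$zone != "Global"]), 82.68),
    c("global stock q50 (Pg)", glob$q50_pg, 83),
    c("potential q75 - q50 (Pg)", glob$pot_intermediate, 29),
    c("potential q90 - q50 (Pg)", glob$pot_maximum, 65),
    c("two temperate ecoregions, potential (Pg)", sh75$potential_pg, 17.2),
    c("two temperate ecoregions, share (%)", sh75$share * 100, 59),
    c("capture rate (Pg/yr)", capture$rate_pg_yr, 0.34),
    c("capture share of 8.9 Pg/yr emissions (%)",
      capture$emission_share * 100, 4),
    c("pre-agriculture stock, 25% loss (Pg)", lossDebt$pre_pg[1], 83),
    c("pre-agriculture stock, 75% loss (Pg)", lossDebt$pre_pg[2], 248),
    c("fractional-loss debt, low (Pg)", lossDebt$debt_pg[1], 21),
    c("fractional-loss debt, high (Pg)", lossDebt$debt_pg[2], 186),
    c("substitution-debt midpoint of (10, 160) (Pg)", midpoint, 85),
    c("recoup of 85 Pg debt at q75 (%)", glob$pot_intermediate / 85 * 100, 35),
    c("recoup of 92 Pg debt at q75 (%)", glob$pot_intermediate / 92 * 100, 32),
    c("recoup of 92 Pg debt at q90 (%)", glob$pot_maximum / 92 * 100, 72)
  )
  data.frame(quantity = rows[, 1], computed = as.numeric(rows[, 2]),
             printed = as.numeric(rows[, 3]), stringsAsFactors = FALSE)
}
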