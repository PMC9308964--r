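#' @include socpotential-package.R
NULL

#' Years to reach a target stock under linear 4-per-mille accumulation
#'
#' With a fixed annual gain of `rate` times the baseline stock (linear
#' accumulation), reaching target stock st from baseline s0 takes
#' \eqn{(st/s0 - 1)/rate} years. Cells whose target lies below the baseline
#' (negative potential) are reported as 0 years; their count is attached as
#' attribute `n_negative` and a warning is raised.
#'
#' @param s0 baseline stock(s), must be positive
#' @param st target stock(s)
#' @param rate annual accumulation rate as a fraction of the baseline,
#'   default 0.004 (4 per mille)
#' @return years (vectorized), same length as the inputs
#' @examples
#' yearsToTarget(1, 2)  # 250 years at 4 per mille
#' @export
yearsToTarget <- function(s0, st, rate = 0.004) {
  if (rate <= 0) stop("rate must be positive")
  if (any(s0 <= 0)) stop("baseline stocks must be positive")
  years <- (st / s0 - 1) / rate
  nNeg <- sum(years < 0)
  if (nNeg > 0) {
    warning(nNeg, " cell(s) with target below baseline set to 0 years")
    years[years < 0] <- 0
  }
  attr(years, "n_negative") <- nNeg
  years
}

#' Summarize a map of years-to-target
#'
#' @param years vector from [yearsToTarget()]
#' @return named vector: median and quartiles (years)
#' @export
yearsSummary <- function(years) {
  q <- quantile(years, c(0.25, 0.5, 0.75))
  c(q25 = unname(q[1]), median = unname(q[2]), q75 = unname(q[3]))
}

#' Average carbon capture rate and emission share
#'
#' Total added carbon divided by the accumulation period, with the companion
#' share of a reference annual emission (default 8.9 Pg C/yr, the emission
#' figure behind the 4-per-mille rate).
#'
#' @param totalAdded carbon added over the period, Pg C
#' @param years accumulation period, yr (> 0)
#' @param referenceEmissions annual reference emissions, Pg C/yr
#' @return list with `rate_pg_yr` and `emission_share` (fraction)
#' @export
averageCaptureRate <- function(totalAdded, years, referenceEmissions = 8.9) {
  if (years <= 0) stop("years must be positive")
  rate <- totalAdded / years
  list(rate_pg_yr = rate, emission_share = rate / referenceEmissions)
}

#' Historical carbon debt by land-cover substitution
#'
#' Predicts the cropland cells of a grid twice more, once as pasture/natural
#' at the median and once as forest at the 90th percentile, and totals the
#' stock difference to the current cropland median. The two substitutions
#' bound a debt range whose mean is the headline debt estimate. Differences
#' are totalled signed by default (cells where cropland out-stocks the
#' replacement subtract); set `clipNegative` for per-cell positive parts.
#'
#' @param model a [QuantileModel-class]; pooled mode, or per-cover mode with
#'   all three groups fitted
#' @param grid a [CovariateGrid-class]
#' @param mask optional logical per-cell cropland mask; default: cells whose
#'   land cover is cropland
#' @param coeffs pedotransfer coefficients for the stock conversion
#' @param clipNegative if TRUE, negative per-cell differences are clipped to 0
#' @return list with `debt_pasture_q50_pg`, `debt_forest_q90_pg`, `range`
#'   (sorted), and `mean` (the debt midpoint), all Pg C
#' @export
substitutionDebt <- function(model, grid, mask = NULL,
                             coeffs = ptfCoefficients(),
                             clipNegative = FALSE) {
  if (model@mode == "per_landcover" &&
      !all(LANDCOVER_LEVELS %in% names(model@perCover))) {
    stop("per-cover model lacks one of the three land-cover groups")
  }
  cells <- gridTable(grid)
  if (is.null(mask)) mask <- cells$landcover == "cropland"
  crop <- cells[mask, , drop = FALSE]
  if (!nrow(crop)) stop("no cropland cells under the mask")
  base <- predictQuantiles(model, crop, landcover = "cropland")
  pasture <- predictQuantiles(model, crop, landcover = "pasture_natural")
  forest <- predictQuantiles(model, crop, landcover = "forest")
  toPg <- function(ocPct) {
    sum(.stockFromConcentration(ocPct, coeffs) * crop$area_km2) * 1e-6
  }
  diffPg <- function(repl, cur) {
    d <- .stockFromConcentration(repl, coeffs) -
      .stockFromConcentration(cur, coeffs)
    if (clipNegative) d <- pmax(d, 0)
    sum(d * crop$area_km2) * 1e-6
  }
  debtA <- diffPg(pasture$q50, base$q50)
  debtB <- diffPg(forest$q90, base$q50)
  rng <- sort(c(debtA, debtB))
  list(debt_pasture_q50_pg = debtA, debt_forest_q90_pg = debtB,
       range = rng, mean = mean(rng), current_q50_pg = toPg(base$q50))
}

#' Debt range implied by a fractional-loss premise
#'
#' If cultivated soils hold between `lossLow` and `lossHigh` less SOC than
#' their natural counterparts, a current stock C implies a pre-agriculture
#' stock C/(1 - loss) and a debt of the difference, at each bound.
#'
#' @param current current stock, Pg C
#' @param lossLow,lossHigh loss fractions, 0 < low <= high < 1
#' @return data.frame with rows low/high and columns loss, pre_pg, debt_pg
#' @examples
#' boundedDebtFromLossFraction(62, 0.25, 0.75)
#' @export
boundedDebtFromLossFraction <- function(current, lossLow = 0.25,
                                        lossHigh = 0.75) {
  if (lossLow <= 0 || lossHigh >= 1 || lossLow > lossHigh) {
    stop("need 0 < lossLow <= lossHigh < 1")
  }
  loss <- c(low = lossLow, high = lossHigh)
  pre <- current / (1 - loss)
  data.frame(bound = names(loss), loss = unname(loss), pre_pg = unname(pre),
             debt_pg = unname(pre - current), stringsAsFactors = FALSE)
}

#' Re-predict stocks and potentials under a replaced climate
#'
#' Swaps the grid's MAT/TAP layers for projected ones, re-runs the model, and
#' reports the percent reduction \eqn{(baseline - projected)/baseline \times
#' 100} of the q50 stock and of the intermediate (q75 - q50) and maximum
#' (q90 - q50) potentials, totalled over the (optionally masked) grid.
#'
#' @param model a [QuantileModel-class]
#' @param grid baseline [CovariateGrid-class]
#' @param matNew,tapNew projected climate matrices with the grid's geometry
#' @param mask optional logical per-cell mask (e.g. cropland)
#' @param coeffs pedotransfer coefficients
#' @return list with `baseline` and `projected` (each: q50_pg,
#'   pot_intermediate_pg, pot_maximum_pg) and `percent_change` (positive =
#'   reduction)
#' @export
climateProjection <- function(model, grid, matNew, tapNew, mask = NULL,
                              coeffs = ptfCoefficients()) {
  if (!identical(dim(matNew), dim(grid@mat)) ||
      !identical(dim(tapNew), dim(grid@tap))) {
    stop("projected climate layers do not match the grid geometry")
  }
  cells <- gridTable(grid)
  keep <- if (is.null(mask)) rep(TRUE, nrow(cells)) else as.logical(mask)
  totals <- function(df) {
    q <- predictQuantiles(model, df)
    s <- vapply(c("q50", "q75", "q90"), function(col) {
      sum(.stockFromConcentration(q[[col]], coeffs) * df$area_km2) * 1e-6
    }, numeric(1))
    c(q50_pg = unname(s["q50"]),
      pot_intermediate_pg = unname(s["q75"] - s["q50"]),
      pot_maximum_pg = unname(s["q90"] - s["q50"]))
  }
  baseCells <- cells[keep, , drop = FALSE]
  projCells <- baseCells
  projCells$mat <- as.vector(matNew)[keep]
  projCells$tap <- as.vector(tapNew)[keep]
  baseline <- totals(baseCells)
  projected <- totals(projCells)
  list(baseline = baseline, projected = projected,
       percent_change = (baseline - projected) / baseline * 100)
}
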