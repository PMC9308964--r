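#' @include socpotential-package.R
NULL

#' Areal carbon stock of one soil layer
#'
#' \eqn{stock = (oc/100) \times (bd \times 1000) \times depth} in kg C per
#' m^2: concentration (percent mass) times bulk density (g/cm^3 = 1000
#' kg/m^3) times layer thickness (m). The default depth of 0.3 m is the
#' managed topsoil.
#'
#' @param oc SOC concentration, percent mass
#' @param bd bulk density, g/cm^3
#' @param depth layer thickness, m
#' @return stock in kg C m^-2
#' @examples
#' cellStock(1, 1.0)  # 3 kg C m^-2
#' @export
cellStock <- function(oc, bd, depth = 0.3) {
  if (any(oc < 0)) stop("oc must be nonnegative")
  if (any(bd <= 0)) stop("bd must be positive")
  if (any(depth <= 0)) stop("depth must be positive")
  (oc / 100) * (bd * 1000) * depth
}

# stock straight from concentration, with BD from the pedotransfer at that
# concentration (oc in percent -> g/kg conversion at this boundary)
.stockFromConcentration <- function(ocPct, coeffs = ptfCoefficients(),
                                    depth = 0.3, fixedBd = NULL) {
  bd <- if (is.null(fixedBd)) evaluatePtf(10 * ocPct, coeffs) else fixedBd
  cellStock(ocPct, bd, depth)
}

#' Aggregate per-cell quantile predictions to zone and global stocks
#'
#' Converts the q50/q75/q90 concentration predictions to per-cell stocks and
#' sums them to zone totals in Pg C: \eqn{\sum stock(kg\,m^{-2}) \times
#' area(km^2) \times 10^{-6}}. Bulk density is re-evaluated from the
#' pedotransfer function at each percentile's own concentration (the curve
#' falls with carbon content, so higher percentiles get lower BD); pass
#' `fixedBd` for fixed-density sensitivity accounting. A final "Global" row
#' holds the sums.
#'
#' @param quantiles data.frame with columns q50, q75, q90 (percent mass), one
#'   row per cell (e.g. from [predictQuantiles()])
#' @param areaKm2 per-cell areas (km^2)
#' @param zones per-cell zone labels
#' @param mask optional logical vector; FALSE cells are excluded (e.g. a
#'   cropland mask)
#' @param coeffs pedotransfer coefficients, default the published calibration
#' @param depth accounting depth in m, default 0.3
#' @param fixedBd optional fixed bulk density (g/cm^3) replacing the
#'   pedotransfer
#' @return zone report data.frame: zone, area_km2, q50_pg, q75_pg, q90_pg,
#'   with the last row "Global"
#' @export
aggregateStocks <- function(quantiles, areaKm2, zones, mask = NULL,
                            coeffs = ptfCoefficients(), depth = 0.3,
                            fixedBd = NULL) {
  if (missing(areaKm2) || is.null(areaKm2)) stop("area layer is required")
  n <- nrow(quantiles)
  stopifnot(length(areaKm2) == n, length(zones) == n)
  keep <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  q <- quantiles[keep, , drop = FALSE]
  area <- areaKm2[keep]; zone <- zones[keep]
  perZone <- lapply(c(q50 = "q50", q75 = "q75", q90 = "q90"), function(col) {
    stock <- .stockFromConcentration(q[[col]], coeffs, depth, fixedBd)
    tapply(stock * area * 1e-6, zone, sum)  # Pg per zone
  })
  zoneNames <- sort(unique(zone))
  report <- data.frame(zone = zoneNames,
                       area_km2 = as.numeric(tapply(area, zone, sum)[zoneNames]),
                       q50_pg = as.numeric(perZone$q50[zoneNames]),
                       q75_pg = as.numeric(perZone$q75[zoneNames]),
                       q90_pg = as.numeric(perZone$q90[zoneNames]),
                       stringsAsFactors = FALSE)
  rbind(report, data.frame(zone = "Global", area_km2 = sum(report$area_km2),
                           q50_pg = sum(report$q50_pg),
                           q75_pg = sum(report$q75_pg),
                           q90_pg = sum(report$q90_pg)))
}

#' Load the packaged global-cropland ecoregion stock table
#'
#' The published zone-level stock table for global croplands: total topsoil
#' (0-30 cm) SOC stocks in Pg C at the 50th, 75th and 90th percentiles and
#' cropland area per ecoregion, with a Global row. Used by the arithmetic
#' verification path and as a fixture for the accounting tests.
#'
#' @param path optional path to a CSV in the same schema (zone, q50_pg,
#'   q75_pg, q90_pg, area_km2)
#' @return zone report data.frame
#' @export
readTable1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_ecoregions.csv",
                        package = "socpotential")
  }
  if (!nzchar(path) || !file.exists(path)) stop("stock table fixture missing")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Additional storage potential from a zone report
#'
#' The intermediate (achievable) potential is the q75 - q50 stock gap; the
#' technical maximum is q90 - q50. Works on any data.frame carrying q50/q75/
#' q90 columns in Pg (zone reports) or kg m^-2 (per-cell tables with columns
#' q50, q75, q90).
#'
#' @param x zone report (columns q50_pg, q75_pg, q90_pg) or per-cell stock
#'   data.frame (columns q50, q75, q90)
#' @return `x` with added columns pot_intermediate and pot_maximum (same
#'   units as the inputs)
#' @export
additionalPotential <- function(x) {
  cols <- if (all(c("q50_pg", "q75_pg", "q90_pg") %in% names(x))) {
    c("q50_pg", "q75_pg", "q90_pg")
  } else if (all(c("q50", "q75", "q90") %in% names(x))) {
    c("q50", "q75", "q90")
  } else stop("need q50/q75/q90 columns")
  if (any(x[[cols[2]]] < x[[cols[1]]] - 1e-9) ||
      any(x[[cols[3]]] < x[[cols[2]]] - 1e-9)) {
    stop("crossing quantiles: q50 <= q75 <= q90 violated")
  }
  x$pot_intermediate <- x[[cols[2]]] - x[[cols[1]]]
  x$pot_maximum <- x[[cols[3]]] - x[[cols[1]]]
  x
}

#' Share of the global additional potential held by a zone subset
#'
#' @param report zone report including a "Global" row (see
#'   [aggregateStocks()] / [readTable1()])
#' @param zones character vector of zone names (may be empty)
#' @param level "intermediate" (q75 - q50) or "maximum" (q90 - q50)
#' @return list with `potential_pg` (subset potential, Pg C) and `share`
#'   (fraction of the global potential)
#' @export
zoneShare <- function(report, zones, level = c("intermediate", "maximum")) {
  level <- match.arg(level)
  report <- additionalPotential(report)
  unknown <- setdiff(zones, report$zone)
  if (length(unknown)) {
    stop("unknown zones: ", paste(unknown, collapse = ", "))
  }
  col <- paste0("pot_", level)
  globalPot <- report[[col]][report$zone == "Global"]
  subsetPot <- sum(report[[col]][report$zone %in% setdiff(zones, "Global")])
  list(potential_pg = subsetPot,
       share = if (globalPot > 0) subsetPot / globalPot else 0)
}
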