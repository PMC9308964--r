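#' @include socpotential-package.R
NULL

#' Covariate raster stack
#'
#' A small in-memory raster stack: continuous covariate layers (MAT in
#' degrees C, TAP in mm, elevation in m) plus categorical land-cover and zone
#' layers, and an explicit per-cell area layer in km^2. Cell areas are
#' supplied rather than derived from a map projection so stock accounting
#' stays testable without geodesy. Serialized to plain-text CSV (one row per
#' cell) by [writeGridCsv()].
#'
#' @slot nx,ny grid dimensions (columns, rows)
#' @slot mat,tap,elevation numeric ny x nx matrices
#' @slot landcover,zones character ny x nx matrices
#' @slot areaKm2 numeric ny x nx matrix of cell areas (km^2)
#' @exportClass CovariateGrid
setClass("CovariateGrid",
         representation(nx = "integer", ny = "integer", mat = "matrix",
                        tap = "matrix", elevation = "matrix",
                        landcover = "matrix", zones = "matrix",
                        areaKm2 = "matrix"))

setValidity("CovariateGrid", function(object) {
  dims <- c(object@ny, object@nx)
  for (l in c("mat", "tap", "elevation", "landcover", "zones", "areaKm2")) {
    if (!identical(dim(slot(object, l)), as.integer(dims))) {
      return(paste("layer", l, "is not ny x nx"))
    }
  }
  if (any(object@areaKm2 <= 0)) return("cell areas must be positive")
  if (!all(object@landcover %in% LANDCOVER_LEVELS)) {
    return("unknown land-cover class in grid")
  }
  TRUE
})

setMethod("show", "CovariateGrid", function(object) {
  cat("CovariateGrid:", object@nx, "x", object@ny, "cells, total area",
      signif(sum(object@areaKm2), 5), "km^2,", length(unique(c(object@zones))),
      "zones\n")
})

#' @describeIn CovariateGrid number of cells
#' @param x a CovariateGrid
#' @export
setMethod("length", "CovariateGrid", function(x) as.integer(x@nx) * x@ny)

#' Flatten a grid to a covariate table
#'
#' One row per cell in column-major order, with the covariate schema expected
#' by [predictQuantiles()] plus cell, area and zone columns.
#'
#' @param grid a [CovariateGrid-class]
#' @return a data.frame
#' @export
gridTable <- function(grid) {
  data.frame(cell = seq_len(length(grid)),
             mat = as.vector(grid@mat), tap = as.vector(grid@tap),
             elevation = as.vector(grid@elevation),
             landcover = as.vector(grid@landcover),
             zone = as.vector(grid@zones),
             area_km2 = as.vector(grid@areaKm2),
             stringsAsFactors = FALSE)
}

# low-frequency random surface on [0,1]^2: a handful of random plane waves
.smoothField <- function(nx, ny, nWaves = 6L) {
  x <- matrix(rep(seq(0, 1, length.out = max(nx, 2L))[seq_len(nx)], each = ny),
              ny, nx)
  y <- matrix(rep(seq(0, 1, length.out = max(ny, 2L))[seq_len(ny)], times = nx),
              ny, nx)
  f <- matrix(0, ny, nx)
  for (w in seq_len(nWaves)) {
    f <- f + rnorm(1) * sin(2 * pi * (runif(1, 0.5, 2.5) * x +
                                      runif(1, 0.5, 2.5) * y) +
                            runif(1, 0, 2 * pi))
  }
  f
}

# min-max rescale a field into a target range (midpoint if degenerate)
.rescaleField <- function(f, range) {
  span <- max(f) - min(f)
  if (span == 0) return(matrix(mean(range), nrow(f), ncol(f)))
  range[1] + (f - min(f)) / span * diff(range)
}

#' Generate a synthetic covariate grid
#'
#' Smooth low-frequency random surfaces for MAT, TAP and elevation (rescaled
#' into the configured ranges), categorical land-cover and zone layers
#' obtained by thresholding further smooth fields, and a uniform per-cell
#' area. The default 0.25 km^2 cell emulates a 500 m grid.
#'
#' @param nx,ny grid dimensions (>= 1)
#' @param config a [SyntheticConfig-class] supplying the covariate ranges and
#'   land-cover probabilities
#' @param seed integer seed
#' @param cellAreaKm2 per-cell area (km^2)
#' @param nZones number of zone labels
#' @return a [CovariateGrid-class]
#' @export
generateGrid <- function(nx, ny, config = syntheticConfig(), seed = 42L,
                         cellAreaKm2 = 0.25, nZones = 4L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  set.seed(seed)
  mat <- .rescaleField(.smoothField(nx, ny), config@matRange)
  tap <- .rescaleField(.smoothField(nx, ny), config@tapRange)
  elev <- .rescaleField(.smoothField(nx, ny), config@elevRange)
  lcField <- .smoothField(nx, ny) + matrix(rnorm(nx * ny, 0, 0.3), ny, nx)
  cuts <- quantile(lcField, cumsum(config@landcoverProbs)[-3])
  lc <- matrix(LANDCOVER_LEVELS[1L + findInterval(lcField, cuts)], ny, nx)
  zField <- .smoothField(nx, ny)
  zCuts <- quantile(zField, seq_len(nZones - 1L) / nZones)
  zones <- matrix(paste0("zone_", 1L + findInterval(zField, zCuts)), ny, nx)
  new("CovariateGrid", nx = nx, ny = ny, mat = mat, tap = tap,
      elevation = elev, landcover = lc, zones = zones,
      areaKm2 = matrix(cellAreaKm2, ny, nx))
}

#' Read/write grids and site tables as CSV
#'
#' The plain-text grid dialect is one row per cell (column-major) with
#' columns row, col, mat, tap, elevation, landcover, zone, area_km2. Site
#' tables use the dialect produced by [generateSites()] /
#' [harmonizeDataset()].
#'
#' @param grid a [CovariateGrid-class]
#' @param path file path
#' @return `readGridCsv()` returns a [CovariateGrid-class]; the writers
#'   return the path invisibly
#' @export
writeGridCsv <- function(grid, path) {
  df <- gridTable(grid)
  df$row <- ((df$cell - 1L) %% grid@ny) + 1L
  df$col <- ((df$cell - 1L) %/% grid@ny) + 1L
  write.csv(df[, c("row", "col", "mat", "tap", "elevation", "landcover",
                   "zone", "area_km2")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridCsv
#' @export
readGridCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ny <- max(df$row); nx <- max(df$col)
  df <- df[order(df$col, df$row), ]
  asMat <- function(v) matrix(v, ny, nx)
  new("CovariateGrid", nx = as.integer(nx), ny = as.integer(ny),
      mat = asMat(df$mat), tap = asMat(df$tap),
      elevation = asMat(df$elevation), landcover = asMat(df$landcover),
      zones = asMat(df$zone), areaKm2 = asMat(df$area_km2))
}

#' @rdname writeGridCsv
#' @param sites a site or harmonized-sample data.frame
#' @export
writeSiteCsv <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridCsv
#' @export
readSiteCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)
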