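#' @include socpotential-package.R
NULL

#' A set of layered soil profiles
#'
#' Container for per-site layer measurements (depth intervals in cm, measured
#' downward from the surface, half-open \[top, bottom)) together with the site
#' covariate table. Layers within a site must be sorted, non-overlapping and
#' have top < bottom.
#'
#' @slot layers data.frame with columns site_id, top, bottom, value (percent
#'   mass SOC, the layer mean)
#' @slot sites data.frame of per-site covariates (may carry the generating
#'   truth in soc_pct)
#' @exportClass SoilProfileSet
setClass("SoilProfileSet",
         representation(layers = "data.frame", sites = "data.frame"))

setValidity("SoilProfileSet", function(object) {
  l <- object@layers
  need <- c("site_id", "top", "bottom", "value")
  if (!all(need %in% names(l))) {
    return(paste("layers must have columns", paste(need, collapse = ", ")))
  }
  if (any(l$top < 0) || any(l$top >= l$bottom)) {
    return("each layer needs 0 <= top < bottom")
  }
  bad <- vapply(split(l, l$site_id), function(p) {
    p <- p[order(p$top), ]
    any(p$top[-1] < p$bottom[-nrow(p)] - 1e-9)
  }, logical(1))
  if (any(bad)) return("overlapping layers within a profile")
  TRUE
})

setMethod("show", "SoilProfileSet", function(object) {
  cat("SoilProfileSet:", length(unique(object@layers$site_id)), "profiles,",
      nrow(object@layers), "layers\n")
})

#' @describeIn SoilProfileSet number of profiles
#' @param x a SoilProfileSet
#' @export
setMethod("length", "SoilProfileSet",
          function(x) length(unique(x@layers$site_id)))

#' Accessors for SoilProfileSet
#'
#' `profileLayers()` returns the layer table; `profileSites()` the site table.
#' @param object a [SoilProfileSet-class]
#' @return a data.frame
#' @export
profileLayers <- function(object) object@layers

#' @rdname profileLayers
#' @export
profileSites <- function(object) object@sites

#' Fitted equal-area smoothing spline
#'
#' A continuous, C1 piecewise-quadratic function of depth. Piece j on
#' \[knots\[j\], knots\[j+1\]) has value a + b u + c u^2 in the local
#' coordinate u = depth - knots\[j\].
#'
#' @slot knots piece boundaries (cm), increasing
#' @slot coef J x 3 matrix of per-piece coefficients (a, b, c)
#' @slot lambda smoothing weight used in the fit
#' @slot layerMidpoints midpoints of the shallowest and deepest observed
#'   layers, used for constant extrapolation outside the support
#' @exportClass SplineFit
setClass("SplineFit",
         representation(knots = "numeric", coef = "matrix", lambda = "numeric",
                        layerMidpoints = "numeric"))

setValidity("SplineFit", function(object) {
  if (any(diff(object@knots) <= 0)) return("knots must be increasing")
  if (nrow(object@coef) != length(object@knots) - 1L ||
      ncol(object@coef) != 3L) {
    return("coef must be (length(knots) - 1) x 3")
  }
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

setMethod("show", "SplineFit", function(object) {
  cat("SplineFit:", nrow(object@coef), "quadratic pieces on",
      object@knots[1], "-", object@knots[length(object@knots)], "cm, lambda =",
      object@lambda, "\n")
})

#' Fit the equal-area smoothing spline to one profile
#'
#' Minimizes
#' \deqn{\frac{1}{m}\sum_k (\bar f_k - y_k)^2 + \lambda \int (f')^2\, dd}
#' over continuous piecewise-quadratic functions with continuous first
#' derivative on the layer partition, where \eqn{\bar f_k} is the mean of f
#' over observed layer k. This is the variational solution of depth smoothing
#' with layer-mean (bulked sample) data: within each layer f'' is constant, so
#' the quadratic family contains the unrestricted Sobolev minimizer. Gaps
#' between observed layers get their own (penalty-only) piece. The exact
#' minimizer is found by solving the KKT system of the quadratic program.
#'
#' As lambda shrinks to 0 the layer means of the fit converge to the observed
#' values (the "equal-area" property); larger lambda trades fidelity for
#' smoothness.
#'
#' @param profile data.frame with columns top, bottom, value (one site), or a
#'   [SoilProfileSet-class] with a single profile
#' @param lambda smoothing weight (>= 0), default 0.1
#' @return a [SplineFit-class]
#' @examples
#' fit <- fitEqualAreaSpline(data.frame(top = c(0, 10), bottom = c(10, 30),
#'                                      value = c(4, 1)), lambda = 0.1)
#' depthAverage(fit, 0, 30)
#' @export
fitEqualAreaSpline <- function(profile, lambda = 0.1) {
  if (is(profile, "SoilProfileSet")) profile <- profile@layers
  if (nrow(profile) < 1L) stop("profile has no layers")
  p <- profile[order(profile$top), , drop = FALSE]
  if (any(p$top >= p$bottom)) stop("each layer needs top < bottom")
  if (nrow(p) > 1L && any(p$top[-1] < p$bottom[-nrow(p)] - 1e-9)) {
    stop("overlapping layers")
  }
  if (lambda < 0) stop("lambda must be >= 0")

  # piece partition: observed layers plus any gaps between them
  bounds <- sort(unique(c(p$top, p$bottom)))
  J <- length(bounds) - 1L
  h <- diff(bounds)
  # map observed layers to pieces
  obsPiece <- match(p$top, bounds[-length(bounds)])
  m <- nrow(p)

  # unknowns x = (a_1, b_1, c_1, ..., a_J, b_J, c_J)
  idx <- function(j) (j - 1L) * 3L + 1:3
  nx <- 3L * J

  # data term: (1/m) sum_k (M_k x - y_k)^2
  M <- matrix(0, m, nx)
  for (k in seq_len(m)) {
    j <- obsPiece[k]
    M[k, idx(j)] <- c(1, h[j] / 2, h[j]^2 / 3)  # piece mean
  }
  # penalty: sum_j int_0^{h} (b + 2 c u)^2 du
  P <- matrix(0, nx, nx)
  for (j in seq_len(J)) {
    ii <- idx(j)
    P[ii[2], ii[2]] <- h[j]
    P[ii[2], ii[3]] <- P[ii[3], ii[2]] <- h[j]^2
    P[ii[3], ii[3]] <- 4 * h[j]^3 / 3
  }
  # continuity of value and slope at interior knots
  nc <- 2L * (J - 1L)
  A <- matrix(0, nc, nx)
  if (J > 1L) {
    for (j in seq_len(J - 1L)) {
      r <- 2L * (j - 1L) + 1L
      A[r, idx(j)] <- c(1, h[j], h[j]^2); A[r, idx(j + 1L)[1]] <- -1
      A[r + 1L, idx(j)] <- c(0, 1, 2 * h[j]); A[r + 1L, idx(j + 1L)[2]] <- -1
    }
  }

  # the roughness penalty vanishes only on constants, so flooring lambda at a
  # negligible level makes the program strictly convex and selects the
  # constant among the lambda = 0 minimizers (e.g. a single layer)
  lambdaEff <- max(lambda, 1e-8)
  H <- 2 * (crossprod(M) / m + lambdaEff * P)
  g <- 2 * crossprod(M, p$value) / m
  KKT <- rbind(cbind(H, t(A)), cbind(A, matrix(0, nc, nc)))
  sol <- solve(KKT, c(g, rep(0, nc)))
  coefs <- matrix(sol[seq_len(nx)], J, 3L, byrow = TRUE)

  new("SplineFit", knots = bounds, coef = coefs, lambda = lambda,
      layerMidpoints = c((p$top[1] + p$bottom[1]) / 2,
                         (p$top[m] + p$bottom[m]) / 2))
}

# evaluate the fitted function at depths; outside the support the value at
# the shallowest / deepest layer midpoint is held constant
.splineValue <- function(fit, d) {
  kn <- fit@knots
  d <- ifelse(d < kn[1], fit@layerMidpoints[1],
              ifelse(d > kn[length(kn)], fit@layerMidpoints[2], d))
  j <- pmin(findInterval(d, kn, rightmost.closed = TRUE), nrow(fit@coef))
  u <- d - kn[j]
  fit@coef[j, 1] + fit@coef[j, 2] * u + fit@coef[j, 3] * u^2
}

#' Average a fitted spline over a depth interval
#'
#' Mean of the fitted function over \[top, bottom\] cm, computed by exact
#' piecewise integration. Outside the fitted support the function is held
#' constant at its value at the shallowest / deepest layer midpoint.
#'
#' @param fit a [SplineFit-class]
#' @param top,bottom interval bounds in cm, top < bottom
#' @return mean SOC over the interval (percent mass)
#' @export
depthAverage <- function(fit, top = 0, bottom = 30) {
  if (top >= bottom) stop("need top < bottom")
  kn <- fit@knots
  J <- nrow(fit@coef)
  total <- 0
  # below-support and above-support constant segments
  lo <- kn[1]; hi <- kn[length(kn)]
  if (top < lo) {
    total <- total + .splineValue(fit, fit@layerMidpoints[1]) *
      (min(bottom, lo) - top)
  }
  if (bottom > hi) {
    total <- total + .splineValue(fit, fit@layerMidpoints[2]) *
      (bottom - max(top, hi))
  }
  a <- max(top, lo); b <- min(bottom, hi)
  if (b > a) {
    for (j in seq_len(J)) {
      s <- max(a, kn[j]); e <- min(b, kn[j + 1])
      if (e <= s) next
      u1 <- s - kn[j]; u2 <- e - kn[j]
      cf <- fit@coef[j, ]
      total <- total + cf[1] * (u2 - u1) + cf[2] * (u2^2 - u1^2) / 2 +
        cf[3] * (u2^3 - u1^3) / 3
    }
  }
  total / (bottom - top)
}

#' Harmonize a profile collection to 0-30 cm
#'
#' Fits the equal-area spline per profile and extracts the 0-30 cm mean.
#' Profiles whose deepest measurement is shallower than `minDepth` cm are
#' dropped (counted in the attached report); for retained profiles shallower
#' than 30 cm the fit is extended as a constant from the deepest layer
#' midpoint.
#'
#' @param profiles a [SoilProfileSet-class]
#' @param lambda smoothing weight, default 0.1
#' @param minDepth minimum measured depth (cm) for retention, default 20
#' @param verbose print the retained/dropped summary
#' @return data.frame of harmonized samples (site_id, soc_pct and any site
#'   covariates), with attribute `report = c(retained, dropped)`
#' @export
harmonizeDataset <- function(profiles, lambda = 0.1, minDepth = 20,
                             verbose = FALSE) {
  stopifnot(is(profiles, "SoilProfileSet"))
  bySite <- split(profiles@layers, profiles@layers$site_id)
  keep <- vapply(bySite, function(p) max(p$bottom) >= minDepth, logical(1))
  vals <- vapply(bySite[keep], function(p) {
    depthAverage(fitEqualAreaSpline(p, lambda), 0, 30)
  }, numeric(1))
  out <- data.frame(site_id = names(vals), soc_pct = unname(vals),
                    stringsAsFactors = FALSE)
  sites <- profiles@sites
  if (nrow(sites)) {
    cov <- sites[, setdiff(names(sites), "soc_pct"), drop = FALSE]
    out <- merge(out, cov, by = "site_id", sort = TRUE)
  }
  report <- c(retained = sum(keep), dropped = sum(!keep))
  if (verbose) {
    message("harmonized ", report[["retained"]], " profiles; dropped ",
            report[["dropped"]], " shallower than ", minDepth, " cm")
  }
  attr(out, "report") <- report
  out
}
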