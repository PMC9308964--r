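#' @include socpotential-package.R
NULL

#' Rational-function bulk-density pedotransfer coefficients
#'
#' Coefficients of \eqn{BD(oc) = (a - b \cdot oc) / (c \cdot oc + d)} with oc
#' in g/kg and BD in g/cm^3. The default coefficients (a = 83.2687,
#' b = 0.011, c = 0.635, d = 52.847) are the published global calibration;
#' they give BD(0) = 1.5756 g/cm^3 and a monotone decrease with carbon
#' content. The parametrization is scale-degenerate (multiplying all four
#' coefficients by k > 0 leaves the curve unchanged); [fitPtf()] therefore
#' returns the d = 1 normalized representative.
#'
#' @slot a,b,c,d dimensionless coefficients; c >= 0, d > 0, a/d > 0
#' @exportClass PTFCoefficients
setClass("PTFCoefficients",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        d = "numeric"))

setValidity("PTFCoefficients", function(object) {
  if (object@c < 0 || object@d <= 0) {
    return("need c >= 0 and d > 0 so the denominator is positive for oc >= 0")
  }
  if (object@a / object@d <= 0) return("BD at oc = 0 (a/d) must be positive")
  TRUE
})

#' @rdname PTFCoefficients-class
#' @param a,b,c,d coefficients; defaults are the published calibration
#' @return a validated [PTFCoefficients-class]
#' @export
ptfCoefficients <- function(a = 83.2687, b = 0.011, c = 0.635, d = 52.847) {
  new("PTFCoefficients", a = a, b = b, c = c, d = d)
}

setMethod("show", "PTFCoefficients", function(object) {
  cat(sprintf("PTF: BD(oc) = (%.4g - %.4g oc) / (%.4g oc + %.4g), BD(0) = %.4f g/cm^3\n",
              object@a, object@b, object@c, object@d, object@a / object@d))
})

#' Predict bulk density from SOC concentration
#'
#' @param oc SOC concentration in g/kg (multiply percent values by 10)
#' @param coeffs a [PTFCoefficients-class]; default the published calibration
#' @return bulk density in g/cm^3
#' @examples
#' evaluatePtf(c(0, 10, 100))
#' @export
evaluatePtf <- function(oc, coeffs = ptfCoefficients()) {
  if (any(oc < 0)) stop("oc must be nonnegative (g/kg)")
  (coeffs@a - coeffs@b * oc) / (coeffs@c * oc + coeffs@d)
}

#' Refit the bulk-density pedotransfer function
#'
#' Nonlinear least squares of BD on oc under the normalized parametrization
#' \eqn{BD = (a' - b' \cdot oc)/(c' \cdot oc + 1)} (d fixed at 1 for
#' identifiability, since the raw four-coefficient form is invariant to a
#' common positive scaling). Started from a' = BD at the smallest oc, b' = 0,
#' c' = 0.01, with up to 5 seeded jittered restarts on failure.
#'
#' @param pairs data.frame with columns oc_gkg and bd_gcm3
#' @param seed integer seed for restart jitters
#' @return list with elements `coefficients` (a d = 1 normalized
#'   [PTFCoefficients-class]), `rmse` (root mean squared error of the fit on
#'   its own pairs, g/cm^3), `bias` (mean residual), and `fit` (the nls
#'   object)
#' @export
fitPtf <- function(pairs, seed = 42L) {
  stopifnot(all(c("oc_gkg", "bd_gcm3") %in% names(pairs)))
  if (nrow(pairs) < 10) stop("need at least 10 pairs")
  if (diff(range(pairs$oc_gkg)) <= 0) {
    stop("degenerate input: all oc values are equal")
  }
  start0 <- list(ap = pairs$bd_gcm3[which.min(pairs$oc_gkg)], bp = 0,
                 cp = 0.01)
  set.seed(seed)
  fit <- NULL
  for (try in 0:5) {
    start <- if (try == 0) start0 else {
      lapply(start0, function(v) v * (1 + rnorm(1, 0, 0.2)) + rnorm(1, 0, 0.01))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(bd_gcm3 ~ (ap - bp * oc_gkg) / (cp * oc_gkg + 1),
                        data = pairs, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("PTF fit did not converge after 5 restarts")
  cf <- coef(fit)
  resid <- pairs$bd_gcm3 - predict(fit)
  list(coefficients = ptfCoefficients(a = cf[["ap"]], b = cf[["bp"]],
                                      c = cf[["cp"]], d = 1),
       rmse = sqrt(mean(resid^2)), bias = mean(resid), fit = fit)
}
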