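#' @include socpotential-package.R
NULL

# features attributed for a QuantileModel; land cover is treated as a single
# categorical feature
.ATTR_FEATURES <- c("mat", "tap", "elevation", "landcover")

# turn a model (QuantileModel or plain function) into f(data.frame) -> matrix
.asPredictor <- function(model) {
  if (is(model, "QuantileModel")) {
    function(df) as.matrix(predictQuantiles(model, df))
  } else if (is.function(model)) {
    function(df) {
      out <- model(df)
      if (is.null(dim(out))) out <- matrix(out, ncol = 1) else as.matrix(out)
    }
  } else stop("model must be a QuantileModel or a prediction function")
}

#' Sampled Shapley attribution of one prediction
#'
#' Monte-Carlo permutation estimator of the Shapley values of a prediction:
#' for each random feature ordering a background row is drawn, features are
#' switched from the background value to the instance value in order, and
#' each feature is credited with the change in prediction it causes. Averaged
#' over orderings this converges to the exact (interventional) Shapley value,
#' which satisfies local accuracy: base value + sum of contributions =
#' prediction.
#'
#' @param model a [QuantileModel-class] or a function mapping a covariate
#'   data.frame to a prediction vector/matrix
#' @param instance single-row data.frame to explain
#' @param background data.frame of reference rows (the "absent" feature
#'   distribution)
#' @param features columns to attribute; default mat, tap, elevation,
#'   landcover (categorical land cover is one feature)
#' @param nPermutations number of sampled orderings (>= 1), default 200
#' @param seed integer seed
#' @return list with `contributions` (features x heads matrix),
#'   `baseValue` (mean prediction over the background), `prediction`, and
#'   `se` (Monte-Carlo standard error per entry)
#' @export
shapleySample <- function(model, instance, background,
                          features = intersect(.ATTR_FEATURES,
                                               names(instance)),
                          nPermutations = 200L, seed = 42L) {
  f <- .asPredictor(model)
  if (nrow(background) < 1L) stop("background must be non-empty")
  if (nPermutations < 1L) stop("need at least one permutation")
  if (!all(features %in% names(background))) {
    stop("feature mismatch between instance and background")
  }
  p <- length(features)
  set.seed(seed)
  pred <- f(instance)[1, , drop = TRUE]
  K <- length(pred)
  baseValue <- colMeans(f(background))

  contrib <- array(0, c(p, K, nPermutations),
                   dimnames = list(features, names(pred), NULL))
  for (s in seq_len(nPermutations)) {
    b <- background[sample.int(nrow(background), 1L), , drop = FALSE]
    ord <- sample.int(p)
    cur <- b
    prev <- f(cur)[1, ]
    for (i in ord) {
      cur[[features[i]]] <- instance[[features[i]]]
      now <- f(cur)[1, ]
      contrib[i, , s] <- now - prev
      prev <- now
    }
  }
  est <- apply(contrib, c(1, 2), mean)
  se <- apply(contrib, c(1, 2), sd) / sqrt(nPermutations)
  list(contributions = est, baseValue = baseValue, prediction = pred, se = se)
}

#' Attribute many instances into a long table
#'
#' Runs [shapleySample()] per row and stacks the results in the long format
#' (instance, covariate, percentile, contribution) used by the summary and
#' percent-change reports.
#'
#' @param model a [QuantileModel-class] or prediction function
#' @param instances data.frame of rows to explain
#' @param background reference rows
#' @param nPermutations sampled orderings per instance
#' @param seed integer seed (per-instance seeds are derived from it)
#' @param ... passed to [shapleySample()]
#' @return long data.frame: instance, covariate, percentile, contribution
#' @export
attributeDataset <- function(model, instances, background,
                             nPermutations = 200L, seed = 42L, ...) {
  rows <- lapply(seq_len(nrow(instances)), function(i) {
    att <- shapleySample(model, instances[i, , drop = FALSE], background,
                         nPermutations = nPermutations, seed = seed + i, ...)
    cm <- att$contributions
    data.frame(instance = i,
               covariate = rep(rownames(cm), times = ncol(cm)),
               percentile = rep(colnames(cm), each = nrow(cm)),
               contribution = as.vector(cm), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent change of covariate contributions between percentiles
#'
#' Normalizes the growth of absolute contributions from one percentile head
#' to another: per covariate,
#' \eqn{(\overline{|c|}_{to} - \overline{|c|}_{from}) / \overline{|c|}_{from}
#' \times 100}, the mean taken over instances.
#'
#' @param attributions long data.frame from [attributeDataset()]
#' @param from,to percentile labels present in the table (e.g. "q50", "q75")
#' @return named numeric vector of percent changes per covariate
#' @export
contributionChange <- function(attributions, from = "q50", to = "q75") {
  stopifnot(all(c(from, to) %in% attributions$percentile))
  meanAbs <- function(pct) {
    sub <- attributions[attributions$percentile == pct, ]
    tapply(abs(sub$contribution), sub$covariate, mean)
  }
  mFrom <- meanAbs(from); mTo <- meanAbs(to)
  if (any(mFrom == 0)) stop("zero mean absolute contribution at ", from)
  change <- (mTo[names(mFrom)] - mFrom) / mFrom * 100
  setNames(as.numeric(change), names(mFrom))
}

#' Tag temperature groups
#'
#' Labels mean annual temperatures by the three SOC response groups: warm
#' (> 17.5 degrees C, fast turnover), intermediate (10-17.5), cold (< 10).
#'
#' @param mat mean annual temperature, degrees C
#' @return character vector in {"warm", "intermediate", "cold"}
#' @export
temperatureGroups <- function(mat) {
  cut(mat, c(-Inf, 10, 17.5, Inf), labels = c("cold", "intermediate", "warm"),
      right = FALSE) |> as.character()
}
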