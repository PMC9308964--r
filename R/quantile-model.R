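#' @include socpotential-package.R
NULL

#' Architecture of the multi-task quantile network
#'
#' A fully-connected trunk of rectified-linear hidden layers shared by five
#' single-unit linear heads, one per predicted percentile. Defaults follow the
#' published architecture: three hidden layers of 20 units; heads at the 25th,
#' 50th, 75th, 90th and 95th percentiles. The outer heads (25th, 95th) act as
#' co-trained regularizers and are not used by the accounting modules.
#'
#' @param hiddenLayers integer vector of hidden-layer unit counts
#' @param percentiles strictly increasing probabilities in (0, 1)
#' @return a list with class "modelSpec"
#' @export
modelSpec <- function(hiddenLayers = c(20L, 20L, 20L),
                      percentiles = c(0.25, 0.5, 0.75, 0.9, 0.95)) {
  if (length(hiddenLayers) < 1L || any(hiddenLayers < 1L)) {
    stop("need at least one hidden layer of positive size")
  }
  if (any(percentiles <= 0) || any(percentiles >= 1) ||
      any(diff(percentiles) <= 0)) {
    stop("percentiles must be strictly increasing within (0, 1)")
  }
  structure(list(hiddenLayers = as.integer(hiddenLayers),
                 percentiles = percentiles),
            class = "modelSpec")
}

#' Training hyperparameters
#'
#' Defaults are the published best grid-search configuration: 100 epochs,
#' batch size 32, learning rate 0.001, with a 5 percent held-out test split.
#'
#' @param epochs,batchSize,learningRate optimizer settings (Adam)
#' @param testFraction fraction held out as the test set, in (0, 1)
#' @param seed integer seed for splitting, initialization and shuffling
#' @param nBootstrap number of bootstrap train/validation resamples to try;
#'   the resample with the lowest validation total loss wins
#' @return a list with class "trainingConfig"
#' @export
trainingConfig <- function(epochs = 100L, batchSize = 32L,
                           learningRate = 0.001, testFraction = 0.05,
                           seed = 42L, nBootstrap = 1L) {
  stopifnot(epochs >= 1, batchSize >= 1, learningRate > 0,
            testFraction > 0, testFraction < 1, nBootstrap >= 1)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, testFraction = testFraction,
                 seed = as.integer(seed), nBootstrap = as.integer(nBootstrap)),
            class = "trainingConfig")
}

#' Pinball (quantile) loss
#'
#' \eqn{\max\{\tau (y - \hat y), (\tau - 1)(y - \hat y)\}}, averaged over the
#' batch when vectors are supplied. Its minimizer over constant predictions is
#' the sample tau-quantile, which is what makes each network head estimate its
#' percentile.
#'
#' @param y observed values
#' @param yhat predicted values
#' @param tau probability in (0, 1)
#' @return nonnegative scalar (batch mean)
#' @examples
#' pinballLoss(5, 3, 0.9)  # 1.8
#' @export
pinballLoss <- function(y, yhat, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  r <- y - yhat
  mean(pmax(tau * r, (tau - 1) * r))
}

#' Total multi-head loss
#'
#' Sum over the heads of the batch-mean pinball losses.
#'
#' @param y observed values
#' @param qmat matrix (n x heads) of predictions, columns ordered as
#'   `percentiles`
#' @param percentiles probabilities matching the columns of `qmat`
#' @return nonnegative scalar
#' @export
totalLoss <- function(y, qmat, percentiles = c(0.25, 0.5, 0.75, 0.9, 0.95)) {
  qmat <- as.matrix(qmat)
  if (ncol(qmat) != length(percentiles)) {
    stop("need one prediction column per percentile head")
  }
  sum(vapply(seq_along(percentiles),
             function(k) pinballLoss(y, qmat[, k], percentiles[k]),
             numeric(1)))
}

#' Split samples into test set and bootstrap train/validation resamples
#'
#' A disjoint test set of round(testFraction * n) rows is held out first; the
#' remaining pool is resampled with replacement to form the training set, with
#' the out-of-bag rows (about 36.8 percent of the pool in expectation) serving
#' as validation.
#'
#' @param samples data.frame of harmonized samples
#' @param testFraction held-out fraction, default 0.05
#' @param seed integer seed
#' @param nBootstrap number of bootstrap resamples to return
#' @return list with `test`, `pool`, and `resamples` (a list of
#'   list(train, validation) index vectors into `pool`)
#' @export
splitData <- function(samples, testFraction = 0.05, seed = 42L,
                      nBootstrap = 1L) {
  n <- nrow(samples)
  if (n < 20) stop("need at least 20 samples to split")
  set.seed(seed)
  nTest <- round(testFraction * n)
  testIdx <- sample.int(n, nTest)
  poolIdx <- setdiff(seq_len(n), testIdx)
  pool <- samples[poolIdx, , drop = FALSE]
  resamples <- lapply(seq_len(nBootstrap), function(i) {
    train <- sample.int(nrow(pool), nrow(pool), replace = TRUE)
    list(train = train, validation = setdiff(seq_len(nrow(pool)), train))
  })
  list(test = samples[testIdx, , drop = FALSE], pool = pool,
       resamples = resamples)
}

# ---- covariate standardization ------------------------------------------

# mean/sd per continuous covariate estimated on training rows only, plus the
# one-hot mapping for land cover
.fitStandardizer <- function(df, covariates = c("mat", "tap", "elevation"),
                             useLandcover = TRUE) {
  mu <- vapply(covariates, function(v) mean(df[[v]]), numeric(1))
  sg <- vapply(covariates, function(v) sd(df[[v]]), numeric(1))
  if (any(!is.finite(sg)) || any(sg <= 0)) {
    stop("degenerate covariate: zero variance in training data")
  }
  list(covariates = covariates, mean = mu, sd = sg,
       useLandcover = useLandcover, levels = LANDCOVER_LEVELS)
}

.applyStandardizer <- function(std, df, landcover = NULL) {
  missing <- setdiff(std$covariates, names(df))
  if (length(missing)) {
    stop("covariates missing from input: ", paste(missing, collapse = ", "))
  }
  X <- vapply(std$covariates,
              function(v) (df[[v]] - std$mean[[v]]) / std$sd[[v]],
              numeric(nrow(df)))
  X <- matrix(X, nrow = nrow(df),
              dimnames = list(NULL, std$covariates))
  if (!all(is.finite(X))) stop("non-finite covariates after standardization")
  if (std$useLandcover) {
    lc <- if (is.null(landcover)) as.character(df$landcover) else
      rep_len(as.character(landcover), nrow(df))
    if (!all(lc %in% std$levels)) stop("unknown land-cover class")
    oneHot <- vapply(std$levels, function(l) as.numeric(lc == l),
                     numeric(nrow(df)))
    oneHot <- matrix(oneHot, nrow = nrow(df),
                     dimnames = list(NULL, std$levels))
    X <- cbind(X, oneHot)
  }
  X
}

# ---- the model container ------------------------------------------------

#' Trained multi-task quantile network
#'
#' Holds the fitted weights (or one set per land-cover group), the covariate
#' standardizer fitted on training rows only, the architecture and training
#' configuration, the per-epoch training-loss history, and the held-out test
#' set.
#'
#' @slot mode "pooled" (land cover one-hot encoded as a covariate) or
#'   "per_landcover" (an independent network per group)
#' @slot weights list of weight matrices (pooled mode)
#' @slot perCover named list of list(weights, standardizer) (per-cover mode)
#' @slot standardizer covariate standardizer (pooled mode)
#' @slot spec,config the [modelSpec()] and [trainingConfig()] used
#' @slot history numeric per-epoch training total loss
#' @slot validationLoss total loss on the winning resample's out-of-bag rows
#' @slot test held-out test data.frame
#' @exportClass QuantileModel
setClass("QuantileModel",
         representation(mode = "character", weights = "list",
                        perCover = "list", standardizer = "list",
                        spec = "list", config = "list", history = "numeric",
                        validationLoss = "numeric", test = "data.frame"))

setMethod("show", "QuantileModel", function(object) {
  cat("QuantileModel (", object@mode, "): trunk ",
      paste(object@spec$hiddenLayers, collapse = "-"), ", heads at ",
      paste(object@spec$percentiles, collapse = "/"), "\n", sep = "")
  if (length(object@history)) {
    cat("  final training loss ", signif(tail(object@history, 1), 4),
        " after ", length(object@history), " epochs; validation loss ",
        signif(object@validationLoss, 4), "\n", sep = "")
  }
})

#' @describeIn QuantileModel per-epoch training total loss
#' @param object a QuantileModel
#' @export
lossHistory <- function(object) object@history

# train one network on standardized X, y
.trainOne <- function(X, y, spec, config, seed) {
  .qmlp_train(X, y, spec$hiddenLayers, spec$percentiles, config$epochs,
              config$batchSize, config$learningRate, as.integer(seed))
}

#' Train the multi-task quantile network
#'
#' Splits the samples (5 percent test by default), fits the covariate
#' standardizer on the bootstrap training rows only, and minimizes the summed
#' pinball loss with Adam. With `nBootstrap > 1` the resample with the lowest
#' out-of-bag validation total loss wins (ties broken by resample order). In
#' "per_landcover" mode an independent network is fitted per land-cover group
#' without the land-cover covariate; in "pooled" mode a single network takes
#' land cover one-hot encoded.
#'
#' @param samples data.frame of harmonized samples with columns mat, tap,
#'   elevation, landcover, soc_pct
#' @param spec a [modelSpec()]
#' @param config a [trainingConfig()]
#' @param mode "pooled" or "per_landcover"
#' @return a [QuantileModel-class]
#' @export
trainQuantileModel <- function(samples, spec = modelSpec(),
                               config = trainingConfig(),
                               mode = c("pooled", "per_landcover")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mat", "tap", "elevation", "landcover", "soc_pct") %in%
                  names(samples)))
  if (!all(is.finite(samples$soc_pct)) ||
      !all(is.finite(as.matrix(samples[, c("mat", "tap", "elevation")])))) {
    stop("non-finite covariates or responses")
  }
  sp <- splitData(samples, config$testFraction, config$seed, config$nBootstrap)
  pool <- sp$pool

  fitResample <- function(train, validation, seedOffset) {
    trainRows <- pool[train, , drop = FALSE]
    if (mode == "pooled") {
      std <- .fitStandardizer(trainRows)
      X <- .applyStandardizer(std, trainRows)
      w <- .trainOne(X, trainRows$soc_pct, spec, config,
                     config$seed + seedOffset)
      predictFun <- function(df) {
        .qmlp_predict(w, .applyStandardizer(std, df))
      }
      result <- list(weights = w, standardizer = std, perCover = list())
    } else {
      perCover <- lapply(setNames(nm = LANDCOVER_LEVELS), function(lc) {
        rows <- trainRows[trainRows$landcover == lc, , drop = FALSE]
        if (nrow(rows) < 10) stop("too few training rows for group ", lc)
        std <- .fitStandardizer(rows, useLandcover = FALSE)
        w <- .trainOne(.applyStandardizer(std, rows), rows$soc_pct, spec,
                       config, config$seed + seedOffset)
        list(weights = w, standardizer = std)
      })
      predictFun <- function(df) {
        out <- matrix(NA_real_, nrow(df), length(spec$percentiles))
        for (lc in LANDCOVER_LEVELS) {
          sel <- df$landcover == lc
          if (!any(sel)) next
          sub <- perCover[[lc]]
          out[sel, ] <- .qmlp_predict(sub$weights,
                                      .applyStandardizer(sub$standardizer,
                                                         df[sel, , drop = FALSE]))
        }
        out
      }
      result <- list(weights = list(), standardizer = list(),
                     perCover = perCover)
    }
    valRows <- pool[validation, , drop = FALSE]
    result$valLoss <- if (nrow(valRows)) {
      totalLoss(valRows$soc_pct, predictFun(valRows), spec$percentiles)
    } else Inf
    result
  }

  fits <- lapply(seq_along(sp$resamples), function(i) {
    rs <- sp$resamples[[i]]
    fitResample(rs$train, rs$validation, i - 1L)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "valLoss"))]]

  history <- if (mode == "pooled") unlist(best$weights$history) else
    Reduce(`+`, lapply(best$perCover, function(m) unlist(m$weights$history)))

  new("QuantileModel", mode = mode, weights = best$weights,
      perCover = best$perCover, standardizer = best$standardizer,
      spec = unclass(spec), config = unclass(config),
      history = as.numeric(history),
      validationLoss = best$valLoss, test = sp$test)
}

#' Predict SOC percentiles
#'
#' Applies the model's own standardizer and network(s) to covariate rows or a
#' [CovariateGrid-class]. Per location the five head outputs are sorted to
#' enforce non-crossing (q25 <= ... <= q95; the number of locations needing a
#' reorder is attached as attribute `n_crossed`) and floored at 0 percent.
#'
#' @param model a [QuantileModel-class]
#' @param newdata data.frame with the training covariate schema, or a
#'   [CovariateGrid-class]
#' @param landcover optional land-cover override (a single class or one per
#'   row), used for substitution scenarios
#' @return data.frame with columns q25, q50, q75, q90, q95 (percent mass),
#'   one row per input row / grid cell (cells in column-major order); grid
#'   input also sets attribute `grid_dim`
#' @export
predictQuantiles <- function(model, newdata, landcover = NULL) {
  gridDim <- NULL
  if (is(newdata, "CovariateGrid")) {
    gridDim <- c(newdata@nx, newdata@ny)
    newdata <- gridTable(newdata)
  }
  if (!is.null(landcover)) newdata$landcover <- rep_len(as.character(landcover),
                                                        nrow(newdata))
  raw <- if (model@mode == "pooled") {
    .qmlp_predict(model@weights, .applyStandardizer(model@standardizer, newdata))
  } else {
    out <- matrix(NA_real_, nrow(newdata), length(model@spec$percentiles))
    for (lc in LANDCOVER_LEVELS) {
      sel <- newdata$landcover == lc
      if (!any(sel)) next
      sub <- model@perCover[[lc]]
      out[sel, ] <- .qmlp_predict(sub$weights,
                                  .applyStandardizer(sub$standardizer,
                                                     newdata[sel, , drop = FALSE]))
    }
    out
  }
  crossed <- sum(apply(raw, 1L, is.unsorted))
  sorted <- t(apply(raw, 1L, sort))
  sorted[sorted < 0] <- 0
  out <- as.data.frame(sorted)
  names(out) <- paste0("q", round(100 * model@spec$percentiles))
  attr(out, "n_crossed") <- crossed
  if (!is.null(gridDim)) attr(out, "grid_dim") <- gridDim
  out
}

#' Test-set RMSE of the median head
#'
#' Root mean squared error between observations and the predicted 50th
#' percentile, the headline accuracy metric.
#'
#' @param model a [QuantileModel-class]
#' @param testset optional data.frame; defaults to the model's held-out test
#'   set
#' @return RMSE in percent mass
#' @export
rmseQ50 <- function(model, testset = NULL) {
  if (is.null(testset)) testset <- model@test
  if (!nrow(testset)) stop("empty test set")
  q <- predictQuantiles(model, testset)
  .rmse(testset$soc_pct, q$q50)
}
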