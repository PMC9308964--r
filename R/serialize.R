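#' @include socpotential-package.R
NULL

#' Save and restore trained quantile models
#'
#' Serializes a [QuantileModel-class] — weights, standardizer, architecture,
#' training configuration, loss history and held-out test set — to a single
#' plain-text JSON file at full double precision, and restores it so that
#' predictions are bit-reproducible.
#'
#' @param model a [QuantileModel-class]
#' @param path JSON file path
#' @return `saveQuantileModel()` the path, invisibly; `loadQuantileModel()` a
#'   [QuantileModel-class]
#' @export
saveQuantileModel <- function(model, path) {
  # named atomic vectors lose their names in JSON arrays; store as objects
  stdPayload <- function(s) {
    if (!length(s)) return(list())
    s$mean <- as.list(s$mean); s$sd <- as.list(s$sd)
    s
  }
  payload <- list(mode = model@mode, weights = model@weights,
                  perCover = lapply(model@perCover, function(m) {
                    list(weights = m$weights,
                         standardizer = stdPayload(m$standardizer))
                  }),
                  standardizer = stdPayload(model@standardizer),
                  spec = model@spec,
                  config = model@config, history = model@history,
                  validationLoss = model@validationLoss, test = model@test)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", dataframe = "columns",
                       null = "null")
  invisible(path)
}

# jsonlite reads b/bo back as plain vectors and W/Wo as matrices; the C++
# predictor accepts both, so only list shapes need realignment
.reviveWeights <- function(w) {
  list(W = lapply(w$W, function(m) matrix(unlist(m), nrow = length(m),
                                          byrow = TRUE)),
       b = lapply(w$b, function(v) as.numeric(unlist(v))),
       Wo = matrix(unlist(w$Wo), nrow = length(w$Wo), byrow = TRUE),
       bo = as.numeric(unlist(w$bo)),
       history = as.numeric(unlist(w$history)))
}

#' @rdname saveQuantileModel
#' @export
loadQuantileModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  std <- function(s) {
    if (!length(s)) return(list())
    list(covariates = unlist(s$covariates), mean = unlist(s$mean),
         sd = unlist(s$sd), useLandcover = isTRUE(s$useLandcover),
         levels = unlist(s$levels))
  }
  test <- as.data.frame(lapply(p$test, unlist), stringsAsFactors = FALSE)
  perCover <- lapply(p$perCover, function(m) {
    list(weights = .reviveWeights(m$weights), standardizer = std(m$standardizer))
  })
  new("QuantileModel", mode = p$mode,
      weights = if (length(p$weights)) .reviveWeights(p$weights) else list(),
      perCover = perCover,
      standardizer = std(p$standardizer),
      spec = list(hiddenLayers = as.integer(unlist(p$spec$hiddenLayers)),
                  percentiles = unlist(p$spec$percentiles)),
      config = lapply(p$config, function(x) if (is.list(x)) unlist(x) else x),
      history = as.numeric(unlist(p$history)),
      validationLoss = as.numeric(p$validationLoss), test = test)
}
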