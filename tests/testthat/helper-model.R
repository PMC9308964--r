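# One moderately sized trained model shared across tests that only need
# "some reasonable fit", memoized so the suite trains it once.
.sharedEnv <- new.env()

sharedConfig <- function() syntheticConfig(nSites = 6000L, seed = 11L)

sharedModel <- function() {
  if (is.null(.sharedEnv$model)) {
    sites <- generateSites(sharedConfig())
    .sharedEnv$model <- trainQuantileModel(
      sites, config = trainingConfig(epochs = 60L, seed = 3L))
  }
  .sharedEnv$model
}
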