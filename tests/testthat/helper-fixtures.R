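## Shared fixtures. Heavy objects (trained models) are built once per run.

.fixtures <- new.env(parent = emptyenv())

## Small cohort where only the four interval parameters vary; 100 Hz beats
## keep the input dimension low enough for second-scale training.
tinyCohort <- function(n = 250, seed = 42, samplingRate = 100) {
  pop <- samplePopulation(n, paramDistributions = intervalOnlyDistributions(),
                          outcomeModel = NULL, seed = seed)
  list(pop = pop,
       cohort = simulateCohortBeats(pop$params, samplingRate = samplingRate))
}

cachedTinyData <- function() {
  if (is.null(.fixtures$tinyData)) .fixtures$tinyData <- tinyCohort()
  .fixtures$tinyData
}

cachedTinyModel <- function() {
  if (is.null(.fixtures$tinyModel)) {
    td <- cachedTinyData()
    cfg <- vaeConfig(latentDim = 6, beta = 0.005, hidden = 64, maxEpochs = 12,
                     batchSize = 32, seed = 7)
    .fixtures$tinyModel <- trainBetaVAE(td$cohort, cfg)
  }
  .fixtures$tinyModel
}

## Hand-built linear model (no hidden layers): mu = X Wmu, xhat = Z Wout.
## Useful when tests need an exactly linear decoder.
linearStubModel <- function(K = 4, tlen = 10, Wout = NULL, seed = 1) {
  D <- 12L * tlen
  set.seed(seed)
  if (is.null(Wout)) Wout <- matrix(rnorm(K * D, sd = 0.3), K, D)
  params <- list(Wmu = matrix(rnorm(D * K, sd = 0.05), D, K),
                 bmu = rep(0, K),
                 Wlv = matrix(0, D, K), blv = rep(0, K),
                 Wout = Wout, bout = rep(0, D))
  new("BetaVAE",
      config = vaeConfig(latentDim = K, hidden = integer(0)),
      params = params,
      history = data.frame(epoch = 0L, train = NA_real_, validation = 0),
      selectedEpoch = 0L,
      latentMean = rep(0, K), latentSd = rep(1, K),
      beatLength = as.integer(tlen), samplingRate = 100,
      rPeakIndex = as.integer(tlen %/% 3),
      leadNames = c("I", "II", "III", "aVR", "aVL", "aVF",
                    paste0("V", 1:6)))
}

## Full-scale parameter-recovery study, shared between acceptance tests.
cachedRecoveryStudy <- function() {
  if (is.null(.fixtures$recovery))
    .fixtures$recovery <- parameterRecoveryStudy(seed = 1)
  .fixtures$recovery
}

flattenBeat <- function(beat) as.vector(t(beatSamples(beat)))
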