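#' Parameter-distribution set where only the conduction parameters vary
#'
#' The marginal distributions of [defaultParamDistributions()] with every
#' generative parameter other than ventricular rate, PR interval, QRS
#' duration and QT interval (and age) fixed at its mean. This is the cohort
#' design used to ask whether the latent space recovers the four traditional
#' interval parameters when they vary independently.
#'
#' @return named list of distribution specifications
#' @export
intervalOnlyDistributions <- function() {
  d <- defaultParamDistributions()
  keep <- c("ventricular_rate", "pr_interval", "qrs_duration", "qt_interval",
            "age")
  for (nm in setdiff(names(d), keep)) d[[nm]]$sd <- 0
  d
}

#' Latent parameter-recovery study
#'
#' End-to-end experiment: simulate a cohort of median beats in which
#' ventricular rate, PR, QRS and QT vary independently (all other
#' generative parameters fixed), train a beta-VAE, and measure (i) the mean
#' held-out reconstruction correlation and (ii), for each of the four
#' parameters, the maximum over factors of the absolute Pearson correlation
#' between a latent factor and that parameter.
#'
#' Defaults define the study conditions: 3,000 beats at 500 Hz (12 x 600
#' samples), K = 8 latent factors, a 128-64 encoder with mirrored decoder
#' behind a 200-component partially whitened principal-subspace front-end,
#' small minibatches, at most 30 epochs. See the package vignette for the
#' reasoning behind the beta value, the front-end and the batch size.
#'
#' @param n cohort size
#' @param config a [vaeConfig()]; `NULL` uses the study configuration
#'   seeded with `seed`
#' @param samplingRate beat sampling rate, Hz
#' @param seed seed for cohort simulation and, when `config` is `NULL`,
#'   training
#' @return list with `maxAbsR` (named, the four parameters), `meanHeldOutR`,
#'   `model` (the trained [BetaVAE-class]), `cohort`, `params`, `qc`
#' @export
parameterRecoveryStudy <- function(n = 3000,
                                   config = NULL,
                                   samplingRate = 500,
                                   seed = 1) {
  if (is.null(config))
    config <- vaeConfig(latentDim = 8, beta = 0.05, hidden = c(128, 64),
                        pcaDim = 200, pcaWhiten = 0.3, batchSize = 2,
                        maxEpochs = 30, seed = seed)
  pop <- samplePopulation(n, paramDistributions = intervalOnlyDistributions(),
                          outcomeModel = NULL, seed = seed)
  cohort <- simulateCohortBeats(pop$params, samplingRate = samplingRate)
  model <- trainBetaVAE(cohort, config)
  X <- beatMatrix(cohort)
  qcVal <- reconstructionQC(model, X[model@params$valIdx, , drop = FALSE],
                            threshold = config$qcThreshold)
  Z <- encode(model, cohort, standardize = TRUE)
  four <- c("ventricular_rate", "pr_interval", "qrs_duration", "qt_interval")
  r <- latentCorrelations(Z, pop$params[, four])
  list(maxAbsR = apply(abs(r), 2, max),
       meanHeldOutR = attr(qcVal, "meanR"),
       model = model, cohort = cohort, params = pop$params, qc = qcVal,
       correlations = r)
}
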