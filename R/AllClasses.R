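#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Standard 12-lead order used throughout the package.
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

## Frontal-plane angles (degrees) of the six limb leads.
LIMB_LEAD_ANGLES <- c(I = 0, II = 60, III = 120, aVR = -150, aVL = -30, aVF = 90)

#' GenerativeParams: ground-truth factors of a synthetic ECG
#'
#' Holds the generative parameters of one synthetic ECG: ventricular rate,
#' conduction intervals (PR, QRS, QT), frontal-plane electrical axes of the
#' P, R and T waves, per-wave amplitudes, baseline drift and noise level.
#' The same fields double as the "traditional ECG parameters" table used in
#' downstream association analyses.
#'
#' @slot ventricularRate beats per minute (> 0)
#' @slot prInterval PR interval in ms (P onset to QRS onset, >= 40)
#' @slot qrsDuration QRS duration in ms (> 0)
#' @slot qtInterval QT interval in ms (QRS onset to T offset, > qrsDuration)
#' @slot pAxis,rAxis,tAxis frontal-plane axes in degrees, in (-180, 180]
#' @slot waveAmplitudes named numeric, mV, names "P","Q","R","S","T"
#' @slot baselineSlope baseline drift slope in mV/s
#' @slot baselineOffset baseline offset in mV
#' @slot noiseSd white-noise standard deviation in mV (>= 0)
#' @exportClass GenerativeParams
setClass("GenerativeParams",
  representation(
    ventricularRate = "numeric",
    prInterval = "numeric",
    qrsDuration = "numeric",
    qtInterval = "numeric",
    pAxis = "numeric",
    rAxis = "numeric",
    tAxis = "numeric",
    waveAmplitudes = "numeric",
    baselineSlope = "numeric",
    baselineOffset = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("GenerativeParams", function(object) {
  msg <- character(0)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@ventricularRate) || object@ventricularRate <= 0)
    msg <- c(msg, "ventricularRate must be a single finite value > 0")
  if (!num1(object@prInterval) || object@prInterval < 40)
    msg <- c(msg, "prInterval must be >= 40 ms")
  if (!num1(object@qrsDuration) || object@qrsDuration <= 0)
    msg <- c(msg, "qrsDuration must be > 0")
  if (!num1(object@qtInterval) || object@qtInterval <= object@qrsDuration)
    msg <- c(msg, "qtInterval must exceed qrsDuration")
  for (ax in c("pAxis", "rAxis", "tAxis")) {
    v <- slot(object, ax)
    if (!num1(v) || v <= -180 || v > 180)
      msg <- c(msg, sprintf("%s must lie in (-180, 180]", ax))
  }
  if (!identical(sort(names(object@waveAmplitudes)), sort(c("P", "Q", "R", "S", "T"))) ||
      !all(is.finite(object@waveAmplitudes)))
    msg <- c(msg, "waveAmplitudes must be finite and named P, Q, R, S, T")
  if (!num1(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!num1(object@baselineSlope) || !num1(object@baselineOffset))
    msg <- c(msg, "baseline terms must be single finite values")
  if (length(msg)) msg else TRUE
})

#' MedianBeat: one aligned cardiac cycle
#'
#' A fixed-length 12 x T sample matrix (mV) holding one representative
#' cardiac cycle, pre-aligned on the R peak. This is the input/output object
#' of the variational autoencoder.
#'
#' @slot samples 12 x T numeric matrix in mV, rows in standard lead order
#' @slot samplingRate sampling rate in Hz
#' @slot rPeakIndex 0-based sample index of the R-wave peak
#' @slot leadNames the standard 12 lead names
#' @exportClass MedianBeat
setClass("MedianBeat",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    rPeakIndex = "integer",
    leadNames = "character"
  )
)

setValidity("MedianBeat", function(object) {
  msg <- character(0)
  if (nrow(object@samples) != 12L)
    msg <- c(msg, "samples must have 12 rows (leads)")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive value")
  if (length(object@rPeakIndex) != 1L ||
      object@rPeakIndex < 0L || object@rPeakIndex >= ncol(object@samples))
    msg <- c(msg, "rPeakIndex must satisfy 0 <= rPeakIndex < T")
  if (length(object@leadNames) != 12L)
    msg <- c(msg, "leadNames must have length 12")
  if (length(msg)) msg else TRUE
})

#' ECGRecord: a multi-beat rhythm strip
#'
#' A 12 x N matrix (mV) holding a continuous rhythm strip, by default 10 s.
#' The `meta` slot carries provenance such as the true R-peak sample indices
#' when the record was simulated.
#'
#' @slot samples 12 x N numeric matrix in mV
#' @slot samplingRate Hz
#' @slot duration seconds; N = duration * samplingRate
#' @slot meta list of provenance (e.g. `rPeaks`, true 0-based peak indices)
#' @exportClass ECGRecord
setClass("ECGRecord",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    duration = "numeric",
    meta = "list"
  ),
  prototype(meta = list())
)

setValidity("ECGRecord", function(object) {
  msg <- character(0)
  if (nrow(object@samples) != 12L)
    msg <- c(msg, "samples must have 12 rows")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  n <- round(object@duration * object@samplingRate)
  if (ncol(object@samples) != n)
    msg <- c(msg, "ncol(samples) must equal duration * samplingRate")
  if (length(msg)) msg else TRUE
})

#' ECGCohort: a cohort of aligned median beats with phenotypes
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The `"beats"` assay
#' stores one flattened median beat per column (leads stacked lead-major, so
#' the assay is (12*T) x n); `colData` holds per-subject phenotypes and,
#' for simulated cohorts, the ground-truth generative parameters. Metadata
#' records the sampling rate, beat length and R-peak alignment shared by the
#' whole cohort.
#'
#' @exportClass ECGCohort
setClass("ECGCohort", contains = "SummarizedExperiment")

setValidity("ECGCohort", function(object) {
  msg <- character(0)
  if (!"beats" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beats' is required")
  md <- S4Vectors::metadata(object)
  for (k in c("samplingRate", "beatLength", "rPeakIndex"))
    if (is.null(md[[k]])) msg <- c(msg, sprintf("metadata '%s' is required", k))
  if (is.null(md$beatLength) ||
      nrow(object) != 12L * md$beatLength)
    msg <- c(msg, "assay rows must equal 12 * beatLength")
  if (length(msg)) msg else TRUE
})

#' WeightMask: per-sample loss weights with an up-weighted QRS window
#'
#' Reconstruction-loss weights over the T samples of a median beat: weight
#' `qrsWeight` (default 10) inside the half-open QRS window `[onset, offset)`
#' and 1 elsewhere.
#'
#' @slot weights length-T numeric vector
#' @slot qrsWindow integer c(onset, offset), 0-based, half-open
#' @slot qrsWeight scalar weight applied inside the window
#' @exportClass WeightMask
setClass("WeightMask",
  representation(
    weights = "numeric",
    qrsWindow = "integer",
    qrsWeight = "numeric"
  )
)

setValidity("WeightMask", function(object) {
  msg <- character(0)
  on <- object@qrsWindow[1]; off <- object@qrsWindow[2]
  if (length(object@qrsWindow) != 2L || on >= off || on < 0L ||
      off > length(object@weights))
    msg <- c(msg, "qrsWindow must satisfy 0 <= onset < offset <= T")
  w <- unique(object@weights)
  if (!all(w %in% c(1, object@qrsWeight)))
    msg <- c(msg, "weights must take values in {1, qrsWeight}")
  if (length(msg)) msg else TRUE
})

#' BetaVAE: a trained beta variational autoencoder
#'
#' Model artifact produced by [trainBetaVAE()]: encoder/decoder weights,
#' the per-epoch training/validation loss history, the selected epoch
#' (lowest validation loss), and the cohort latent means/SDs used for
#' z-standardisation of the latent factors.
#'
#' @slot config the [vaeConfig()] list used for training
#' @slot params list of encoder/decoder weight matrices and biases
#' @slot history data.frame with columns epoch, train, validation
#' @slot selectedEpoch epoch whose weights are stored (argmin validation loss)
#' @slot latentMean,latentSd length-K standardisation statistics
#' @slot beatLength,samplingRate,rPeakIndex,leadNames geometry of the beats
#'   the model was trained on, used to rebuild [MedianBeat] objects on decode
#' @exportClass BetaVAE
setClass("BetaVAE",
  representation(
    config = "list",
    params = "list",
    history = "data.frame",
    selectedEpoch = "integer",
    latentMean = "numeric",
    latentSd = "numeric",
    beatLength = "integer",
    samplingRate = "numeric",
    rPeakIndex = "integer",
    leadNames = "character"
  )
)

setValidity("BetaVAE", function(object) {
  msg <- character(0)
  k <- object@config$latentDim
  if (length(object@latentMean) != k || length(object@latentSd) != k)
    msg <- c(msg, "standardisation statistics must have length latentDim")
  if (nrow(object@history) &&
      !identical(object@selectedEpoch,
                 as.integer(object@history$epoch[which.min(object@history$validation)])))
    msg <- c(msg, "selectedEpoch must be the epoch with minimal validation loss")
  if (length(msg)) msg else TRUE
})

#' FactorTraversal: decoded beats along one latent factor
#'
#' Median beats decoded while one latent factor sweeps a grid of
#' standardised values (default -3 to 3) with all other factors held at 0.
#'
#' @slot factorIndex which latent factor was traversed (1..K)
#' @slot grid strictly increasing grid of standardised latent values
#' @slot beats list of [MedianBeat], one per grid value
#' @exportClass FactorTraversal
setClass("FactorTraversal",
  representation(
    factorIndex = "integer",
    grid = "numeric",
    beats = "list"
  )
)

setValidity("FactorTraversal", function(object) {
  msg <- character(0)
  if (is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(object@beats) != length(object@grid))
    msg <- c(msg, "one decoded beat per grid value is required")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: biallelic dosages with planted effects
#'
#' Hardy-Weinberg dosages in \{0,1,2\} for m variants in n subjects, the
#' minor-allele frequencies they were drawn with, and the ground-truth
#' additive per-allele effects on generative ECG parameters.
#'
#' @slot dosages n x m matrix with values in \{0,1,2\}; columns named by variant
#' @slot mafs per-variant minor-allele frequency in (0, 0.5]
#' @slot trueEffects named list: variant id -> named numeric
#'   (generative parameter -> per-allele additive shift)
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    dosages = "matrix",
    mafs = "numeric",
    trueEffects = "list"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@dosages) != length(object@mafs))
    msg <- c(msg, "one maf per variant column is required")
  if (length(object@mafs) && (any(object@mafs <= 0) || any(object@mafs > 0.5)))
    msg <- c(msg, "mafs must lie in (0, 0.5]")
  if (length(object@dosages) && !all(object@dosages %in% 0:2))
    msg <- c(msg, "dosages must take values in {0, 1, 2}")
  if (length(msg)) msg else TRUE
})

#' VariantEffectProfile: per-factor effect sizes of one variant
#'
#' Per-latent-factor effect sizes (on the original, unstandardised latent
#' scale) and p-values for one genetic variant, plus the allele-dose
#' multiplier applied when the profile perturbs the average latent vector.
#'
#' @slot variantId variant identifier
#' @slot effects length-K effects on the original latent scale
#' @slot pValues length-K association p-values
#' @slot dose allele-count multiplier (default 1)
#' @exportClass VariantEffectProfile
setClass("VariantEffectProfile",
  representation(
    variantId = "character",
    effects = "numeric",
    pValues = "numeric",
    dose = "numeric"
  ),
  prototype(dose = 1)
)

setValidity("VariantEffectProfile", function(object) {
  msg <- character(0)
  if (length(object@effects) != length(object@pValues))
    msg <- c(msg, "effects and pValues must have the same length")
  if (!all(is.finite(object@effects)))
    msg <- c(msg, "effects must be finite")
  if (length(object@pValues) &&
      (any(object@pValues < 0) || any(object@pValues > 1)))
    msg <- c(msg, "pValues must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
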