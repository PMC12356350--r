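#' Construct a GenerativeParams object
#'
#' Defaults describe a normal resting adult ECG: 65 bpm, PR 160 ms, QRS 90 ms,
#' QT 400 ms, axes in the normal quadrant, dominant R wave of 1 mV.
#'
#' @param ventricularRate beats/min
#' @param prInterval,qrsDuration,qtInterval intervals in ms
#' @param pAxis,rAxis,tAxis frontal-plane axes in degrees, (-180, 180]
#' @param waveAmplitudes named numeric (P, Q, R, S, T) in mV
#' @param baselineSlope baseline drift in mV/s
#' @param baselineOffset baseline offset in mV
#' @param noiseSd white-noise SD in mV
#' @return a [GenerativeParams-class] object
#' @examples
#' p <- generativeParams(ventricularRate = 72)
#' p
#' @export
generativeParams <- function(ventricularRate = 65,
                             prInterval = 160,
                             qrsDuration = 90,
                             qtInterval = 400,
                             pAxis = 45, rAxis = 30, tAxis = 40,
                             waveAmplitudes = c(P = 0.15, Q = -0.1, R = 1,
                                                S = -0.25, T = 0.3),
                             baselineSlope = 0,
                             baselineOffset = 0,
                             noiseSd = 0) {
  new("GenerativeParams",
      ventricularRate = as.numeric(ventricularRate),
      prInterval = as.numeric(prInterval),
      qrsDuration = as.numeric(qrsDuration),
      qtInterval = as.numeric(qtInterval),
      pAxis = as.numeric(pAxis), rAxis = as.numeric(rAxis),
      tAxis = as.numeric(tAxis),
      waveAmplitudes = waveAmplitudes[c("P", "Q", "R", "S", "T")],
      baselineSlope = as.numeric(baselineSlope),
      baselineOffset = as.numeric(baselineOffset),
      noiseSd = as.numeric(noiseSd))
}

#' Construct a MedianBeat
#'
#' @param samples 12 x T numeric matrix, mV
#' @param samplingRate Hz
#' @param rPeakIndex 0-based R-peak sample index
#' @param leadNames lead names; defaults to the standard 12
#' @return a [MedianBeat-class]
#' @export
medianBeat <- function(samples, samplingRate = 500, rPeakIndex,
                       leadNames = ECG_LEADS) {
  new("MedianBeat", samples = samples, samplingRate = samplingRate,
      rPeakIndex = as.integer(rPeakIndex), leadNames = leadNames)
}

#' Sample matrix of an ECG object
#'
#' @param x a [MedianBeat-class] or [ECGRecord-class]
#' @return the 12 x T numeric matrix of samples in mV
#' @export
#' @aliases beatSamples,MedianBeat-method beatSamples,ECGRecord-method
setMethod("beatSamples", "MedianBeat", function(x) x@samples)
setMethod("beatSamples", "ECGRecord", function(x) x@samples)

#' Sampling rate accessor
#' @param x a beat, record, cohort or model object
#' @return sampling rate in Hz
#' @export
#' @aliases samplingRate,MedianBeat-method samplingRate,ECGRecord-method
#'   samplingRate,ECGCohort-method samplingRate,BetaVAE-method
setMethod("samplingRate", "MedianBeat", function(x) x@samplingRate)
setMethod("samplingRate", "ECGRecord", function(x) x@samplingRate)
setMethod("samplingRate", "ECGCohort",
          function(x) S4Vectors::metadata(x)$samplingRate)
setMethod("samplingRate", "BetaVAE", function(x) x@samplingRate)

#' R-peak alignment index accessor
#' @param x a [MedianBeat-class] or [ECGCohort-class]
#' @return 0-based sample index of the R peak
#' @export
#' @aliases rPeakIndex,MedianBeat-method rPeakIndex,ECGCohort-method
setMethod("rPeakIndex", "MedianBeat", function(x) x@rPeakIndex)
setMethod("rPeakIndex", "ECGCohort",
          function(x) S4Vectors::metadata(x)$rPeakIndex)

#' Lead names accessor
#' @param x a [MedianBeat-class] or [ECGCohort-class]
#' @return character vector of the 12 lead names
#' @export
#' @aliases leadNames,MedianBeat-method leadNames,ECGCohort-method
setMethod("leadNames", "MedianBeat", function(x) x@leadNames)
setMethod("leadNames", "ECGCohort", function(x) {
  ln <- S4Vectors::metadata(x)$leadNames
  if (is.null(ln)) ECG_LEADS else ln
})

#' Latent dimension of a model
#' @param x a [BetaVAE-class]
#' @return number of latent factors K
#' @export
#' @aliases latentDim,BetaVAE-method
setMethod("latentDim", "BetaVAE", function(x) as.integer(x@config$latentDim))

#' Training history of a BetaVAE
#' @param model a [BetaVAE-class]
#' @return data.frame with columns epoch, train, validation
#' @export
trainingHistory <- function(model) model@history

#' Selected training epoch (lowest validation loss)
#' @param model a [BetaVAE-class]
#' @return integer epoch
#' @export
selectedEpoch <- function(model) model@selectedEpoch

#' Cohort latent standardisation statistics
#' @param model a [BetaVAE-class]
#' @return list with `mean` and `sd`, each length K
#' @export
latentStats <- function(model) list(mean = model@latentMean, sd = model@latentSd)

#' Assemble an ECGCohort from median beats
#'
#' Flattens each beat lead-major into one column of the `"beats"` assay and
#' attaches per-subject phenotypes / generative parameters as `colData`.
#'
#' @param beats list of [MedianBeat-class], all with identical geometry, or a
#'   (12*T) x n matrix of already-flattened beats
#' @param colData data.frame of per-subject covariates (optional)
#' @param samplingRate,rPeakIndex required when `beats` is a matrix
#' @return an [ECGCohort-class]
#' @export
beatCohort <- function(beats, colData = NULL, samplingRate = NULL,
                       rPeakIndex = NULL) {
  if (is.list(beats)) {
    stopifnot(length(beats) >= 1L)
    tlen <- ncol(beatSamples(beats[[1]]))
    mat <- vapply(beats, function(b) {
      stopifnot(ncol(beatSamples(b)) == tlen)
      as.vector(t(beatSamples(b)))   # lead-major: lead I samples first
    }, numeric(12L * tlen))
    samplingRate <- samplingRate(beats[[1]])
    rPeakIndex <- rPeakIndex(beats[[1]])
    leadNm <- leadNames(beats[[1]])
  } else {
    mat <- beats
    stopifnot(!is.null(samplingRate), !is.null(rPeakIndex),
              nrow(mat) %% 12L == 0L)
    tlen <- nrow(mat) %/% 12L
    leadNm <- ECG_LEADS
  }
  if (is.null(colData)) colData <- S4Vectors::DataFrame(row.names = seq_len(ncol(mat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beats = mat),
    colData = S4Vectors::DataFrame(colData),
    metadata = list(samplingRate = samplingRate,
                    beatLength = as.integer(tlen),
                    rPeakIndex = as.integer(rPeakIndex),
                    leadNames = leadNm))
  as(se, "ECGCohort")
}

#' Extract one median beat from a cohort
#'
#' @param cohort an [ECGCohort-class]
#' @param i column index
#' @return a [MedianBeat-class]
#' @export
getBeat <- function(cohort, i) {
  md <- S4Vectors::metadata(cohort)
  v <- SummarizedExperiment::assay(cohort, "beats")[, i]
  m <- matrix(v, nrow = 12L, byrow = TRUE)
  rownames(m) <- leadNames(cohort)
  medianBeat(m, samplingRate = md$samplingRate, rPeakIndex = md$rPeakIndex,
             leadNames = leadNames(cohort))
}

#' Beat matrix of a cohort, records in rows
#'
#' @param cohort an [ECGCohort-class]
#' @return n x (12*T) matrix, one flattened beat per row
#' @export
beatMatrix <- function(cohort) t(SummarizedExperiment::assay(cohort, "beats"))

setMethod("show", "GenerativeParams", function(object) {
  cat("GenerativeParams\n")
  cat(sprintf("  rate %.1f bpm | PR %.0f ms | QRS %.0f ms | QT %.0f ms\n",
              object@ventricularRate, object@prInterval,
              object@qrsDuration, object@qtInterval))
  cat(sprintf("  axes (P/R/T): %.0f / %.0f / %.0f deg\n",
              object@pAxis, object@rAxis, object@tAxis))
  cat("  amplitudes (mV):",
      paste(sprintf("%s=%.2f", names(object@waveAmplitudes),
                    object@waveAmplitudes), collapse = " "), "\n")
})

setMethod("show", "MedianBeat", function(object) {
  cat(sprintf("MedianBeat: 12 x %d samples @ %g Hz, R peak at sample %d\n",
              ncol(object@samples), object@samplingRate, object@rPeakIndex))
})

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord: 12 x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@samples), object@samplingRate, object@duration))
})

setMethod("show", "BetaVAE", function(object) {
  cat(sprintf("BetaVAE: K = %d, beta = %g, input 12 x %d\n",
              object@config$latentDim, object@config$beta, object@beatLength))
  cat(sprintf("  trained %d epochs, selected epoch %d (validation loss %.5g)\n",
              max(object@history$epoch), object@selectedEpoch,
              min(object@history$validation)))
})

setMethod("show", "FactorTraversal", function(object) {
  cat(sprintf("FactorTraversal of factor %d over [%g, %g] (%d beats)\n",
              object@factorIndex, min(object@grid), max(object@grid),
              length(object@grid)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d subjects x %d variants, %d with planted effects\n",
              nrow(object@dosages), ncol(object@dosages),
              length(object@trueEffects)))
})

#' Dosage matrix accessor
#' @param geno a [GenotypeMatrix-class]
#' @return n x m dosage matrix
#' @export
dosages <- function(geno) geno@dosages

#' Ground-truth variant effects accessor
#' @param geno a [GenotypeMatrix-class]
#' @return named list of per-allele effects on generative parameters
#' @export
trueEffects <- function(geno) geno@trueEffects

#' Construct a VariantEffectProfile
#'
#' @param variantId variant identifier
#' @param effects per-factor effect sizes on the original latent scale
#' @param pValues per-factor p-values
#' @param dose allele-count multiplier
#' @return a [VariantEffectProfile-class]
#' @export
variantEffectProfile <- function(variantId, effects, pValues, dose = 1) {
  new("VariantEffectProfile", variantId = as.character(variantId),
      effects = as.numeric(effects), pValues = as.numeric(pValues),
      dose = as.numeric(dose))
}
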