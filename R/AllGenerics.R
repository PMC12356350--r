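#' @rdname beatSamples
#' @export
setGeneric("beatSamples", function(x) standardGeneric("beatSamples"))

#' @rdname samplingRate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname rPeakIndex
#' @export
setGeneric("rPeakIndex", function(x) standardGeneric("rPeakIndex"))

#' @rdname leadNames
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))

#' @rdname latentDim
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname encode
#' @export
setGeneric("encode", function(model, x, standardize = TRUE)
  standardGeneric("encode"))

#' @rdname decodeLatent
#' @export
setGeneric("decodeLatent", function(model, z, standardized = TRUE)
  standardGeneric("decodeLatent"))
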