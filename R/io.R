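#' Write a median beat or rhythm strip as a plain numeric matrix file
#'
#' One row per lead, tab-separated, preceded by `#`-prefixed metadata lines
#' (sampling rate, R-peak index, lead names) so the file round-trips.
#'
#' @param x a [MedianBeat-class] or [ECGRecord-class]
#' @param file output path
#' @export
writeBeatMatrix <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# samplingRate\t%g", samplingRate(x)), con)
  if (is(x, "MedianBeat")) {
    writeLines(sprintf("# rPeakIndex\t%d", rPeakIndex(x)), con)
    writeLines(paste0("# leads\t", paste(leadNames(x), collapse = "\t")), con)
  } else {
    writeLines(sprintf("# duration\t%g", x@duration), con)
  }
  utils::write.table(beatSamples(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a median beat written by [writeBeatMatrix()]
#'
#' @param file path to a beat matrix file
#' @return a [MedianBeat-class]
#' @export
readBeatMatrix <- function(file) {
  hdr <- readLines(file, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  kv <- lapply(strsplit(sub("^# ", "", meta), "\t"), identity)
  names(kv) <- vapply(kv, `[`, "", 1)
  m <- as.matrix(utils::read.table(file, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  leads <- if ("leads" %in% names(kv)) kv$leads[-1] else ECG_LEADS
  rownames(m) <- leads
  medianBeat(m, samplingRate = as.numeric(kv$samplingRate[2]),
             rPeakIndex = as.integer(kv$rPeakIndex[2]), leadNames = leads)
}

#' Write latent factors (or any per-subject table) as TSV
#'
#' @param x matrix or data.frame, one row per subject
#' @param file output path
#' @export
writeTableTSV <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a TSV written by [writeTableTSV()]
#' @param file path
#' @return data.frame
#' @export
readTableTSV <- function(file)
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Write ground-truth generating coefficients as YAML
#'
#' @param truth the `truth` element returned by [samplePopulation()]
#' @param file output path
#' @export
writeTruthYAML <- function(truth, file) yaml::write_yaml(truth, file)

#' Read ground truth written by [writeTruthYAML()]
#' @param file path
#' @return list
#' @export
readTruthYAML <- function(file) yaml::read_yaml(file)
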