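#' Detect R peaks in a rhythm strip
#'
#' Pan-Tompkins-style detector on a single lead: 5-15 Hz band-pass,
#' differentiate, square, moving-window integrate (150 ms), threshold at a
#' fraction of the upper envelope, then local-maximum refinement on the raw
#' signal with a 200 ms refractory period.
#'
#' A flat or all-noise record yields an empty index vector with attribute
#' `flag = "no-peaks"` and a warning, never an error.
#'
#' @param record an [ECGRecord-class], at least 2 s long
#' @param lead lead name to detect on (default `"II"`)
#' @return sorted 0-based sample indices of detected R peaks (integer);
#'   possibly empty, with attribute `flag` when detection failed
#' @examples
#' r <- simulateRhythmStrip(generativeParams(ventricularRate = 60), seed = 1)
#' detectRPeaks(r)
#' @export
detectRPeaks <- function(record, lead = "II") {
  stopifnot(is(record, "ECGRecord"))
  if (record@duration < 2) stop("record must be at least 2 s long")
  fs <- record@samplingRate
  x <- beatSamples(record)[match(lead, ECG_LEADS), ]
  if (stats::sd(x) < 1e-9) {
    out <- integer(0); attr(out, "flag") <- "no-peaks"
    warning("flat signal: no R peaks detected")
    return(out)
  }
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  win <- max(1L, round(0.15 * fs))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.25 * stats::quantile(integ, 0.995)
  above <- integ > thr
  if (!any(above)) {
    out <- integer(0); attr(out, "flag") <- "no-peaks"
    warning("no samples cross the detection threshold")
    return(out)
  }
  ## candidate regions -> refine to local max of |band-passed| signal
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  refractory <- round(0.2 * fs)
  half <- round(0.06 * fs)
  peaks <- integer(0)
  for (i in which(runs$values)) {
    centre <- which.max(integ[starts[i]:ends[i]]) + starts[i] - 1L
    lo <- max(1L, centre - half); hi <- min(length(x), centre + half)
    p <- which.max(abs(xf[lo:hi])) + lo - 1L
    if (!length(peaks) || p - peaks[length(peaks)] >= refractory)
      peaks <- c(peaks, p)
  }
  as.integer(peaks - 1L)   # 0-based
}

#' Compute a median beat from a rhythm strip
#'
#' Extracts the half-open window `[peak - preMs, peak + postMs)` around each
#' R peak, drops beats whose window is truncated by the record edges, and
#' takes the per-lead, per-sample median across the remaining beats. With an
#' even number of beats the median is the mean of the two middle order
#' statistics.
#'
#' @param record an [ECGRecord-class]
#' @param peaks 0-based R-peak sample indices (e.g. from [detectRPeaks()])
#' @param preMs window extent before the R peak, ms (default 400)
#' @param postMs window extent after the R peak, ms (default 800)
#' @return a [MedianBeat-class] with `rPeakIndex = preMs` in samples
#' @export
computeMedianBeat <- function(record, peaks, preMs = 400, postMs = 800) {
  fs <- record@samplingRate
  pre <- round(preMs / 1000 * fs)
  post <- round(postMs / 1000 * fs)
  n <- ncol(beatSamples(record))
  peaks <- as.integer(peaks)
  usable <- peaks[peaks - pre >= 0L & peaks + post <= n]
  if (length(usable) < 3L)
    stop(sprintf("only %d usable beat(s); at least 3 are required",
                 length(usable)))
  tlen <- pre + post
  arr <- array(NA_real_, dim = c(12L, tlen, length(usable)))
  for (k in seq_along(usable)) {
    from <- usable[k] - pre + 1L   # 1-based start
    arr[, , k] <- beatSamples(record)[, from:(from + tlen - 1L)]
  }
  med <- apply(arr, c(1, 2), stats::median)
  rownames(med) <- ECG_LEADS
  medianBeat(med, samplingRate = fs, rPeakIndex = pre)
}

#' Remove first-order baseline wander from a median beat
#'
#' Per lead, subtracts the least-squares straight line fitted to that lead's
#' full trace. Idempotent; a pure line maps to zero.
#'
#' @param beat a [MedianBeat-class]
#' @return the baseline-corrected [MedianBeat-class]
#' @export
removeBaseline <- function(beat) {
  m <- beatSamples(beat)
  tlen <- ncol(m)
  t0 <- seq_len(tlen) - 1
  tc <- t0 - mean(t0)
  denom <- sum(tc^2)
  ## closed-form per-lead linear fit: y - (a + b t)
  b <- (m %*% tc) / denom
  a <- rowMeans(m)
  corrected <- m - (a %o% rep(1, tlen)) - (as.vector(b) %o% tc)
  rownames(corrected) <- rownames(m)
  medianBeat(corrected, samplingRate = beat@samplingRate,
             rPeakIndex = beat@rPeakIndex, leadNames = beat@leadNames)
}

#' Build a QRS weight mask
#'
#' Per-sample reconstruction-loss weights: `qrsWeight` (default 10) inside
#' the half-open QRS window `[onset, offset)` and 1 elsewhere, reflecting
#' up-weighting of QRS samples during representation learning.
#'
#' @param tlen beat length in samples, or a [MedianBeat-class]
#' @param qrsWindow integer `c(onset, offset)`, 0-based half-open
#' @param qrsWeight weight applied inside the window (default 10)
#' @return a [WeightMask-class]
#' @examples
#' m <- qrsWeightMask(600, c(100, 160))
#' sum(m@weights)  # 60 * 10 + 540 * 1
#' @export
qrsWeightMask <- function(tlen, qrsWindow, qrsWeight = 10) {
  if (is(tlen, "MedianBeat")) tlen <- ncol(beatSamples(tlen))
  on <- qrsWindow[1]; off <- qrsWindow[2]
  if (on < 0 || on >= off || off > tlen)
    stop("qrsWindow must satisfy 0 <= onset < offset <= T")
  w <- rep(1, tlen)
  w[(on + 1):off] <- qrsWeight   # 0-based half-open [on, off)
  new("WeightMask", weights = w, qrsWindow = as.integer(qrsWindow),
      qrsWeight = qrsWeight)
}

#' Full strip-to-beat preprocessing for one record
#'
#' Convenience pipeline: detect R peaks, take the per-sample median beat and
#' remove first-order baseline wander.
#'
#' @param record an [ECGRecord-class]
#' @param lead detection lead
#' @param preMs,postMs median-beat window, ms
#' @return a [MedianBeat-class]
#' @export
preprocessRecord <- function(record, lead = "II", preMs = 400, postMs = 800) {
  peaks <- detectRPeaks(record, lead = lead)
  removeBaseline(computeMedianBeat(record, peaks, preMs = preMs,
                                   postMs = postMs))
}
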