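## Default projection gains of the precordial leads V1-V6. Frontal-plane
## axes drive the limb leads; the chest leads get a fixed gain vector that
## sketches normal R-wave progression.
PRECORDIAL_GAINS <- c(V1 = -0.35, V2 = -0.1, V3 = 0.25,
                      V4 = 0.7, V5 = 1.0, V6 = 0.85)

## Wave layout (ms) relative to the QRS geometry. Widths are the Gaussian
## SDs; P and T have fixed durations, Q/R/S scale with the QRS duration.
P_DURATION_MS <- 110
T_DURATION_MS <- 180

## Per-wave centres and SDs in ms, given interval parameters and the R time.
waveLayout <- function(params, rPeakMs) {
  qrs <- params@qrsDuration
  qrsOnset <- rPeakMs - qrs / 2
  pOnset <- qrsOnset - params@prInterval
  tOffset <- qrsOnset + params@qtInterval
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    center = c(pOnset + P_DURATION_MS / 2,
               rPeakMs - 0.35 * qrs,
               rPeakMs,
               rPeakMs + 0.35 * qrs,
               tOffset - T_DURATION_MS / 2),
    sd = c(P_DURATION_MS / 5, qrs / 12, qrs / 7, qrs / 12, T_DURATION_MS / 4.5),
    axis = c(params@pAxis, params@rAxis, params@rAxis, params@rAxis,
             params@tAxis),
    amplitude = unname(params@waveAmplitudes[c("P", "Q", "R", "S", "T")]),
    stringsAsFactors = FALSE)
}

## 12-vector of per-lead gains for a wave with a given frontal axis: limb
## leads project by the cosine of the angle between lead and axis, chest
## leads use the fixed gain vector.
leadProjection <- function(axisDeg, precordialGains = PRECORDIAL_GAINS) {
  c(cos((LIMB_LEAD_ANGLES - axisDeg) * pi / 180), precordialGains)
}

## Deterministic 12 x length(tMs) wave-sum matrix for a beat whose R peak
## sits at rCenterMs on the supplied time grid.
beatWaveMatrix <- function(params, tMs, rCenterMs,
                           precordialGains = PRECORDIAL_GAINS) {
  layout <- waveLayout(params, rCenterMs)
  out <- matrix(0, nrow = 12L, ncol = length(tMs))
  for (i in seq_len(nrow(layout))) {
    g <- exp(-0.5 * ((tMs - layout$center[i]) / layout$sd[i])^2)
    proj <- layout$amplitude[i] * leadProjection(layout$axis[i], precordialGains)
    out <- out + proj %o% g
  }
  rownames(out) <- ECG_LEADS
  out
}

#' Simulate a 12-lead median beat from generative parameters
#'
#' Deterministic sum-of-Gaussians beat model: P, Q, R, S and T waves are
#' Gaussian bumps whose centres and widths derive from the PR interval, QRS
#' duration and QT interval, and whose per-lead amplitudes are the wave
#' amplitude times the projection of the wave's frontal axis onto the limb
#' leads (I at 0 degrees, II at 60, III at 120, aVR at -150, aVL at -30,
#' aVF at 90) and a fixed gain vector for V1-V6. The output is noise- and
#' baseline-free; noise and drift belong to [simulateRhythmStrip()].
#'
#' @param params a [GenerativeParams-class]
#' @param lengthMs beat window length in ms (default 1200, i.e. 600 samples
#'   at 500 Hz)
#' @param samplingRate Hz (default 500)
#' @param rPeakMs position of the R peak inside the window, ms (default 400)
#' @param precordialGains length-6 gain vector for V1-V6
#' @return a [MedianBeat-class] with `rPeakIndex` at the R-wave centre
#' @examples
#' b <- simulateMedianBeat(generativeParams())
#' dim(beatSamples(b))
#' @export
simulateMedianBeat <- function(params, lengthMs = 1200, samplingRate = 500,
                               rPeakMs = 400,
                               precordialGains = PRECORDIAL_GAINS) {
  validObject(params)
  qrsOnset <- rPeakMs - params@qrsDuration / 2
  pOnset <- qrsOnset - params@prInterval
  tOffset <- qrsOnset + params@qtInterval
  if (pOnset < 0 || tOffset > lengthMs)
    stop(sprintf(paste0("beat window [0, %g] ms cannot contain the beat: ",
                        "P onset at %g ms, T offset at %g ms"),
                 lengthMs, pOnset, tOffset))
  tlen <- round(lengthMs / 1000 * samplingRate)
  tMs <- (seq_len(tlen) - 1) / samplingRate * 1000
  ## The fixed-length window also shows the tails of the adjacent beats at
  ## +/- RR (and beyond), exactly as a vendor median beat does; this is how
  ## ventricular rate leaves a morphological trace in an aligned beat.
  rrMs <- 60000 / params@ventricularRate
  m <- matrix(0, nrow = 12L, ncol = tlen, dimnames = list(ECG_LEADS, NULL))
  for (k in -3:3) {
    centre <- rPeakMs + k * rrMs
    if (centre > -2000 && centre < lengthMs + 2000)
      m <- m + beatWaveMatrix(params, tMs, rCenterMs = centre,
                              precordialGains = precordialGains)
  }
  medianBeat(m, samplingRate = samplingRate,
             rPeakIndex = round(rPeakMs / 1000 * samplingRate))
}

#' Simulate a multi-beat rhythm strip
#'
#' Places a train of beats at mean RR interval 60/rate seconds with Gaussian
#' RR jitter, adds linear baseline drift (`baselineSlope * t +
#' baselineOffset`, identical in every lead) and white Gaussian noise of SD
#' `noiseSd`. Reproducible: the output is a pure function of the inputs and
#' `seed`. The true R-peak sample indices are recorded in `meta$rPeaks`.
#'
#' @param params a [GenerativeParams-class]
#' @param duration strip length in seconds (default 10)
#' @param rrJitterSd SD of the per-interval RR jitter in seconds
#' @param seed RNG seed
#' @param samplingRate Hz
#' @param precordialGains length-6 gain vector for V1-V6
#' @return an [ECGRecord-class]; `meta(record)$rPeaks` holds the true
#'   0-based R-peak indices
#' @examples
#' r <- simulateRhythmStrip(generativeParams(ventricularRate = 60), seed = 1)
#' length(r@meta$rPeaks)  # 10 beats in 10 s at 60 bpm
#' @export
simulateRhythmStrip <- function(params, duration = 10, rrJitterSd = 0,
                                seed = 1, samplingRate = 500,
                                precordialGains = PRECORDIAL_GAINS) {
  validObject(params)
  rr <- 60 / params@ventricularRate
  nBeats <- floor((duration - rr / 2) / rr) + 1
  if (nBeats < 2)
    stop(sprintf("rate %g bpm yields %d beat(s) in %g s; need at least 2",
                 params@ventricularRate, nBeats, duration))
  set.seed(seed)
  gaps <- rep(rr, nBeats - 1) +
    if (rrJitterSd > 0) stats::rnorm(nBeats - 1, 0, rrJitterSd) else 0
  rTimes <- rr / 2 + c(0, cumsum(gaps))
  rTimes <- rTimes[rTimes >= 0 & rTimes < duration]
  n <- round(duration * samplingRate)
  tSec <- (seq_len(n) - 1) / samplingRate
  tMs <- tSec * 1000
  m <- matrix(0, nrow = 12L, ncol = n, dimnames = list(ECG_LEADS, NULL))
  for (rt in rTimes)
    m <- m + beatWaveMatrix(params, tMs, rCenterMs = rt * 1000,
                            precordialGains = precordialGains)
  baseline <- params@baselineOffset + params@baselineSlope * tSec
  m <- m + rep(baseline, each = 12L)
  if (params@noiseSd > 0)
    m <- m + matrix(stats::rnorm(12L * n, 0, params@noiseSd), nrow = 12L)
  new("ECGRecord", samples = m, samplingRate = samplingRate,
      duration = duration,
      meta = list(rPeaks = round(rTimes * samplingRate), seed = seed))
}
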