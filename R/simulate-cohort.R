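#' Default marginal distributions of the generative parameters
#'
#' Each entry is a truncated Normal given as `list(mean, sd, min, max)`.
#' Ages follow Normal(64.6, 7.73) truncated to 40-80 years, matching the
#' summary statistics of a typical imaging-substudy cohort of older adults;
#' interval and amplitude ranges span normal resting ECG variation.
#'
#' @return named list of distribution specifications, including `age`
#' @export
defaultParamDistributions <- function() {
  list(
    ventricular_rate = list(mean = 65,  sd = 10,   min = 40,   max = 120),
    pr_interval      = list(mean = 160, sd = 18,   min = 100,  max = 240),
    qrs_duration     = list(mean = 90,  sd = 10,   min = 60,   max = 140),
    qt_interval      = list(mean = 400, sd = 25,   min = 320,  max = 500),
    p_axis           = list(mean = 45,  sd = 20,   min = -60,  max = 130),
    r_axis           = list(mean = 30,  sd = 30,   min = -90,  max = 150),
    t_axis           = list(mean = 40,  sd = 20,   min = -60,  max = 130),
    amp_P            = list(mean = 0.15,  sd = 0.03, min = 0.02, max = 0.4),
    amp_Q            = list(mean = -0.10, sd = 0.03, min = -0.3, max = -0.01),
    amp_R            = list(mean = 1.0,   sd = 0.2,  min = 0.3,  max = 2.0),
    amp_S            = list(mean = -0.25, sd = 0.07, min = -0.8, max = -0.02),
    amp_T            = list(mean = 0.30,  sd = 0.07, min = 0.05, max = 0.8),
    baseline_slope   = list(mean = 0, sd = 0.02, min = -0.1, max = 0.1),
    baseline_offset  = list(mean = 0, sd = 0.05, min = -0.3, max = 0.3),
    noise_sd         = list(mean = 0.02, sd = 0, min = 0, max = 1),
    age              = list(mean = 64.6, sd = 7.73, min = 40, max = 80)
  )
}

#' Default outcome-generating model
#'
#' Continuous outcomes emulate CMR-derived structure/function measures as
#' linear combinations of standardised generative parameters, age and sex
#' plus Gaussian noise; binary outcomes follow a logistic model on the same
#' predictors; survival follows exponential proportional hazards. Slopes on
#' generative parameters and age are per SD of the generating distribution;
#' sex (0 = female, 1 = male) enters untransformed.
#'
#' @return list with elements `continuous`, `binary`, `survival`
#' @export
defaultOutcomeModel <- function() {
  list(
    continuous = list(
      lvedm = list(intercept = 89, coef = c(qrs_duration = 6, amp_R = 3,
                                            age = 2, sex = 14), noiseSd = 10),
      lvef  = list(intercept = 58, coef = c(qt_interval = -1.5,
                                            ventricular_rate = -1, sex = -2),
                   noiseSd = 4),
      lvsv  = list(intercept = 85, coef = c(ventricular_rate = -4,
                                            qt_interval = 2, sex = 12),
                   noiseSd = 9)
    ),
    binary = list(
      hypertension = list(intercept = -0.8,
                          coef = c(age = 0.6, ventricular_rate = 0.25,
                                   sex = 0.2)),
      atrial_fibrillation = list(intercept = -3.2,
                                 coef = c(pr_interval = 0.7,
                                          ventricular_rate = 0.4, age = 0.5)),
      bundle_branch_block = list(intercept = -3.5,
                                 coef = c(qrs_duration = 1.2, age = 0.3))
    ),
    survival = list(coef = c(ventricular_rate = 0.25, qt_interval = 0.2,
                             age = 0.7),
                    baselineHazard = 0.008, followUp = 5)
  )
}

## Draw an n x p matrix of truncated normals with optional correlation among
## columns. Truncation is by per-entry rejection resampling (independent
## redraws; the stated correlation applies to the untruncated scale).
drawTruncatedNormals <- function(n, dists, correlation = NULL) {
  nms <- names(dists)
  p <- length(nms)
  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nms))
  if (!is.null(correlation)) {
    cn <- colnames(correlation)
    if (is.null(cn) || !all(cn %in% nms))
      stop("correlation matrix must be named by generative parameters")
    full <- diag(p); dimnames(full) <- list(nms, nms)
    full[cn, cn] <- correlation
    correlation <- full
    ev <- eigen(correlation, symmetric = TRUE)
    if (min(ev$values) < -1e-8)
      stop("correlation matrix is not positive semi-definite")
    sqrtR <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    z <- z %*% sqrtR
    colnames(z) <- nms
  }
  out <- z
  for (j in nms) {
    d <- dists[[j]]
    x <- d$mean + d$sd * z[, j]
    if (d$sd > 0) {
      for (iter in 1:50) {
        bad <- which(x < d$min | x > d$max)
        if (!length(bad)) break
        x[bad] <- d$mean + d$sd * stats::rnorm(length(bad))
      }
    }
    out[, j] <- pmin(pmax(x, d$min), d$max)
  }
  out
}

## Standardise predictors named in `coef` against the generating
## distributions; sex stays on its 0/1 coding.
linearPredictor <- function(coef, paramsDf, age, sex, dists) {
  lp <- numeric(length(age))
  for (nm in names(coef)) {
    v <- switch(nm,
      age = (age - dists$age$mean) / dists$age$sd,
      sex = sex,
      {
        d <- dists[[nm]]
        if (is.null(d)) stop(sprintf("unknown predictor '%s'", nm))
        s <- if (d$sd > 0) d$sd else 1
        (paramsDf[[nm]] - d$mean) / s
      })
    lp <- lp + coef[[nm]] * v
  }
  lp
}

#' Sample a synthetic cohort of generative parameters and phenotypes
#'
#' Draws per-subject generative ECG parameters from (optionally correlated)
#' truncated normals, ages from a truncated Normal, sex from a Bernoulli
#' (default 51.6% female), and generates continuous, binary and survival
#' outcomes from the supplied generating model. All generating coefficients
#' are returned as ground truth.
#'
#' @param n number of subjects
#' @param paramDistributions named list as [defaultParamDistributions()]
#' @param outcomeModel list as [defaultOutcomeModel()]; any of the three
#'   components may be `NULL` to skip that outcome class
#' @param seed RNG seed
#' @param sexMaleProb probability of sex = 1 (male)
#' @param correlation optional correlation matrix (named, over a superset of
#'   the generative parameters) applied on the untruncated normal scale
#' @return list with `params` (data.frame, one row per subject),
#'   `phenotypes` (data.frame: id, age, sex, outcomes, survival_time, event)
#'   and `truth` (the generating distributions and coefficients)
#' @examples
#' pop <- samplePopulation(100, seed = 7)
#' head(pop$phenotypes)
#' @export
samplePopulation <- function(n,
                             paramDistributions = defaultParamDistributions(),
                             outcomeModel = defaultOutcomeModel(),
                             seed = 1,
                             sexMaleProb = 0.484,
                             correlation = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  dists <- paramDistributions
  ageDist <- dists$age
  paramDists <- dists[setdiff(names(dists), "age")]
  paramsDf <- as.data.frame(drawTruncatedNormals(n, paramDists, correlation))
  age <- drawTruncatedNormals(n, list(age = ageDist))[, "age"]
  sex <- stats::rbinom(n, 1, sexMaleProb)

  pheno <- data.frame(id = seq_len(n), age = age, sex = sex)
  for (nm in names(outcomeModel$continuous)) {
    m <- outcomeModel$continuous[[nm]]
    lp <- m$intercept + linearPredictor(m$coef, paramsDf, age, sex, dists)
    pheno[[nm]] <- lp + if (m$noiseSd > 0) stats::rnorm(n, 0, m$noiseSd) else 0
  }
  for (nm in names(outcomeModel$binary)) {
    m <- outcomeModel$binary[[nm]]
    lp <- m$intercept + linearPredictor(m$coef, paramsDf, age, sex, dists)
    pheno[[nm]] <- stats::rbinom(n, 1, stats::plogis(lp))
  }
  if (!is.null(outcomeModel$survival)) {
    m <- outcomeModel$survival
    lp <- linearPredictor(m$coef, paramsDf, age, sex, dists)
    latent <- stats::rexp(n, rate = m$baselineHazard * exp(lp))
    pheno$survival_time <- pmax(pmin(latent, m$followUp), 1e-6)
    pheno$event <- as.integer(latent <= m$followUp)
  }
  list(params = paramsDf, phenotypes = pheno,
       truth = list(paramDistributions = dists, outcomeModel = outcomeModel,
                    sexMaleProb = sexMaleProb, seed = seed))
}

#' Convert one row of a parameter table to a GenerativeParams object
#'
#' @param row a single-row data.frame (or list) with the columns produced by
#'   [samplePopulation()]
#' @return a [GenerativeParams-class]
#' @export
paramsFromRow <- function(row) {
  generativeParams(
    ventricularRate = row$ventricular_rate,
    prInterval = row$pr_interval,
    qrsDuration = row$qrs_duration,
    qtInterval = row$qt_interval,
    pAxis = row$p_axis, rAxis = row$r_axis, tAxis = row$t_axis,
    waveAmplitudes = c(P = row$amp_P, Q = row$amp_Q, R = row$amp_R,
                       S = row$amp_S, T = row$amp_T),
    baselineSlope = row$baseline_slope,
    baselineOffset = row$baseline_offset,
    noiseSd = row$noise_sd)
}

#' Synthesize a cohort of median beats from a parameter table
#'
#' Renders one deterministic median beat per subject with
#' [simulateMedianBeat()], optionally adding white measurement noise, and
#' assembles them into an [ECGCohort-class] whose `colData` carries the
#' generative parameters and any phenotypes.
#'
#' @param paramsDf parameter data.frame from [samplePopulation()]
#' @param phenotypes optional phenotype data.frame bound into `colData`
#' @param lengthMs,samplingRate,rPeakMs beat geometry, see
#'   [simulateMedianBeat()]
#' @param noiseSd white-noise SD (mV) added to each beat; 0 for none
#' @param seed RNG seed used when `noiseSd > 0`
#' @return an [ECGCohort-class]
#' @export
simulateCohortBeats <- function(paramsDf, phenotypes = NULL, lengthMs = 1200,
                                samplingRate = 500, rPeakMs = 400,
                                noiseSd = 0, seed = 1) {
  n <- nrow(paramsDf)
  tlen <- round(lengthMs / 1000 * samplingRate)
  mat <- matrix(0, nrow = 12L * tlen, ncol = n)
  for (i in seq_len(n)) {
    b <- simulateMedianBeat(paramsFromRow(paramsDf[i, ]), lengthMs = lengthMs,
                            samplingRate = samplingRate, rPeakMs = rPeakMs)
    mat[, i] <- as.vector(t(beatSamples(b)))
  }
  if (noiseSd > 0) {
    set.seed(seed)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, noiseSd), nrow = nrow(mat))
  }
  cd <- if (is.null(phenotypes)) paramsDf else cbind(paramsDf, phenotypes)
  beatCohort(mat, colData = cd, samplingRate = samplingRate,
             rPeakIndex = round(rPeakMs / 1000 * samplingRate))
}

#' Simulate Hardy-Weinberg genotype dosages with planted effects
#'
#' Dosages are drawn Binomial(2, maf) per variant. `effectSpec` plants
#' additive per-allele shifts on generative ECG parameters; apply them to a
#' parameter table with [applyGenotypeEffects()] before beat synthesis.
#'
#' @param n subjects
#' @param m variants
#' @param mafs per-variant minor-allele frequencies in (0, 0.5]; a scalar is
#'   recycled; default draws Uniform(0.05, 0.5)
#' @param effectSpec named list: variant id (e.g. `"v1"`) -> named numeric of
#'   per-allele shifts on generative parameters
#' @param seed RNG seed
#' @return a [GenotypeMatrix-class]
#' @examples
#' g <- simulateGenotypes(50, 3, mafs = 0.3,
#'                        effectSpec = list(v1 = c(qrs_duration = 4)))
#' colMeans(dosages(g))
#' @export
simulateGenotypes <- function(n, m, mafs = NULL, effectSpec = list(),
                              seed = 1) {
  set.seed(seed)
  if (is.null(mafs)) mafs <- stats::runif(m, 0.05, 0.5)
  if (length(mafs) == 1L) mafs <- rep(mafs, m)
  stopifnot(length(mafs) == m)
  if (m > 0 && (any(mafs <= 0) || any(mafs > 0.5)))
    stop("mafs must lie in (0, 0.5]")
  dos <- matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n)
  colnames(dos) <- if (m > 0) paste0("v", seq_len(m)) else character(0)
  if (length(effectSpec)) {
    unknown <- setdiff(names(effectSpec), colnames(dos))
    if (length(unknown))
      stop("effectSpec names not among variants: ",
           paste(unknown, collapse = ", "))
  }
  new("GenotypeMatrix", dosages = dos, mafs = as.numeric(mafs),
      trueEffects = effectSpec)
}

#' Apply planted genotype effects to a parameter table
#'
#' Adds `dosage * beta` to each targeted generative parameter, per variant.
#'
#' @param paramsDf parameter data.frame from [samplePopulation()]
#' @param geno a [GenotypeMatrix-class] with `trueEffects`
#' @return the shifted parameter data.frame
#' @export
applyGenotypeEffects <- function(paramsDf, geno) {
  stopifnot(nrow(paramsDf) == nrow(dosages(geno)))
  for (v in names(trueEffects(geno))) {
    eff <- trueEffects(geno)[[v]]
    for (p in names(eff)) {
      if (!p %in% names(paramsDf))
        stop(sprintf("parameter '%s' not in parameter table", p))
      paramsDf[[p]] <- paramsDf[[p]] + dosages(geno)[, v] * eff[[p]]
    }
  }
  paramsDf
}
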