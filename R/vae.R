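#' Training configuration for the beta-VAE
#'
#' @param latentDim number of latent factors K (default 32)
#' @param beta weight of the KL term. The reconstruction term is a weighted
#'   *mean* squared error per sample while the KL is a *sum* over the K
#'   factors, so a beta well below 1 balances the two at ECG amplitudes;
#'   see the package vignette.
#' @param hidden encoder hidden-layer widths (decoder mirrors them);
#'   `integer(0)` gives a purely linear encoder/decoder
#' @param maxEpochs maximum training epochs
#' @param learningRate initial Adam learning rate
#' @param lrDecay multiplicative per-epoch learning-rate decay (1 = none)
#' @param batchSize minibatch size
#' @param splitFraction training fraction of the 90:10-style split
#' @param qrsWeight loss weight on QRS samples (default 10)
#' @param qcThreshold reconstruction-correlation QC cutoff (default 0.7)
#' @param pcaDim optional principal-subspace front-end: the VAE is trained
#'   on the leading `pcaDim` principal components of the QRS-weighted,
#'   feature-standardised training beats, a basis in which the Euclidean
#'   metric equals the weighted metric in signal space. Dramatically
#'   faster and better conditioned for dense networks; `NULL` trains
#'   directly on (standardised) samples
#' @param pcaWhiten partial-whitening exponent alpha in [0, 1]: component
#'   scores are scaled by sd^(-alpha) (SDs floored at max sd / 50). 0
#'   leaves the weighted metric untouched; 1 whitens fully, which is
#'   equivalent to a Gaussian observation model whose noise scales with
#'   the data covariance. Intermediate values boost low-variance but
#'   structured directions (e.g. wave-position shifts) so they carry a
#'   larger share of the reconstruction loss
#' @param seed RNG seed controlling initialisation, split, shuffling and
#'   reparameterisation noise
#' @return a validated config list
#' @export
vaeConfig <- function(latentDim = 32, beta = 1, hidden = c(256),
                      maxEpochs = 30, learningRate = 1e-3, lrDecay = 1,
                      batchSize = 64, splitFraction = 0.9, qrsWeight = 10,
                      qcThreshold = 0.7, pcaDim = NULL, pcaWhiten = 0,
                      seed = 1) {
  stopifnot(latentDim >= 1, beta >= 0,
            splitFraction > 0, splitFraction < 1,
            maxEpochs >= 1, learningRate > 0, batchSize >= 1,
            lrDecay > 0, lrDecay <= 1,
            pcaWhiten >= 0, pcaWhiten <= 1)
  list(latentDim = as.integer(latentDim), beta = beta,
       hidden = as.integer(hidden), maxEpochs = as.integer(maxEpochs),
       learningRate = learningRate, lrDecay = lrDecay,
       batchSize = as.integer(batchSize),
       splitFraction = splitFraction, qrsWeight = qrsWeight,
       qcThreshold = qcThreshold,
       pcaDim = if (is.null(pcaDim)) NULL else as.integer(pcaDim),
       pcaWhiten = pcaWhiten, seed = as.integer(seed))
}

## Resolve a weight specification into the length-D feature weight vector.
resolveWeights <- function(weights, D, tlen) {
  if (is.null(weights)) return(rep(1, D))
  if (is(weights, "WeightMask")) weights <- weights@weights
  if (length(weights) == tlen) return(rep(weights, 12L))
  if (length(weights) == D) return(weights)
  stop("weights must have length T or 12*T")
}

asBeatRow <- function(x) {
  if (is(x, "MedianBeat")) matrix(as.vector(t(beatSamples(x))), nrow = 1)
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1)
}

#' Beta-VAE loss: weighted reconstruction error plus scaled KL divergence
#'
#' The reconstruction term is the weighted mean squared error over all
#' leads x samples (weights from the QRS mask, normalised by the total
#' weight); the KL term is the closed form for diagonal Gaussians against a
#' standard normal prior, summed over factors:
#' \eqn{\sum_k \frac12 (\mu_k^2 + \sigma_k^2 - 1 - \log \sigma_k^2)}.
#' `total = reconstruction + beta * kl` exactly.
#'
#' @param x,xhat original and reconstructed beats: [MedianBeat-class]
#'   objects or n x D matrices of flattened beats
#' @param mu,logVar latent mean and log-variance (vectors or n x K matrices)
#' @param weights `NULL`, a [WeightMask-class], or a numeric vector of
#'   length T (replicated over leads) or 12*T
#' @param beta KL weight
#' @return list with `total`, `reconstruction`, `kl`
#' @examples
#' b <- simulateMedianBeat(generativeParams())
#' elboLoss(b, b, mu = rep(0, 4), logVar = rep(0, 4))$total
#' @export
elboLoss <- function(x, xhat, mu, logVar, weights = NULL, beta = 1) {
  X <- asBeatRow(x); Xh <- asBeatRow(xhat)
  stopifnot(identical(dim(X), dim(Xh)))
  if (!all(is.finite(X), is.finite(Xh), is.finite(mu), is.finite(logVar)))
    stop("non-finite inputs to elboLoss")
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = nrow(X), byrow = TRUE)
  if (!is.matrix(logVar)) logVar <- matrix(logVar, nrow = nrow(X), byrow = TRUE)
  D <- ncol(X)
  wFull <- resolveWeights(weights, D, tlen = D %/% 12L)
  B <- nrow(X)
  E <- Xh - X
  recon <- sum(t(t(E) * wFull) * E) / (B * sum(wFull))
  kl <- sum(0.5 * (mu^2 + exp(logVar) - 1 - logVar)) / B
  list(total = recon + beta * kl, reconstruction = recon, kl = kl)
}

#' Train a beta-VAE on a cohort of median beats
#'
#' Splits the records into training and validation sets (default 90:10),
#' optimises the weighted ELBO with Adam, records the per-epoch training and
#' validation losses, and keeps the weights of the epoch with the lowest
#' validation loss. Validation loss is evaluated at the deterministic code
#' `z = mu`. After training, latent standardisation statistics (mean and SD
#' of each factor) are computed on the training records that pass
#' reconstruction QC. Fully reproducible given `config$seed`.
#'
#' @param x an [ECGCohort-class], a list of [MedianBeat-class], or an
#'   n x D matrix of flattened beats (rows = records)
#' @param config a [vaeConfig()] list
#' @param weights QRS weighting: `NULL` (derive a window around the cohort
#'   R peak, using the mean `qrs_duration` from `colData` when present), a
#'   [WeightMask-class], or a numeric weight vector
#' @param geometry for matrix input only: list with `samplingRate` and
#'   `rPeakIndex` describing the beats (defaults 500 Hz, T/3)
#' @return a [BetaVAE-class] model artifact
#' @export
trainBetaVAE <- function(x, config = vaeConfig(), weights = NULL,
                         geometry = list()) {
  if (is(x, "ECGCohort")) {
    X <- beatMatrix(x)
    fs <- samplingRate(x); rpk <- rPeakIndex(x); leads <- leadNames(x)
    tlen <- S4Vectors::metadata(x)$beatLength
    if (is.null(weights)) {
      qrsMs <- if ("qrs_duration" %in% colnames(SummarizedExperiment::colData(x)))
        mean(SummarizedExperiment::colData(x)$qrs_duration) else 100
      half <- round(qrsMs / 2 / 1000 * fs)
      weights <- qrsWeightMask(tlen, c(max(0L, rpk - half),
                                       min(tlen, rpk + half)),
                               qrsWeight = config$qrsWeight)
    }
  } else {
    if (is.list(x) && !is.data.frame(x)) x <- beatCohortMatrix(x)
    X <- x
    tlen <- ncol(X) %/% 12L
    fs <- geometry$samplingRate %||% 500
    rpk <- geometry$rPeakIndex %||% (tlen %/% 3L)
    leads <- ECG_LEADS
  }
  n <- nrow(X); D <- ncol(X)
  if (n < 10) stop("at least 10 beats are required for training")
  wFull <- resolveWeights(weights, D, tlen)

  set.seed(config$seed)
  nTrain <- min(n - 1L, max(1L, round(config$splitFraction * n)))
  nVal <- n - nTrain
  valIdx <- sort(sample.int(n, nVal))
  trainIdx <- setdiff(seq_len(n), valIdx)
  ## standardise inputs feature-wise on the training set: the network then
  ## models deviations from the average morphology with every region of the
  ## beat (including low-amplitude waves such as P) contributing
  ## proportionately to the loss. The scale is floored so near-constant
  ## features are not blown up. Decoding inverts the transform. With
  ## `pcaDim` set, the model is additionally trained in the leading
  ## principal subspace of the sqrt(weight)-scaled standardised beats, in
  ## which plain squared error equals the QRS-weighted standardised error.
  xCenter <- colMeans(X[trainIdx, , drop = FALSE])
  sds <- apply(X[trainIdx, , drop = FALSE], 2, stats::sd)
  xScale <- pmax(sds, 0.02 * max(sds, 1e-12))
  Xn <- sweep(X, 2, xCenter)
  proj <- NULL; backProj <- NULL
  if (!is.null(config$pcaDim)) {
    M <- min(config$pcaDim, length(trainIdx) - 1L, D)
    A <- sqrt(wFull) / xScale
    sv <- svd(sweep(Xn[trainIdx, , drop = FALSE], 2, A, "*"), nu = 0, nv = M)
    V <- sv$v
    proj <- A * V                       # D x M: scores = (x - c) %*% proj
    backProj <- t(V / A)                # M x D: x = scores %*% backProj + c
    alpha <- config$pcaWhiten %||% 0
    if (alpha > 0) {
      sdev <- sv$d[seq_len(M)] / sqrt(max(1, length(trainIdx) - 1))
      sdev <- pmax(sdev, max(sdev) / 50)^alpha
      proj <- sweep(proj, 2, sdev, "/")
      backProj <- backProj * sdev
    }
    Xtr <- Xn[trainIdx, , drop = FALSE] %*% proj
    Xval <- Xn[valIdx, , drop = FALSE] %*% proj
    wTrain <- rep(1, M)
  } else {
    Xtr <- sweep(Xn[trainIdx, , drop = FALSE], 2, xScale, "/")
    Xval <- sweep(Xn[valIdx, , drop = FALSE], 2, xScale, "/")
    wTrain <- wFull
  }

  p <- initVAEParams(ncol(Xtr), config$hidden, config$latentDim)

  valLoss <- function(pp)
    vaeBatch(pp, Xval, wTrain, config$beta, eps = NULL, wantGrad = FALSE)$total

  history <- data.frame(epoch = 0L, train = NA_real_,
                        validation = valLoss(p))
  st <- adamInit(p)
  best <- list(epoch = 0L, loss = history$validation[1], p = p)

  for (ep in seq_len(config$maxEpochs)) {
    lr <- config$learningRate * (config$lrDecay %||% 1)^(ep - 1)
    ord <- sample(length(trainIdx))
    lossSum <- 0; nSeen <- 0
    for (start in seq(1, length(ord), by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, length(ord))]
      Xb <- Xtr[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * config$latentDim),
                    nrow = length(idx))
      res <- vaeBatch(p, Xb, wTrain, config$beta, eps = eps)
      if (!is.finite(res$total))
        stop(sprintf("training diverged at epoch %d (loss %g); reduce the learning rate",
                     ep, res$total))
      upd <- adamStep(p, res$grad, st, lr)
      p <- upd$params; st <- upd$state
      lossSum <- lossSum + res$total * length(idx)
      nSeen <- nSeen + length(idx)
    }
    vl <- valLoss(p)
    history <- rbind(history,
                     data.frame(epoch = ep, train = lossSum / nSeen,
                                validation = vl))
    if (vl < best$loss) best <- list(epoch = ep, loss = vl, p = p)
  }

  pBest <- best$p
  model <- new("BetaVAE", config = config, params = pBest,
               history = history, selectedEpoch = as.integer(best$epoch),
               latentMean = rep(0, config$latentDim),
               latentSd = rep(1, config$latentDim),
               beatLength = as.integer(tlen), samplingRate = fs,
               rPeakIndex = as.integer(rpk), leadNames = leads)
  ## standardisation statistics from QC-passing training records;
  ## QC correlations are computed on the original (uncentred) scale
  muTr <- encoderForward(pBest, Xtr)$mu
  recT <- decoderForward(pBest, muTr)$xhat
  rec <- if (!is.null(proj)) sweep(recT %*% backProj, 2, xCenter, "+")
         else sweep(sweep(recT, 2, xScale, "*"), 2, xCenter, "+")
  Xorig <- X[trainIdx, , drop = FALSE]
  rTr <- vapply(seq_len(nrow(Xorig)),
                function(i) suppressWarnings(stats::cor(Xorig[i, ], rec[i, ])),
                numeric(1))
  pass <- which(is.finite(rTr) & rTr >= config$qcThreshold)
  if (!length(pass)) {
    warning("no training record passed reconstruction QC; using all records")
    pass <- seq_len(nrow(Xtr))
  }
  model@latentMean <- colMeans(muTr[pass, , drop = FALSE])
  model@latentSd <- pmax(apply(muTr[pass, , drop = FALSE], 2, stats::sd), 1e-8)
  model@params$xCenter <- xCenter
  model@params$xScale <- xScale
  model@params$proj <- proj
  model@params$backProj <- backProj
  model@params$trainIdx <- trainIdx
  model@params$valIdx <- valIdx
  validObject(model)
  model
}

## Apply / invert the stored input transform: feature-wise standardisation
## and, when present, the whitened principal-subspace projection. Identity
## when the model carries no statistics (hand-built stubs).
normalizeInput <- function(model, X) {
  p <- model@params
  if (is.null(p$xCenter)) return(X)
  X <- sweep(X, 2, p$xCenter)
  if (!is.null(p$proj)) return(X %*% p$proj)
  if (!is.null(p$xScale)) X <- sweep(X, 2, p$xScale, "/")
  X
}

denormalizeOutput <- function(model, Xh) {
  p <- model@params
  if (is.null(p$xCenter)) return(Xh)
  if (!is.null(p$backProj)) return(sweep(Xh %*% p$backProj, 2, p$xCenter, "+"))
  if (!is.null(p$xScale)) Xh <- sweep(Xh, 2, p$xScale, "*")
  sweep(Xh, 2, p$xCenter, "+")
}

beatCohortMatrix <- function(beats) {
  t(vapply(beats, function(b) as.vector(t(beatSamples(b))),
           numeric(12L * ncol(beatSamples(beats[[1]])))))
}

#' Encode beats to latent factors
#'
#' Returns the encoder mean mu (no sampling). With `standardize = TRUE`
#' the factors are z-transformed using the cohort statistics stored in the
#' model.
#'
#' @param model a [BetaVAE-class]
#' @param x a [MedianBeat-class], [ECGCohort-class], or n x D matrix
#' @param standardize z-transform with stored cohort means/SDs
#' @return numeric length-K vector (single beat) or n x K matrix
#' @export
#' @aliases encode,BetaVAE-method
setMethod("encode", "BetaVAE", function(model, x, standardize = TRUE) {
  single <- is(x, "MedianBeat")
  X <- if (is(x, "ECGCohort")) beatMatrix(x) else asBeatRow(x)
  if (ncol(X) != 12L * model@beatLength)
    stop(sprintf("beat length mismatch: model expects 12 x %d samples",
                 model@beatLength))
  X <- normalizeInput(model, X)
  mu <- encoderForward(model@params, X)$mu
  if (standardize)
    mu <- sweep(sweep(mu, 2, model@latentMean), 2, model@latentSd, "/")
  colnames(mu) <- paste0("factor", seq_len(ncol(mu)))
  if (single) drop(mu) else mu
})

#' Decode latent factors to a median beat
#'
#' Deterministic decoder pass. By default `z` is interpreted on the
#' standardised scale (the scale of factor traversals); it is mapped back to
#' the original latent scale with the stored cohort statistics before the
#' decoder. Pass `standardized = FALSE` for latents already on the original
#' scale (e.g. cohort-average latents in variant-effect rendering).
#'
#' @param model a [BetaVAE-class]
#' @param z length-K vector or n x K matrix of latent values
#' @param standardized whether `z` is on the standardised scale
#' @return a [MedianBeat-class] (vector input) or list of them
#' @export
#' @aliases decodeLatent,BetaVAE-method
setMethod("decodeLatent", "BetaVAE", function(model, z, standardized = TRUE) {
  K <- latentDim(model)
  single <- !is.matrix(z)
  Z <- if (single) matrix(z, nrow = 1) else z
  if (ncol(Z) != K)
    stop(sprintf("latent vector length %d does not match K = %d", ncol(Z), K))
  if (standardized)
    Z <- sweep(sweep(Z, 2, model@latentSd, "*"), 2, model@latentMean, "+")
  Xh <- denormalizeOutput(model, decoderForward(model@params, Z)$xhat)
  toBeat <- function(v) {
    m <- matrix(v, nrow = 12L, byrow = TRUE)
    rownames(m) <- model@leadNames
    medianBeat(m, samplingRate = model@samplingRate,
               rPeakIndex = model@rPeakIndex, leadNames = model@leadNames)
  }
  if (single) toBeat(Xh[1, ]) else lapply(seq_len(nrow(Xh)), function(i) toBeat(Xh[i, ]))
})

#' Reconstruction quality control
#'
#' Computes the Pearson correlation between each original beat and its
#' reconstruction (decode of the encoder mean) over the flattened 12 x T
#' matrices, and flags records below the threshold for exclusion. A
#' zero-variance record has undefined correlation and fails QC with an
#' explicit reason.
#'
#' @param model a [BetaVAE-class]
#' @param x an [ECGCohort-class] or n x D matrix of beats
#' @param threshold exclusion cutoff on r (default 0.7)
#' @return data.frame with columns `record`, `r`, `pass`, `reason`;
#'   attributes `meanR` (mean r among defined values) and `excluded`
#'   (indices failing QC)
#' @export
reconstructionQC <- function(model, x, threshold = 0.7) {
  X <- if (is(x, "ECGCohort")) beatMatrix(x) else asBeatRow(x)
  mu <- encoderForward(model@params, normalizeInput(model, X))$mu
  Xh <- denormalizeOutput(model, decoderForward(model@params, mu)$xhat)
  n <- nrow(X)
  r <- vapply(seq_len(n), function(i) {
    if (stats::sd(X[i, ]) == 0) NA_real_
    else stats::cor(X[i, ], Xh[i, ])
  }, numeric(1))
  pass <- !is.na(r) & r >= threshold
  reason <- rep("", n)
  reason[is.na(r)] <- "zero-variance record: correlation undefined"
  reason[!is.na(r) & !pass] <- sprintf("r below threshold %g", threshold)
  out <- data.frame(record = seq_len(n), r = r, pass = pass,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "meanR") <- mean(r, na.rm = TRUE)
  attr(out, "excluded") <- which(!pass)
  out
}

#' Latent factor traversal
#'
#' Decodes a grid of standardised values of one latent factor (default -3
#' to 3) with all other factors held at 0, visualising that factor's
#' morphological meaning.
#'
#' @param model a [BetaVAE-class]
#' @param factorIndex factor to traverse (1..K)
#' @param from,to,step traversal grid in standardised latent units
#' @return a [FactorTraversal-class]
#' @export
factorTraversal <- function(model, factorIndex, from = -3, to = 3, step = 1) {
  K <- latentDim(model)
  if (factorIndex < 1 || factorIndex > K)
    stop(sprintf("factorIndex must lie in 1..%d", K))
  grid <- seq(from, to, by = step)
  beats <- lapply(grid, function(v) {
    z <- rep(0, K); z[factorIndex] <- v
    decodeLatent(model, z, standardized = TRUE)
  })
  new("FactorTraversal", factorIndex = as.integer(factorIndex),
      grid = grid, beats = beats)
}
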