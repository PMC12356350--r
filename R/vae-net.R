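## Internal dense-network machinery for the beta-VAE. Encoder and decoder
## are multilayer perceptrons with tanh hidden units and linear heads; all
## gradients are written out by hand (no autodiff), so everything runs as
## BLAS matrix products. Parameters live in one flat named list
## (encW1/encb1, ..., Wmu/bmu, Wlv/blv, decW1/decb1, ..., Wout/bout) so the
## optimiser can iterate them without restructuring copies.

glorot <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -s, s), fin, fout)
}

initVAEParams <- function(inputDim, hidden, latentDim) {
  L <- length(hidden)
  p <- list()
  fin <- inputDim
  for (i in seq_len(L)) {
    p[[paste0("encW", i)]] <- glorot(fin, hidden[i])
    p[[paste0("encb", i)]] <- rep(0, hidden[i])
    fin <- hidden[i]
  }
  p$Wmu <- glorot(fin, latentDim); p$bmu <- rep(0, latentDim)
  p$Wlv <- glorot(fin, latentDim); p$blv <- rep(0, latentDim)
  decHidden <- rev(hidden)
  din <- latentDim
  for (i in seq_len(L)) {
    p[[paste0("decW", i)]] <- glorot(din, decHidden[i])
    p[[paste0("decb", i)]] <- rep(0, decHidden[i])
    din <- decHidden[i]
  }
  p$Wout <- glorot(din, inputDim); p$bout <- rep(0, inputDim)
  p
}

nEncLayers <- function(p) sum(grepl("^encW", names(p)))
nDecLayers <- function(p) sum(grepl("^decW", names(p)))

addBias <- function(A, b) A + rep(b, each = nrow(A))

encoderForward <- function(p, X) {
  A <- X
  acts <- list()
  for (i in seq_len(nEncLayers(p))) {
    A <- tanh(addBias(A %*% p[[paste0("encW", i)]], p[[paste0("encb", i)]]))
    acts[[i]] <- A
  }
  mu <- addBias(A %*% p$Wmu, p$bmu)
  lv <- addBias(A %*% p$Wlv, p$blv)
  lv <- pmin(pmax(lv, -10), 10)   # keep exp(lv) finite
  list(acts = acts, last = A, mu = mu, logVar = lv)
}

decoderForward <- function(p, Z) {
  A <- Z
  acts <- list()
  for (i in seq_len(nDecLayers(p))) {
    A <- tanh(addBias(A %*% p[[paste0("decW", i)]], p[[paste0("decb", i)]]))
    acts[[i]] <- A
  }
  list(acts = acts, xhat = addBias(A %*% p$Wout, p$bout))
}

## Loss + full gradient for one minibatch. wFull is the length-D feature
## weight vector (QRS mask replicated across leads); eps the reparameterised
## noise (NULL for deterministic z = mu).
vaeBatch <- function(p, X, wFull, beta, eps = NULL, wantGrad = TRUE) {
  B <- nrow(X)
  Wsum <- sum(wFull)
  ef <- encoderForward(p, X)
  mu <- ef$mu; lv <- ef$logVar
  Z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  df <- decoderForward(p, Z)
  E <- df$xhat - X
  Ew <- t(t(E) * wFull)                       # columns scaled by weights
  recon <- sum(E * Ew) / (B * Wsum)
  kl <- sum(0.5 * (mu^2 + exp(lv) - 1 - lv)) / B
  total <- recon + beta * kl
  if (!wantGrad)
    return(list(total = total, reconstruction = recon, kl = kl))

  g <- list()
  dXhat <- 2 * Ew / (B * Wsum)
  lastDec <- if (length(df$acts)) df$acts[[length(df$acts)]] else Z
  g$Wout <- crossprod(lastDec, dXhat)
  g$bout <- colSums(dXhat)
  dA <- dXhat %*% t(p$Wout)
  nd <- nDecLayers(p)
  if (nd > 0) {
    for (i in nd:1) {
      dA <- dA * (1 - df$acts[[i]]^2)
      Ain <- if (i == 1) Z else df$acts[[i - 1]]
      g[[paste0("decW", i)]] <- crossprod(Ain, dA)
      g[[paste0("decb", i)]] <- colSums(dA)
      dA <- dA %*% t(p[[paste0("decW", i)]])
    }
  }
  dZ <- dA
  dmu <- dZ + beta * mu / B
  dlv <- beta * 0.5 * (exp(lv) - 1) / B
  if (!is.null(eps)) dlv <- dlv + dZ * 0.5 * (Z - mu)
  lastEnc <- ef$last
  g$Wmu <- crossprod(lastEnc, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(lastEnc, dlv); g$blv <- colSums(dlv)
  dA <- dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv)
  ne <- nEncLayers(p)
  if (ne > 0) {
    for (i in ne:1) {
      dA <- dA * (1 - ef$acts[[i]]^2)
      Ain <- if (i == 1) X else ef$acts[[i - 1]]
      g[[paste0("encW", i)]] <- crossprod(Ain, dA)
      g[[paste0("encb", i)]] <- colSums(dA)
      if (i > 1) dA <- dA %*% t(p[[paste0("encW", i)]])
    }
  }
  list(total = total, reconstruction = recon, kl = kl, grad = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamInit <- function(p) {
  z <- lapply(p, function(x) x * 0)
  list(m = z, v = z, t = 0)
}

adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(p)) {
    gx <- g[[nm]]
    if (is.null(gx)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gx
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gx^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / c1) /
      (sqrt(state$v[[nm]] / c2) + epsilon)
  }
  list(params = p, state = state)
}
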