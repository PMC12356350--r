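test_that("ELBO vanishes for perfect reconstruction at the prior", {
  b <- simulateMedianBeat(generativeParams())
  l <- elboLoss(b, b, mu = rep(0, 8), logVar = rep(0, 8))
  expect_equal(l$total, 0)
  expect_equal(l$reconstruction, 0)
  expect_equal(l$kl, 0)
})

test_that("KL term matches the diagonal-Gaussian closed form", {
  K <- 5
  l <- elboLoss(matrix(0, 1, 120), matrix(0, 1, 120),
                mu = rep(1, K), logVar = rep(0, K))
  expect_equal(l$kl, K / 2)   # each factor contributes 1/2 (1 + 1 - 1 - 0)

  ## against a numeric-quadrature oracle: KL(N(mu, s2) || N(0,1))
  set.seed(1)
  for (i in 1:5) {
    mu <- rnorm(1); s2 <- exp(rnorm(1, sd = 0.5))
    q <- function(x) dnorm(x, mu, sqrt(s2)) *
      (dnorm(x, mu, sqrt(s2), log = TRUE) - dnorm(x, log = TRUE))
    klNum <- integrate(q, mu - 12 * sqrt(s2), mu + 12 * sqrt(s2),
                       rel.tol = 1e-10)$value
    lq <- elboLoss(matrix(0, 1, 120), matrix(0, 1, 120),
                   mu = mu, logVar = log(s2))
    expect_equal(lq$kl, klNum, tolerance = 1e-7)
  }
})

test_that("weighted reconstruction term equals a brute-force loop", {
  set.seed(2)
  tlen <- 20; D <- 12 * tlen
  x <- matrix(rnorm(3 * D), 3, D)
  xh <- x + matrix(rnorm(3 * D, sd = 0.3), 3, D)
  mask <- qrsWeightMask(tlen, c(5, 11), qrsWeight = 10)
  l <- elboLoss(x, xh, mu = matrix(0, 3, 4), logVar = matrix(0, 3, 4),
                weights = mask, beta = 2)
  wFull <- rep(mask@weights, 12)
  acc <- 0
  for (i in 1:3) for (j in 1:D)
    acc <- acc + wFull[j] * (x[i, j] - xh[i, j])^2
  expect_equal(l$reconstruction, acc / (3 * sum(wFull)), tolerance = 1e-12)
  expect_equal(l$total, l$reconstruction + 2 * l$kl)   # exact decomposition
})

test_that("non-finite inputs to the loss are rejected", {
  x <- matrix(0, 1, 120); x2 <- x; x2[5] <- NA
  expect_error(elboLoss(x, x2, mu = 0, logVar = 0), "non-finite")
})

test_that("the 90:10 split yields the stated counts and is recorded", {
  td <- cachedTinyData()
  m <- cachedTinyModel()
  n <- ncol(SummarizedExperiment::assay(td$cohort, "beats"))
  expect_length(m@params$valIdx, floor(0.1 * n))
  expect_length(m@params$trainIdx, n - floor(0.1 * n))
  expect_length(intersect(m@params$trainIdx, m@params$valIdx), 0)
})

test_that("training is deterministic given the seed", {
  td <- tinyCohort(n = 60, seed = 1)
  cfg <- vaeConfig(latentDim = 3, beta = 0.005, hidden = 16, maxEpochs = 3,
                   batchSize = 16, seed = 5)
  m1 <- trainBetaVAE(td$cohort, cfg)
  m2 <- trainBetaVAE(td$cohort, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@params$Wout, m2@params$Wout)
})

test_that("the selected epoch improves on the untrained validation loss", {
  m <- cachedTinyModel()
  h <- trainingHistory(m)
  expect_equal(selectedEpoch(m), h$epoch[which.min(h$validation)])
  expect_lt(min(h$validation), h$validation[h$epoch == 0])
})

test_that("standardized latents have mean 0 and sd 1 on QC-passing training records", {
  td <- cachedTinyData()
  m <- cachedTinyModel()
  Xtr <- beatMatrix(td$cohort)[m@params$trainIdx, ]
  qc <- reconstructionQC(m, Xtr, threshold = m@config$qcThreshold)
  Z <- encode(m, Xtr[qc$pass, ], standardize = TRUE)
  expect_equal(unname(colMeans(Z)), rep(0, latentDim(m)), tolerance = 1e-6)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, latentDim(m)), tolerance = 1e-6)
})

test_that("encoding and decoding are deterministic", {
  m <- cachedTinyModel()
  b <- getBeat(cachedTinyData()$cohort, 1)
  expect_identical(encode(m, b), encode(m, b))
  z <- rep(0, latentDim(m))
  d1 <- decodeLatent(m, z); d2 <- decodeLatent(m, z)
  expect_identical(beatSamples(d1), beatSamples(d2))
  expect_true(all(is.finite(beatSamples(d1))))
})

test_that("encode rejects beats of the wrong geometry", {
  m <- cachedTinyModel()
  expect_error(encode(m, matrix(0, 1, 24)), "mismatch")
  expect_error(decodeLatent(m, rep(0, latentDim(m) + 1)), "does not match")
})

test_that("desk-scale training reconstructs held-out beats faithfully", {
  td <- cachedTinyData()
  m <- cachedTinyModel()
  qc <- reconstructionQC(m, beatMatrix(td$cohort)[m@params$valIdx, ])
  expect_gt(attr(qc, "meanR"), 0.8)
})

test_that("a latent factor tracks ventricular rate after rate-only training", {
  d <- intervalOnlyDistributions()
  for (nm in c("pr_interval", "qrs_duration", "qt_interval")) d[[nm]]$sd <- 0
  pop <- samplePopulation(200, paramDistributions = d, outcomeModel = NULL,
                          seed = 21)
  co <- simulateCohortBeats(pop$params, samplingRate = 100)
  cfg <- vaeConfig(latentDim = 3, beta = 0.005, hidden = 32, maxEpochs = 12,
                   batchSize = 32, seed = 22)
  m <- trainBetaVAE(co, cfg)
  r <- latentCorrelations(encode(m, co), pop$params[, "ventricular_rate",
                                                    drop = FALSE])
  expect_gt(max(abs(r)), 0.5)
})

test_that("reconstruction QC flags zero-variance and corrupted records", {
  m <- cachedTinyModel()
  td <- cachedTinyData()
  X <- beatMatrix(td$cohort)[1:10, ]
  set.seed(30)
  X[3, ] <- rnorm(ncol(X), sd = 1)        # noise record
  X[7, ] <- rnorm(ncol(X), sd = 1)
  qc <- reconstructionQC(m, X, threshold = 0.7)
  expect_equal(sum(qc$pass), 8)
  expect_setequal(attr(qc, "excluded"), c(3, 7))

  Xz <- X; Xz[1, ] <- 0                   # flat record: r undefined
  qcz <- reconstructionQC(m, Xz, threshold = 0.7)
  expect_false(qcz$pass[1])
  expect_match(qcz$reason[1], "zero-variance")
  expect_true(is.na(qcz$r[1]))
})

test_that("factor traversal decodes v * e_j with other factors at zero", {
  m <- cachedTinyModel()
  tr <- factorTraversal(m, 2, from = -3, to = 3, step = 1)
  expect_equal(tr@grid, -3:3)
  z0 <- decodeLatent(m, rep(0, latentDim(m)))
  expect_identical(beatSamples(tr@beats[[which(tr@grid == 0)]]),
                   beatSamples(z0))
  v <- 2
  ej <- rep(0, latentDim(m)); ej[2] <- v
  expect_identical(beatSamples(tr@beats[[which(tr@grid == v)]]),
                   beatSamples(decodeLatent(m, ej)))
  expect_error(factorTraversal(m, latentDim(m) + 1), "factorIndex")
})

test_that("collapsed factors are flagged by the disentanglement report", {
  set.seed(31)
  L <- matrix(rnorm(200 * 4), 200, 4)
  L[, 3] <- L[, 3] * 1e-3                 # variance 1e-6 < 1e-3
  rep_ <- disentanglementReport(L)
  expect_equal(sum(rep_$subtle), 1)
  expect_true(rep_$subtle[3])
  expect_equal(sum(rep_$subtle) + sum(!rep_$subtle), 4)
})
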