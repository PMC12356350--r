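test_that("latent correlations reproduce hand-computed Pearson r", {
  ## 5 x 2 hand table, brute-force covariance / sd oracle
  L <- cbind(a = c(1, 2, 4, 3, 5), b = c(2, 1, 3, 5, 4))
  P <- cbind(p = c(2, 4, 8, 6, 10), q = c(1, 2, 2, 3, 1))
  r <- latentCorrelations(L, P)
  bf <- function(x, y) {
    n <- length(x)
    cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    cxy / (sd(x) * sd(y))
  }
  for (i in 1:2) for (j in 1:2)
    expect_equal(r[i, j], bf(L[, i], P[, j]), tolerance = 1e-12)
  expect_equal(r["a", "p"], 1)                 # copied (scaled) column
})

test_that("null correlations are small and zero-variance columns flagged", {
  set.seed(1)
  L <- matrix(rnorm(10000 * 2), ncol = 2)
  P <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_lt(max(abs(latentCorrelations(L, P))), 0.05)

  P2 <- cbind(P[, 1], 7)                       # constant column
  r <- latentCorrelations(L, P2)
  expect_true(all(is.na(r[, 2])))
  expect_true(all(attr(r, "undefined")[, 2]))
})

test_that("linear fits match the normal-equations oracle on a small fixture", {
  set.seed(2)
  n <- 20
  Z <- scale(matrix(rnorm(n * 2), n, 2))       # exactly mean 0, sd 1
  colnames(Z) <- c("f1", "f2")
  age <- rnorm(n, 60, 8); sex <- rbinom(n, 1, 0.5)
  y <- 1 + 0.8 * Z[, 1] - 0.5 * Z[, 2] + 0.02 * age + 0.3 * sex + rnorm(n, 0, 0.4)
  fit <- fitContinuous(y, Z, age = age, sex = sex)

  X <- cbind(1, Z, age, sex)
  betaHat <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% betaHat
  s2 <- sum(resid^2) / (n - ncol(X))
  seHat <- sqrt(diag(s2 * solve(crossprod(X))))
  expect_equal(fit$coefficients$estimate, as.vector(betaHat), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(seHat), tolerance = 1e-8)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - ncol(X))
  expect_equal(fit$adjR2, adj, tolerance = 1e-10)
})

test_that("an exact linear combination gives adjusted R-squared 1", {
  set.seed(3)
  Z <- scale(matrix(rnorm(60 * 3), 60, 3))
  y <- 2 + Z %*% c(1, -2, 0.5)
  fit <- suppressWarnings(fitContinuous(as.vector(y), Z))
  expect_equal(fit$adjR2, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[-1], c(1, -2, 0.5), tolerance = 1e-10)
})

test_that("pure-noise outcomes give near-zero adjusted R-squared", {
  set.seed(4)
  Z <- matrix(rnorm(1000 * 32), 1000, 32)
  y <- rnorm(1000)
  fit <- fitContinuous(y, Z, age = rnorm(1000, 60, 8),
                       sex = rbinom(1000, 1, 0.5))
  expect_lt(abs(fit$adjR2), 0.05)
})

test_that("rank-deficient designs are reported with offending columns", {
  set.seed(5)
  Z <- matrix(rnorm(30 * 2), 30, 2)
  Z <- cbind(Z, dup = Z[, 1])  # sd differs? exact duplicate after z-scaling
  expect_error(fitContinuous(rnorm(30), Z), "aliased|rank")
})

test_that("model comparison favours the richer, informative predictor set", {
  set.seed(6)
  n <- 300
  P <- matrix(rnorm(n * 3), n, 3)
  extra <- rnorm(n)
  y <- P %*% c(0.5, -0.3, 0.2) + 0.8 * extra + rnorm(n, 0, 0.5)
  same <- compareModels(as.vector(y), P, P)
  expect_equal(attr(same, "difference"), 0, tolerance = 1e-12)
  cmp <- compareModels(as.vector(y), cbind(P, extra), P)
  expect_gte(attr(cmp, "difference"), 0)
  expect_true(all(cmp$adjR2 > 0))
})

test_that("logistic fits match a direct likelihood-maximisation oracle", {
  set.seed(7)
  n <- 20
  Z <- scale(matrix(rnorm(n * 2), n, 2))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * Z[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fitBinary(y, Z)
  X <- cbind(1, Z)
  nll <- function(b) -sum(y * (X %*% b) - log1p(exp(X %*% b)))
  opt <- optim(rep(0, 3), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit$coefficients$estimate, opt$par, tolerance = 1e-4)
  ## classical SEs from the observed information at the optimum
  ph <- plogis(as.vector(X %*% opt$par))
  info <- crossprod(X * (ph * (1 - ph)), X)
  expect_equal(fit$coefficients$se, sqrt(diag(solve(info))), tolerance = 1e-4)
})

test_that("logistic regression recovers a planted log-odds effect", {
  set.seed(8)
  n <- 5000
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * Z[, 3]))
  fit <- fitBinary(y, Z)
  est <- fit$coefficients[fit$coefficients$term == "factor3", ]
  expect_lt(abs(est$estimate - 0.5), 2 * est$se)
})

test_that("single-class outcomes are rejected", {
  expect_error(fitBinary(rep(1, 50), matrix(rnorm(100), 50, 2)),
               "single class")
})

test_that("Cox fit maximises the hand-coded partial likelihood on a toy set", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 0)
  x <- c(0.5, -1, 2, 0, 1)
  fit <- fitSurvival(time, event, cbind(x = x))
  ## hand partial likelihood (distinct event times, no ties):
  ## for each event time, exp(b z_i) / sum over the risk set of exp(b z)
  xs <- as.vector(scale(x))
  nlpl <- function(b) {
    acc <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      acc <- acc - (b * xs[i] - log(sum(exp(b * xs[risk]))))
    }
    acc
  }
  opt <- optimize(nlpl, c(-5, 5), tol = 1e-10)
  expect_equal(log(fit$table$hr), opt$minimum, tolerance = 1e-6)
  expect_equal(fit$nEvents, 3)
  ## CI construction
  expect_equal(fit$table$ciLow,
               exp(fit$table$coef - 1.96 * fit$table$se), tolerance = 1e-12)
})

test_that("a null predictor yields a hazard ratio near one", {
  set.seed(9)
  n <- 400
  x <- rnorm(n)
  time <- rexp(n, 0.1); event <- as.integer(time < quantile(time, 0.3))
  time <- pmin(time, quantile(time, 0.3))
  fit <- fitSurvival(time, event, cbind(x = x))
  expect_true(fit$table$ciLow < 1 && fit$table$ciHigh > 1)
  expect_error(fitSurvival(time, rep(0, n), cbind(x = x)), "event")
  expect_error(fitSurvival(c(-1, time[-1]), event, cbind(x = x)), "positive")
})

test_that("effective test counts match the eigenvalue closed forms", {
  expect_equal(effectiveTests(diag(32)), 32)
  expect_equal(effectiveTests(matrix(1, 32, 32)), 1)
  blocks <- kronecker(diag(2), matrix(1, 16, 16))
  expect_equal(effectiveTests(blocks), 2)
  ## from data: identical columns collapse to one effective test
  x <- rnorm(100)
  expect_equal(effectiveTests(cbind(x, x, x)), 1)
})

test_that("effective test counts are bounded by 1 and K", {
  set.seed(10)
  for (i in 1:5) {
    L <- matrix(rnorm(50 * 6), 50, 6)
    L[, 6] <- L[, 1] + rnorm(50, sd = 0.2)  # induce correlation
    m <- effectiveTests(L)
    expect_gte(m, 1); expect_lte(m, 6)
  }
})

test_that("Bonferroni thresholds reproduce printed arithmetic", {
  expect_equal(bonferroni(5e-8, 23)$printed, 2.17e-9)
  expect_equal(bonferroni(0.05, 496)$printed, 1.01e-4)
  expect_equal(bonferroni(0.05, 1)$threshold, 0.05)
  expect_error(bonferroni(0.05, 0.5), "divisor")
  expect_error(bonferroni(1.5, 10))
})

test_that("variant scan equals per-variant linear model fits", {
  set.seed(11)
  n <- 40
  L <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  age <- rnorm(n, 60, 8); sex <- rbinom(n, 1, 0.5)
  scan <- variantScan(L, G, age = age, sex = sex)
  for (v in 1:3) for (f in 1:2) {
    lmfit <- summary(lm(L[, f] ~ G[, v] + age + sex))$coefficients
    row <- scan[scan$variant == paste0("v", v) &
                scan$factor == colnames(L)[f], ]
    expect_equal(row$beta, lmfit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, lmfit[2, 2], tolerance = 1e-10)
    expect_equal(row$p, lmfit[2, 4], tolerance = 1e-10)
  }
})

test_that("a dosage collinear with a factor gives beta 1 and p of zero", {
  set.seed(12)
  g <- rbinom(50, 2, 0.4)
  L <- cbind(f1 = as.numeric(g))
  scan <- variantScan(L, matrix(g, dimnames = list(NULL, "v1")))
  expect_equal(scan$beta, 1, tolerance = 1e-10)
  expect_lt(scan$p, 1e-200)
})

test_that("scan p-values are invariant to affine dosage rescaling", {
  set.seed(13)
  n <- 60
  L <- matrix(rnorm(n * 2), n, 2)
  G <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  p1 <- variantScan(L, G)$p
  p2 <- variantScan(L, 2 * G + 1)$p
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("monomorphic variants are skipped and flagged", {
  set.seed(14)
  G <- cbind(v1 = rbinom(30, 2, 0.4), v2 = rep(0, 30))
  scan <- variantScan(matrix(rnorm(60), 30, 2), G)
  expect_identical(attr(scan, "skipped"), "v2")
  expect_false("v2" %in% scan$variant)
})

test_that("disentanglement report partitions factors by the variance flag", {
  L <- matrix(rnorm(100 * 5), 100, 5)
  rep1 <- disentanglementReport(L)
  expect_equal(sum(rep1$subtle), 0)
  expect_equal(nrow(rep1), 5)
})
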