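test_that("median beat is zero when all wave amplitudes are zero", {
  p <- generativeParams(waveAmplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  b <- simulateMedianBeat(p)
  expect_equal(dim(beatSamples(b)), c(12L, 600L))
  expect_true(all(beatSamples(b) == 0))
})

test_that("R-wave projection follows the frontal lead geometry", {
  ## only an R wave, axis 0 degrees: positive in lead I (cos 0 = 1),
  ## negative in aVR (cos(-150) = -0.866), zero-ish nowhere forced
  p <- generativeParams(rAxis = 0,
                        waveAmplitudes = c(P = 0, Q = 0, R = 1, S = 0, T = 0))
  b <- simulateMedianBeat(p)
  m <- beatSamples(b)
  at <- rPeakIndex(b) + 1L
  expect_equal(unname(m["I", at]), 1, tolerance = 1e-8)
  expect_equal(unname(m["aVR", at]), cos(-150 * pi / 180), tolerance = 1e-8)
  expect_lt(m["aVR", at], 0)
  ## aVF at 90 degrees is orthogonal to a 0-degree axis
  expect_equal(unname(m["aVF", at]), 0, tolerance = 1e-8)
})

test_that("beat synthesis is additive and homogeneous in wave amplitudes", {
  a <- c(P = 0.15, Q = -0.1, R = 1, S = -0.25, T = 0.3)
  b1 <- simulateMedianBeat(generativeParams(waveAmplitudes = a))
  b2 <- simulateMedianBeat(generativeParams(waveAmplitudes = 2 * a))
  expect_equal(beatSamples(b2), 2 * beatSamples(b1), tolerance = 1e-12)
})

test_that("frontal R axis is recoverable from limb-lead amplitudes", {
  for (axis in c(-60, 0, 30, 85, 140)) {
    p <- generativeParams(rAxis = axis,
                          waveAmplitudes = c(P = 0, Q = 0, R = 1, S = 0, T = 0))
    m <- beatSamples(simulateMedianBeat(p))
    at <- 201L
    est <- unname(atan2(m["aVF", at], m["I", at]) * 180 / pi)
    expect_equal(est, axis, tolerance = 0.5)
  }
})

test_that("interval geometry: P wave tracks the PR interval monotonically", {
  centres <- vapply(c(120, 160, 200), function(pr) {
    p <- generativeParams(prInterval = pr, pAxis = 45,
                          waveAmplitudes = c(P = 0.2, Q = 0, R = 0, S = 0, T = 0))
    which.max(beatSamples(simulateMedianBeat(p))["II", ])
  }, numeric(1))
  expect_true(all(diff(centres) < 0))  # longer PR pushes P earlier
  ## spacing between P peaks matches the PR differences on the sample grid
  expect_equal(as.vector(diff(centres)) * 2, c(-40, -40), tolerance = 1)
})

test_that("beat window rejects intervals that do not fit", {
  expect_error(simulateMedianBeat(generativeParams(prInterval = 400)),
               "cannot contain")
  expect_error(simulateMedianBeat(generativeParams(qtInterval = 900)),
               "cannot contain")
})

test_that("generative parameter validity is enforced", {
  expect_error(generativeParams(prInterval = 20), "prInterval")
  expect_error(generativeParams(qtInterval = 80, qrsDuration = 90),
               "qtInterval")
  expect_error(generativeParams(ventricularRate = -5), "ventricularRate")
})

test_that("rhythm strip places beats at the expected RR spacing", {
  p <- generativeParams(ventricularRate = 60)
  r <- simulateRhythmStrip(p, duration = 10, rrJitterSd = 0, seed = 1)
  expect_identical(r@meta$rPeaks, 250 + 500 * (0:9))
  expect_equal(ncol(beatSamples(r)), 5000L)
})

test_that("baseline drift in a strip is recovered by a least-squares line", {
  ## no beats, no noise: the record is exactly the baseline
  p0 <- generativeParams(waveAmplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0),
                         baselineSlope = 0.1, baselineOffset = -0.05)
  r0 <- simulateRhythmStrip(p0, seed = 1)
  t <- (seq_len(5000) - 1) / 500
  fit <- stats::lm.fit(cbind(1, t), beatSamples(r0)["II", ])
  expect_equal(unname(fit$coefficients), c(-0.05, 0.1), tolerance = 1e-10)
  ## with beats, the fitted slope is still close to the injected drift
  p1 <- generativeParams(baselineSlope = 0.1)
  r1 <- simulateRhythmStrip(p1, seed = 1)
  fit1 <- stats::lm.fit(cbind(1, t), beatSamples(r1)["II", ])
  expect_equal(unname(fit1$coefficients[2]), 0.1, tolerance = 0.03)
})

test_that("rhythm strips are a pure function of inputs and seed", {
  p <- generativeParams(noiseSd = 0.05)
  r1 <- simulateRhythmStrip(p, rrJitterSd = 0.02, seed = 9)
  r2 <- simulateRhythmStrip(p, rrJitterSd = 0.02, seed = 9)
  expect_identical(beatSamples(r1), beatSamples(r2))
  r3 <- simulateRhythmStrip(p, rrJitterSd = 0.02, seed = 10)
  expect_false(identical(beatSamples(r1), beatSamples(r3)))
})

test_that("too-slow rates are rejected for short strips", {
  expect_error(simulateRhythmStrip(generativeParams(ventricularRate = 20),
                                   duration = 2), "at least 2")
})

test_that("outcomes collapse to the intercept when coefficients vanish", {
  om <- list(continuous = list(y = list(intercept = 3.5, coef = numeric(0),
                                        noiseSd = 0)),
             binary = NULL, survival = NULL)
  pop <- samplePopulation(50, outcomeModel = om, seed = 1)
  expect_true(all(pop$phenotypes$y == 3.5))
})

test_that("null logistic model gives prevalence 0.5 at large n", {
  om <- list(continuous = NULL,
             binary = list(d = list(intercept = 0, coef = numeric(0))),
             survival = NULL)
  pop <- samplePopulation(10000, outcomeModel = om, seed = 2)
  ## binomial MC error: 3 * sqrt(0.25 / 10000) = 0.015
  expect_lt(abs(mean(pop$phenotypes$d) - 0.5), 0.015)
})

test_that("population sampling is deterministic given the seed", {
  a <- samplePopulation(40, seed = 5)
  b <- samplePopulation(40, seed = 5)
  expect_identical(a$params, b$params)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("age and sex follow the configured cohort demography", {
  pop <- samplePopulation(20000, seed = 6)
  expect_true(all(pop$phenotypes$age >= 40 & pop$phenotypes$age <= 80))
  expect_equal(mean(pop$phenotypes$age), 64.6, tolerance = 0.35)
  expect_equal(mean(pop$phenotypes$sex == 0), 0.516, tolerance = 0.015)
})

test_that("non-positive-semidefinite correlation matrices are rejected", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3,
              dimnames = rep(list(c("ventricular_rate", "pr_interval",
                                    "qrs_duration")), 2))
  expect_error(samplePopulation(10, correlation = R),
               "positive semi-definite")
})

test_that("genotype dosages follow Hardy-Weinberg expectations", {
  g <- simulateGenotypes(10000, 4, mafs = 0.5, seed = 3)
  ## var(dosage) = 2 * 0.5 * 0.5 = 0.5; 3 MC standard errors
  expect_true(all(abs(colMeans(dosages(g)) - 1) < 3 * sqrt(0.5 / 10000)))
  expect_error(simulateGenotypes(10, 2, mafs = 0.7), "mafs")
})

test_that("zero variants yields a valid empty genotype object", {
  g <- simulateGenotypes(10, 0, seed = 1)
  expect_true(validObject(g))
  expect_equal(dim(dosages(g)), c(10L, 0L))
})

test_that("without planted effects, parameters are independent of dosages", {
  pop <- samplePopulation(2000, outcomeModel = NULL, seed = 8)
  g <- simulateGenotypes(2000, 20, mafs = 0.3, seed = 9)
  r <- suppressWarnings(cor(dosages(g), as.matrix(pop$params)))
  r <- r[, apply(pop$params, 2, sd) > 0]
  expect_lt(max(abs(r)), 0.1)   # null correlations at n = 2000
})

test_that("planted genotype effects shift parameters additively", {
  pop <- samplePopulation(500, outcomeModel = NULL, seed = 10)
  g <- simulateGenotypes(500, 2, mafs = 0.4,
                         effectSpec = list(v1 = c(qrs_duration = 4)), seed = 11)
  shifted <- applyGenotypeEffects(pop$params, g)
  expect_equal(shifted$qrs_duration,
               pop$params$qrs_duration + 4 * dosages(g)[, "v1"])
  expect_identical(shifted$pr_interval, pop$params$pr_interval)
})
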