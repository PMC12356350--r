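#' Pearson correlation between latent factors and ECG parameters
#'
#' Column-by-column Pearson correlations. Zero-variance columns yield `NA`
#' entries, which are flagged in the `"undefined"` attribute rather than
#' raising an error.
#'
#' @param latents n x K matrix of latent factors
#' @param params n x p matrix/data.frame of traditional ECG parameters
#' @return K x p correlation matrix; attribute `undefined` marks entries
#'   with a zero-variance column
#' @export
latentCorrelations <- function(latents, params) {
  latents <- as.matrix(latents); params <- as.matrix(params)
  stopifnot(nrow(latents) == nrow(params), nrow(latents) >= 3)
  sdL <- apply(latents, 2, stats::sd)
  sdP <- apply(params, 2, stats::sd)
  r <- suppressWarnings(stats::cor(latents, params))
  undef <- outer(sdL == 0, sdP == 0, "|")
  r[undef] <- NA_real_
  attr(r, "undefined") <- undef
  r
}

## z-scale columns, flagging zero-variance ones.
zscale <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 2, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("zero-variance predictor column(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "))
  scale(m)
}

#' Multivariable linear model of an outcome on latent factors
#'
#' Ordinary least squares of a continuous outcome on all latent factors
#' plus age and sex. Latent predictors are z-scaled inside the fitter so
#' coefficients are per standard-deviation change. Reports classical
#' standard errors, Wald p-values and the adjusted R-squared
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param outcome numeric outcome vector
#' @param latents n x K matrix of latent factors (z-scaled internally)
#' @param age,sex covariate vectors (optional; included untransformed)
#' @param outcomeName label for the result
#' @return list of class `"assocResult"`: `outcome`, `coefficients`
#'   (data.frame: term, estimate, se, p), `adjR2`, `r2`, `n`
#' @export
fitContinuous <- function(outcome, latents, age = NULL, sex = NULL,
                          outcomeName = "outcome") {
  Z <- zscale(latents)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("factor", seq_len(ncol(Z)))
  df <- data.frame(.y = outcome, Z, check.names = FALSE)
  if (!is.null(age)) df$age <- age
  if (!is.null(sex)) df$sex <- sex
  n <- nrow(df); p <- ncol(df) - 1L
  if (n <= p + 2) stop("need n > p + 2 observations")
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < p + 1L) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; aliased columns: ",
         paste(rownames(al), collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  res <- list(outcome = outcomeName,
              coefficients = data.frame(term = rownames(co),
                                        estimate = co[, 1], se = co[, 2],
                                        p = co[, 4], row.names = NULL,
                                        stringsAsFactors = FALSE),
              adjR2 = sm$adj.r.squared, r2 = sm$r.squared, n = n)
  class(res) <- "assocResult"
  res
}

#' Compare latent-factor and traditional-parameter models
#'
#' Fits the same outcome (always adjusted for age and sex when supplied)
#' once on the latent factors and once on the traditional ECG parameters,
#' and reports the paired adjusted R-squared values and their difference.
#'
#' @param outcome numeric outcome
#' @param latents n x K latent matrix
#' @param traditionalParams n x p matrix of traditional ECG parameters
#' @param age,sex optional covariates used in both fits
#' @param outcomeName label
#' @return data.frame with one row per model plus the difference
#'   (latents minus traditional) as attribute `difference`
#' @export
compareModels <- function(outcome, latents, traditionalParams,
                          age = NULL, sex = NULL, outcomeName = "outcome") {
  fL <- fitContinuous(outcome, latents, age, sex, outcomeName)
  fT <- fitContinuous(outcome, traditionalParams, age, sex, outcomeName)
  out <- data.frame(outcome = outcomeName,
                    model = c("latents", "traditional"),
                    adjR2 = c(fL$adjR2, fT$adjR2),
                    stringsAsFactors = FALSE)
  attr(out, "difference") <- fL$adjR2 - fT$adjR2
  out
}

#' Logistic regression of a binary outcome on latent factors
#'
#' Maximum-likelihood logistic fit adjusted for age and sex, with latent
#' predictors z-scaled so coefficients are per SD. Wald p-values per factor;
#' when a Bonferroni threshold is supplied a significance flag is added.
#' Quasi-separation (fitted probabilities numerically 0 or 1) is reported.
#'
#' @param outcome 0/1 outcome vector; both classes must be present
#' @param latents n x K latent matrix
#' @param age,sex optional covariates
#' @param threshold optional Bonferroni-corrected significance threshold
#' @param outcomeName label
#' @return list of class `"assocResult"` with `coefficients`
#'   (term, estimate, se, p, and `significant` if thresholded),
#'   `logLik`, `n`, `separation` flag
#' @export
fitBinary <- function(outcome, latents, age = NULL, sex = NULL,
                      threshold = NULL, outcomeName = "outcome") {
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome has a single class; logistic model undefined")
  Z <- zscale(latents)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("factor", seq_len(ncol(Z)))
  df <- data.frame(.y = outcome, Z, check.names = FALSE)
  if (!is.null(age)) df$age <- age
  if (!is.null(sex)) df$sex <- sex
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  eta <- stats::fitted(fit)
  separation <- any(eta < 1e-8 | eta > 1 - 1e-8)
  if (separation)
    warning("fitted probabilities numerically 0 or 1: possible separation")
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    p = co[, 4], row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(threshold)) tab$significant <- tab$p < threshold
  res <- list(outcome = outcomeName, coefficients = tab,
              logLik = as.numeric(stats::logLik(fit)), n = nrow(df),
              separation = separation)
  class(res) <- "assocResult"
  res
}

#' Cox proportional hazards model with z-scaled predictors
#'
#' Partial-likelihood fit (Efron tie handling) of survival on z-scaled
#' predictors plus optional age/sex covariates. Hazard ratios are per SD of
#' the predictor with normal-approximation 95% confidence intervals
#' `exp(coef +/- 1.96 * SE)`.
#'
#' @param time follow-up times (> 0)
#' @param event 0/1 event indicators; at least one event required
#' @param predictors n x K matrix (z-scaled internally)
#' @param age,sex optional covariates (untransformed)
#' @return list of class `"survResult"`: `table` (term, hr, ciLow, ciHigh,
#'   p), `nEvents`, `medianFollowUp`, `n`
#' @export
fitSurvival <- function(time, event, predictors, age = NULL, sex = NULL) {
  if (any(time <= 0)) stop("survival times must be positive")
  if (sum(event) < 1) stop("at least one event is required")
  Z <- zscale(predictors)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("factor", seq_len(ncol(Z)))
  df <- data.frame(Z, check.names = FALSE)
  if (!is.null(age)) df$age <- age
  if (!is.null(sex)) df$sex <- sex
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ciLow = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ciHigh = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- list(table = tab, nEvents = sum(event),
              medianFollowUp = stats::median(time), n = length(time))
  class(res) <- "survResult"
  res
}

#' Effective number of independent tests among correlated factors
#'
#' Eigenvalue-based estimator: eigendecompose the factor correlation matrix
#' and count
#' \eqn{m_{eff} = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i \rfloor) ]}.
#' Identity correlation gives K; perfectly collinear factors collapse to the
#' number of independent blocks. Eigenvalues are clamped at zero and rounded
#' at 1e-9 so exact-rank inputs are not perturbed by floating-point noise.
#'
#' @param latents n x K matrix of factors, or a K x K correlation matrix
#' @return the effective number of independent tests (numeric scalar)
#' @examples
#' effectiveTests(diag(32))  # 32
#' @export
effectiveTests <- function(latents) {
  m <- as.matrix(latents)
  R <- if (nrow(m) == ncol(m) && max(abs(m - t(m))) < 1e-12 &&
           all(abs(diag(m) - 1) < 1e-12)) m else stats::cor(m)
  if (ncol(R) < 2) stop("at least 2 factors are required")
  if (!all(is.finite(R))) stop("non-finite correlations")
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lambda <- round(pmax(lambda, 0), 9)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level, in (0, 1)
#' @param divisor number of (effective) tests, >= 1
#' @return list with `threshold` (full precision `alpha / divisor`) and
#'   `printed` (rounded to 3 significant figures)
#' @examples
#' bonferroni(5e-8, 23)$printed   # 2.17e-9
#' bonferroni(0.05, 496)$printed  # 1.01e-4
#' @export
bonferroni <- function(alpha, divisor) {
  stopifnot(alpha > 0, alpha < 1)
  if (divisor < 1) stop("divisor must be >= 1")
  thr <- alpha / divisor
  list(threshold = thr, printed = signif(thr, 3))
}

#' Additive-dosage variant scan of the latent factors
#'
#' For every (variant, factor) pair, fits the linear model
#' `factor ~ dosage + age + sex` and reports the additive effect, its
#' standard error and Wald p-value in GWAS summary-statistics form. The
#' scan is computed by Frisch-Waugh residualisation (latents and dosages
#' residualised on the covariates), which is algebraically identical to the
#' full per-pair regression but runs as two matrix products. Monomorphic
#' variants are flagged and skipped.
#'
#' @param latents n x K latent matrix
#' @param genotypes a [GenotypeMatrix-class] or n x m dosage matrix
#' @param age,sex optional covariate vectors
#' @param effectAllele label written to the `effect_allele` column
#' @return data.frame with columns variant, factor, effect_allele, beta,
#'   se, p, n; attribute `skipped` lists monomorphic variants
#' @export
variantScan <- function(latents, genotypes, age = NULL, sex = NULL,
                        effectAllele = "A") {
  L <- as.matrix(latents)
  G <- if (is(genotypes, "GenotypeMatrix")) dosages(genotypes) else as.matrix(genotypes)
  stopifnot(nrow(L) == nrow(G))
  n <- nrow(L)
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  if (is.null(colnames(L))) colnames(L) <- paste0("factor", seq_len(ncol(L)))
  mono <- which(apply(G, 2, function(g) stats::var(g) == 0))
  keep <- setdiff(seq_len(ncol(G)), mono)
  X <- cbind(intercept = rep(1, n), age = age, sex = sex)
  q <- qr(X)
  Lr <- qr.resid(q, L)
  Gr <- qr.resid(q, G[, keep, drop = FALSE])
  gg <- colSums(Gr^2)
  ll <- colSums(Lr^2)
  M <- crossprod(Gr, Lr)                       # m x K inner products
  beta <- M / gg
  dfree <- n - ncol(X) - 1L
  rss <- pmax(outer(rep(1, length(gg)), ll) - M^2 / gg, 0)
  se <- sqrt(rss / dfree / gg)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), dfree)
  out <- data.frame(
    variant = rep(colnames(G)[keep], times = ncol(L)),
    factor = rep(colnames(L), each = length(keep)),
    effect_allele = effectAllele,
    beta = as.vector(beta), se = as.vector(se), p = as.vector(pval),
    n = n, stringsAsFactors = FALSE)
  attr(out, "skipped") <- colnames(G)[mono]
  out
}

#' Per-factor variance and disentanglement bookkeeping
#'
#' Reports each factor's variance across the cohort, its maximum absolute
#' correlation with any other factor, and flags "subtle-morphology" factors
#' whose variance falls below the threshold (default 0.001). Variances are
#' only meaningful on unstandardised latents.
#'
#' @param latents n x K matrix of unstandardised latent factors
#' @param varianceThreshold subtle-morphology flag cutoff (default 1e-3)
#' @return data.frame with columns factor, variance, maxAbsCor, subtle
#' @export
disentanglementReport <- function(latents, varianceThreshold = 1e-3) {
  L <- as.matrix(latents)
  K <- ncol(L)
  if (is.null(colnames(L))) colnames(L) <- paste0("factor", seq_len(K))
  v <- apply(L, 2, stats::var)
  R <- suppressWarnings(abs(stats::cor(L)))
  diag(R) <- 0
  maxAbs <- apply(R, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(factor = colnames(L), variance = v, maxAbsCor = maxAbs,
             subtle = v < varianceThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.assocResult <- function(x, ...) {
  cat(sprintf("Association model for '%s' (n = %d)\n", x$outcome, x$n))
  if (!is.null(x$adjR2)) cat(sprintf("  adjusted R^2 = %.4f\n", x$adjR2))
  if (!is.null(x$logLik)) cat(sprintf("  log-likelihood = %.3f\n", x$logLik))
  print(utils::head(x$coefficients, 8), ...)
  if (nrow(x$coefficients) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
print.survResult <- function(x, ...) {
  cat(sprintf("Cox model: %d events in %d subjects, median follow-up %.2f\n",
              x$nEvents, x$n, x$medianFollowUp))
  print(x$table, ...)
  invisible(x)
}
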