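#' Transform z-scale effect sizes back to the original latent scale
#'
#' Association scans are run on z-transformed latent factors; decoding
#' requires effects on the original scale, obtained as
#' `beta_original = beta_z * sd_k` with the per-factor cohort SDs stored in
#' the model artifact.
#'
#' @param effectsZ per-factor effect sizes on the z scale
#' @param cohortSds per-factor cohort SDs (> 0), e.g. `latentStats(model)$sd`
#' @return per-factor effects on the original latent scale
#' @export
toOriginalScale <- function(effectsZ, cohortSds) {
  if (any(cohortSds <= 0)) stop("cohort SDs must be positive")
  stopifnot(length(effectsZ) == length(cohortSds))
  effectsZ * cohortSds
}

#' Decode the morphological effect of a variant
#'
#' Additively perturbs the average latent vector by the variant's
#' per-factor effect sizes (original scale), keeping only factors whose
#' association p-value passes the suggestive threshold (default 1e-5), and
#' decodes both the baseline and the perturbed latent vectors:
#' `perturbed_k = mean_k + dose * effect_k * I(p_k < threshold)`.
#'
#' @param model a [BetaVAE-class]
#' @param meanLatent length-K cohort-average latent vector on the original
#'   scale; defaults to the model's stored cohort means
#' @param profile a [VariantEffectProfile-class]
#' @param pThreshold suggestive p-value filter (default 1e-5)
#' @return list with `baseline` and `perturbed` ([MedianBeat-class]) and
#'   `delta`, the samplewise 12 x T difference matrix (perturbed - baseline)
#' @export
decodeVariantEffect <- function(model, profile,
                                meanLatent = latentStats(model)$mean,
                                pThreshold = 1e-5) {
  K <- latentDim(model)
  if (length(profile@effects) != K || length(meanLatent) != K)
    stop(sprintf("profile and mean latent must have length K = %d", K))
  keep <- as.numeric(profile@pValues < pThreshold)
  perturbed <- meanLatent + profile@dose * profile@effects * keep
  b0 <- decodeLatent(model, meanLatent, standardized = FALSE)
  b1 <- decodeLatent(model, perturbed, standardized = FALSE)
  delta <- beatSamples(b1) - beatSamples(b0)
  list(baseline = b0, perturbed = b1, delta = delta)
}

#' Render a variant-effect report
#'
#' Writes a deterministic per-lead table of the maximum absolute morphology
#' change (TSV, byte-identical across runs for identical inputs) and,
#' optionally, a 12-lead overlay figure of the baseline and perturbed beats.
#'
#' @param effect list from [decodeVariantEffect()]
#' @param file path of the TSV table to write
#' @param plotFile optional path of a PNG overlay figure
#' @return (invisibly) the per-lead summary data.frame with columns `lead`,
#'   `maxAbsDelta`, `atSample`
#' @export
renderEffectReport <- function(effect, file = NULL, plotFile = NULL) {
  delta <- effect$delta
  leads <- rownames(delta) %||% ECG_LEADS
  tab <- data.frame(
    lead = leads,
    maxAbsDelta = apply(abs(delta), 1, max),
    atSample = apply(abs(delta), 1, which.max) - 1L,
    stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(format(tab, digits = 10), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(plotFile)) {
    grDevices::png(plotFile, width = 1200, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    op <- graphics::par(mfrow = c(4, 3), mar = c(2, 3, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    base <- beatSamples(effect$baseline)
    pert <- beatSamples(effect$perturbed)
    for (i in seq_len(12)) {
      ylim <- range(base[i, ], pert[i, ])
      graphics::plot(base[i, ], type = "l", col = "grey30", ylim = ylim,
                     main = leads[i], xlab = "", ylab = "mV")
      graphics::lines(pert[i, ], col = "firebrick")
    }
  }
  invisible(tab)
}
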