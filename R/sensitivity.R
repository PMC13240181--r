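## Two-step sensitivity analysis: nominal SPR at the host WET, then SPR
## recomputed with calibration factors looked up at a perturbed WET while
## the CT numbers are held constant.  The perturbation is applied both as
## an increase and a decrease.

#' SPR of fixed CT numbers at a given calibration WET
#'
#' Looks up the weighting factors at `wet` and runs the full
#' RED/EAN/I/Bethe chain on the fixed low/high CT numbers.
#'
#' @param hLow,hHigh CT numbers (HU) of the tissue.
#' @param wet WET (mm) at which the calibration factors are taken.
#' @param curve a [CalibrationCurve-class].
#' @param settings a [BetheSettings-class].
#' @param mapping EAN-to-I mapping.
#' @return stopping-power ratio.
#' @export
sprAtWet <- function(hLow, hHigh, wet, curve,
                     settings = betheSettings(),
                     mapping = defaultIvalueMapping()) {
    alpha <- lookupAlpha(curve, wet)
    muL <- hLow / 1000 + 1
    muH <- hHigh / 1000 + 1
    red <- redFromCtn(muL, muH, alpha[["alpha_red"]])
    ean <- eanFromCtn(muL, muH, red, alpha[["alpha_ean"]])$ean
    betheSpr(red, ivalueFromEan(ean, mapping), settings)
}

#' Size-biased CT numbers of tissues at a host WET
#'
#' Applies the hardening model's multiplicative bias to the tissues'
#' nominal dual-energy attenuations at the given host WET, emulating the
#' CT numbers that surrogates exhibit inside a phantom of that size.
#'
#' @param tissues data frame with columns `name`, `reference_red`,
#'   `reference_ean`, `muLow`, `muHigh` (see [defaultSurrogates()]).
#' @param wet host WET (mm).
#' @param hardening a [HardeningModel-class].
#' @return data frame with columns `name`, `H_low`, `H_high`.
#' @export
tissueCtns <- function(tissues, wet,
                       hardening = defaultHardeningModel()) {
    bias <- t(vapply(tissues$reference_ean,
        function(z) hardeningBias(hardening, wet, z), c(low = 0,
            high = 0)))
    data.frame(name = tissues$name,
        H_low = (tissues$muLow * bias[, "low"] - 1) * 1000,
        H_high = (tissues$muHigh * bias[, "high"] - 1) * 1000)
}

#' WET-perturbation sensitivity of SPR prediction
#'
#' For every tissue, host WET, method and perturbation, computes the
#' nominal SPR (calibration factors at the host WET) and the SPR with
#' factors looked up at the perturbed WET, holding the CT numbers
#' constant.  Perturbations are applied with both signs; the default
#' magnitude would typically come from [maxPairwiseDeviation()] of the
#' phantom sweep.  Inputs are expected couch-free.
#'
#' @param tissues tissue table (see [tissueCtns()]).
#' @param wetGrid host WETs (mm) to evaluate.
#' @param deltaMm perturbation magnitude(s).  Interpreted in mm
#'   (`mode = "mm"`) or as percent of the host WET
#'   (`mode = "percent"`).
#' @param curves named list of [CalibrationCurve-class] (names are the
#'   method tags).
#' @param hardening hardening model used to derive the tissues' host CT
#'   numbers (see [tissueCtns()]).
#' @param settings a [BetheSettings-class].
#' @param mapping EAN-to-I mapping.
#' @param mode perturbation units.
#' @return tidy data frame: tissue, method, wet_mm, delta_mm,
#'   spr_nominal, spr_perturbed, delta_spr_percent.
#' @export
sensitivityTable <- function(tissues, wetGrid, deltaMm, curves,
                             hardening = defaultHardeningModel(),
                             settings = betheSettings(),
                             mapping = defaultIvalueMapping(),
                             mode = c("mm", "percent")) {
    mode <- match.arg(mode)
    if (!nrow(tissues))
        stop("empty tissue list", call. = FALSE)
    if (!length(curves) || is.null(names(curves)))
        stop("'curves' must be a named list of calibration curves",
            call. = FALSE)
    stopifnot(all(vapply(curves, is, TRUE, "CalibrationCurve")))
    out <- list()
    for (w in wetGrid) {
        ctn <- tissueCtns(tissues, w, hardening)
        for (m in names(curves)) {
            curve <- curves[[m]]
            nominal <- vapply(seq_len(nrow(ctn)), function(k)
                sprAtWet(ctn$H_low[k], ctn$H_high[k], w, curve,
                    settings, mapping), 0)
            for (d in deltaMm) {
                dmm <- if (mode == "percent") w * d / 100 else d
                signs <- if (dmm == 0) 0 else c(-1, 1)
                for (s in signs) {
                    wp <- max(w + s * dmm, 0)
                    pert <- vapply(seq_len(nrow(ctn)), function(k)
                        sprAtWet(ctn$H_low[k], ctn$H_high[k], wp,
                            curve, settings, mapping), 0)
                    out[[length(out) + 1L]] <- data.frame(
                        tissue = ctn$name, method = m, wet_mm = w,
                        delta_mm = s * dmm, spr_nominal = nominal,
                        spr_perturbed = pert,
                        delta_spr_percent =
                            100 * (pert - nominal) / nominal)
                }
            }
        }
    }
    do.call(rbind, out)
}
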