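## Voxel-wise tissue characterization chain: relative electron density
## (RED) and effective atomic number (EAN) from the calibrated dual-energy
## blend, mean excitation energy from EAN, and stopping-power ratio (SPR)
## via the Bethe equation.

#' Bethe-equation settings constructor and accessors
#'
#' @param energyMeV proton kinetic energy in MeV (default 100; SPR is
#'   only weakly energy-dependent over therapeutic energies).
#' @param waterIvalueEV mean excitation energy of water in eV
#'   (default 75).
#' @return a [BetheSettings-class].
#' @export
betheSettings <- function(energyMeV = 100, waterIvalueEV = 75) {
    new("BetheSettings", energyMeV = energyMeV,
        waterIvalueEV = waterIvalueEV)
}

#' @rdname betheSettings
#' @param settings a [BetheSettings-class].
#' @return `betaSquared()` returns the relativistic \eqn{\beta^2 =
#'   1 - (1 + E/m_p c^2)^{-2}} of the proton.
#' @export
betaSquared <- function(settings) {
    1 - (1 + settings@energyMeV / settings@protonRestMeV)^-2
}

#' Relative electron density from the calibrated dual-energy blend
#'
#' \eqn{\rho_e = \alpha\,\mu_L + (1-\alpha)\,\mu_H} with
#' \eqn{\mu_E = H_E/1000 + 1}.
#'
#' @param muLow,muHigh relative attenuation at low/high tube voltage
#'   (vectorized).
#' @param alphaRed weighting factor from the calibration curve.
#' @return relative electron density.
#' @export
redFromCtn <- function(muLow, muHigh, alphaRed) {
    alphaRed * muLow + (1 - alphaRed) * muHigh
}

#' Effective atomic number from the calibrated dual-energy blend
#'
#' \eqn{Z = Z_w \left[(\alpha_E \mu_L + (1-\alpha_E)\mu_H)/\rho_e
#' \right]^{1/n}}.  Voxels with \eqn{\rho_e} at or below `redFloor` are
#' classified as air and get the water fallback EAN with `air = TRUE`;
#' a non-positive blend numerator likewise falls back to \eqn{Z_w} with
#' `fallback = TRUE` (no exception is raised in either case).
#'
#' @inheritParams redFromCtn
#' @param red relative electron density of the voxel(s).
#' @param alphaEan EAN weighting factor.
#' @param n EAN exponent (3.1).
#' @param zw water EAN under that convention.
#' @param redFloor air classification threshold (default 0.01).
#' @return list with numeric `ean` and logical `air`, `fallback`.
#' @export
eanFromCtn <- function(muLow, muHigh, red, alphaEan, n = 3.1, zw = 7.45,
                       redFloor = 0.01) {
    blend <- alphaEan * muLow + (1 - alphaEan) * muHigh
    air <- red <= redFloor
    fallback <- !air & blend <= 0
    ean <- rep(zw, length.out = max(length(blend), length(red)))
    ok <- !air & !fallback
    if (any(ok)) {
        blendOk <- rep(blend, length.out = length(ean))[ok]
        redOk <- rep(red, length.out = length(ean))[ok]
        ean[ok] <- zw * (blendOk / redOk)^(1 / n)
    }
    list(ean = ean, air = air, fallback = fallback)
}

#' EAN to mean-excitation-energy mapping
#'
#' Heuristic piecewise log-linear conversion: `ln I` is interpolated
#' linearly in Z between sorted knots and clamped at the end knots.  The
#' packaged default mapping is a synthetic stand-in anchored so that the
#' water EAN maps exactly to the water I-value; it is an editable table,
#' not a vendor-equivalent conversion.
#'
#' @param ean effective atomic number (vectorized).
#' @param mapping data frame with sorted columns `ean`, `i_ev`
#'   (at least two knots); see [defaultIvalueMapping()].
#' @return mean excitation energy in eV.
#' @examples
#' ivalueFromEan(7.45)    # 75 eV, the water anchor
#' @export
ivalueFromEan <- function(ean, mapping = defaultIvalueMapping()) {
    if (!all(c("ean", "i_ev") %in% names(mapping)) ||
        nrow(mapping) < 2L)
        stop("mapping needs >= 2 knots with columns ean, i_ev",
            call. = FALSE)
    if (is.unsorted(mapping$ean, strictly = TRUE))
        stop("mapping knots must be strictly increasing in ean",
            call. = FALSE)
    exp(stats::approx(mapping$ean, log(mapping$i_ev), xout = ean,
        rule = 2)$y)
}

#' @rdname ivalueFromEan
#' @param zw,waterIvalueEV water anchor knot.
#' @export
defaultIvalueMapping <- function(zw = 7.45, waterIvalueEV = 75) {
    data.frame(ean = c(6.0, zw, 13.8),
        i_ev = c(65, waterIvalueEV, 112))
}

#' Stopping-power ratio via the Bethe equation
#'
#' \deqn{\mathrm{SPR} = \rho_e \,
#'   \frac{\ln\!\left(2 m_e c^2 \beta^2 / (I (1-\beta^2))\right) - \beta^2}
#'        {\ln\!\left(2 m_e c^2 \beta^2 / (I_w (1-\beta^2))\right) - \beta^2}}
#' with energies in eV inside the logarithms.  Linear in \eqn{\rho_e} and
#' strictly decreasing in I; water (\eqn{\rho_e = 1}, \eqn{I = I_w})
#' gives exactly 1.
#'
#' @param red relative electron density (vectorized).
#' @param iValueEV mean excitation energy in eV.
#' @param settings a [BetheSettings-class].
#' @return stopping-power ratio.
#' @examples
#' betheSpr(1, 75)       # 1 by definition
#' betheSpr(1.1, 75)     # 1.1, linear in electron density
#' @export
betheSpr <- function(red, iValueEV, settings = betheSettings()) {
    if (any(iValueEV <= 0))
        stop("mean excitation energy must be positive", call. = FALSE)
    bsq <- betaSquared(settings)
    meEV <- settings@electronRestMeV * 1e6
    num <- log(2 * meEV * bsq / (iValueEV * (1 - bsq))) - bsq
    if (any(num <= 0))
        stop(paste("Bethe bracket non-positive: mean excitation energy",
            "outside the validity range at this proton energy"),
            call. = FALSE)
    den <- log(2 * meEV * bsq /
        (settings@waterIvalueEV * (1 - bsq))) - bsq
    red * num / den
}

#' Voxel-wise SPR image from a dual-energy slice
#'
#' Runs the full chain per voxel: calibration lookup at the slice WET,
#' RED and EAN from the dual-energy blend, mean excitation energy from
#' the EAN mapping, SPR from the Bethe equation.  Air voxels (RED at or
#' below `redFloor`) get SPR 0.  Provenance (method tag, WET used,
#' proton energy) is recorded on the result.
#'
#' @param deImage a [DualEnergyImage-class].
#' @param curve a [CalibrationCurve-class] (its method tag should match
#'   the TEM used to estimate `wet`).
#' @param wet slice WET in mm for the calibration lookup; if `NULL`
#'   (default) it is estimated from the low-energy image with the
#'   curve's own method (the per-slice lookup policy).
#' @param settings a [BetheSettings-class].
#' @param mapping EAN-to-I mapping (see [ivalueFromEan()]).
#' @param redFloor air classification threshold.
#' @return an [SprImage-class].
#' @export
sprImage <- function(deImage, curve, wet = NULL,
                     settings = betheSettings(),
                     mapping = defaultIvalueMapping(), redFloor = 0.01) {
    stopifnot(is(deImage, "DualEnergyImage"),
        is(curve, "CalibrationCurve"))
    muL <- huToMu(deImage@low)@pixels
    muH <- huToMu(deImage@high)@pixels
    if (is.null(wet))
        wet <- estimateWet(huToMu(deImage@low), temMethod(curve))
    alpha <- lookupAlpha(curve, wet)
    red <- redFromCtn(muL, muH, alpha[["alpha_red"]])
    eanRes <- eanFromCtn(as.vector(muL), as.vector(muH), as.vector(red),
        alpha[["alpha_ean"]], redFloor = redFloor)
    iVal <- ivalueFromEan(eanRes$ean, mapping)
    spr <- betheSpr(as.vector(red), iVal, settings)
    spr[eanRes$air] <- 0
    new("SprImage",
        pixels = matrix(spr, nrow(muL), ncol(muL)),
        spacing = deImage@low@spacing,
        sliceIndex = deImage@low@sliceIndex,
        provenance = list(method = temMethod(curve), wet_mm = wet,
            energy_mev = settings@energyMeV,
            water_i_ev = settings@waterIvalueEV))
}

#' Reference SPR of a tissue from its reference parameters
#'
#' Computes the SPR directly from reference relative electron density and
#' effective atomic number (via the same EAN-to-I mapping), bypassing the
#' imaging chain; used as the comparison standard in self-consistency
#' checks.
#'
#' @param red,ean reference parameters (vectorized).
#' @param settings a [BetheSettings-class].
#' @param mapping EAN-to-I mapping.
#' @return stopping-power ratio.
#' @export
referenceSpr <- function(red, ean, settings = betheSettings(),
                         mapping = defaultIvalueMapping()) {
    betheSpr(red, ivalueFromEan(ean, mapping), settings)
}

#' Predict insert SPRs from ROI measurements
#'
#' Applies the RED/EAN/I/Bethe chain to per-insert ROI mean CT numbers
#' with the weighting factors looked up at the given WET, and reports the
#' reference SPR alongside.
#'
#' @param measurements measurement table (see [simulateDect()]).
#' @param curve a [CalibrationCurve-class].
#' @param wet WET (mm) for the calibration lookup.
#' @param settings a [BetheSettings-class].
#' @param mapping EAN-to-I mapping.
#' @return the measurement table with added columns `red_pred`,
#'   `ean_pred`, `spr_pred`, `spr_ref`, `spr_err_pct`.
#' @export
predictInsertSpr <- function(measurements, curve, wet,
                             settings = betheSettings(),
                             mapping = defaultIvalueMapping()) {
    .measCheck(measurements)
    alpha <- lookupAlpha(curve, wet)
    muL <- measurements$H_low / 1000 + 1
    muH <- measurements$H_high / 1000 + 1
    red <- redFromCtn(muL, muH, alpha[["alpha_red"]])
    ean <- eanFromCtn(muL, muH, red, alpha[["alpha_ean"]])$ean
    spr <- betheSpr(red, ivalueFromEan(ean, mapping), settings)
    sprRef <- referenceSpr(measurements$reference_red,
        measurements$reference_ean, settings, mapping)
    cbind(measurements, red_pred = red, ean_pred = ean, spr_pred = spr,
        spr_ref = sprRef,
        spr_err_pct = 100 * (spr - sprRef) / sprRef)
}
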