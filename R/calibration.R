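## Size-dependent calibration of the dual-energy weighting factors
## alpha_RED(WET) and alpha_EAN(WET): one-parameter weighted least squares
## per phantom size, piecewise-linear curve over sizes.

.measCheck <- function(measurements) {
    need <- c("H_low", "H_high", "reference_red", "reference_ean")
    if (!all(need %in% names(measurements)))
        stop("measurements need columns ",
            paste(need, collapse = ", "), call. = FALSE)
    if (!nrow(measurements))
        stop("no measurements supplied", call. = FALSE)
    invisible(TRUE)
}

## closed-form weighted LS for target ~ alpha*muL + (1-alpha)*muH
.fitAlpha <- function(muL, muH, target, weight) {
    d <- muL - muH
    denom <- sum(weight * d^2)
    if (denom <= .Machine$double.eps * max(1, sum(weight)))
        stop(paste("weighting factor unidentifiable: low- and high-energy",
            "attenuations coincide for all measurements"), call. = FALSE)
    sum(weight * d * (target - muH)) / denom
}

#' Fit the electron-density weighting factor at one phantom size
#'
#' Weighted least squares for
#' \eqn{\rho_e \approx \alpha\,\mu_L + (1-\alpha)\,\mu_H}
#' over the surrogate measurements of a single phantom size, with
#' \eqn{\mu_E = H_E/1000 + 1}.  Closed form:
#' \eqn{\alpha = \sum w (\mu_L-\mu_H)(\rho_{ref}-\mu_H) /
#' \sum w (\mu_L-\mu_H)^2}.
#'
#' @param measurements data frame with columns `H_low`, `H_high`,
#'   `reference_red`, `reference_ean` and optionally `weight`
#'   (default 1; bone surrogates may be upweighted).
#' @return fitted `alpha_red`.
#' @examples
#' m <- data.frame(H_low = 50, H_high = 20, reference_red = 1.03,
#'     reference_ean = 7.5)
#' fitAlphaRed(m)   # (1.03 - 1.02)/(1.05 - 1.02) = 1/3
#' @export
fitAlphaRed <- function(measurements) {
    .measCheck(measurements)
    w <- if ("weight" %in% names(measurements)) measurements$weight
        else rep(1, nrow(measurements))
    if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
    .fitAlpha(measurements$H_low / 1000 + 1,
        measurements$H_high / 1000 + 1, measurements$reference_red, w)
}

#' Fit the effective-atomic-number weighting factor at one phantom size
#'
#' Same one-parameter least squares as [fitAlphaRed()] but with target
#' \eqn{z = \rho_{ref} (Z_{ref}/Z_w)^n}, the EAN-exponent blend adopted
#' from the dual-energy calibration literature (exponent fixed at 3.1 by
#' the \eqn{\alpha_{EAN3.1}} convention).  The reference (not predicted)
#' electron density is used in the target, keeping the two fits decoupled
#' linear problems.
#'
#' @inheritParams fitAlphaRed
#' @param n EAN exponent (default 3.1).
#' @param zw effective atomic number of water under that convention
#'   (default 7.45).
#' @return fitted `alpha_ean`.
#' @export
fitAlphaEan <- function(measurements, n = 3.1, zw = 7.45) {
    .measCheck(measurements)
    w <- if ("weight" %in% names(measurements)) measurements$weight
        else rep(1, nrow(measurements))
    if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
    z <- measurements$reference_red *
        (measurements$reference_ean / zw)^n
    .fitAlpha(measurements$H_low / 1000 + 1,
        measurements$H_high / 1000 + 1, z, w)
}

#' Build a size-dependent calibration curve from per-size fits
#'
#' Knots must have distinct WETs; evaluation is piecewise linear with
#' constant (clamped) extrapolation outside the knot range.
#'
#' @param wet knot WET positions (mm), one per phantom size.
#' @param alphaRed,alphaEan fitted weighting factors per size.
#' @param method TEM tag that produced the WET axis.
#' @return a [CalibrationCurve-class].
#' @examples
#' cv <- buildCurve(c(100, 300), alphaRed = c(0.4, 0.6),
#'     alphaEan = c(1, 2), method = "tem-b1")
#' lookupAlpha(cv, 200)["alpha_red"]    # 0.5
#' lookupAlpha(cv, 50)["alpha_red"]     # clamped to 0.4
#' @export
buildCurve <- function(wet, alphaRed, alphaEan,
                       method = c("tem-a", "tem-b1", "tem-b2")) {
    method <- match.arg(method)
    if (anyDuplicated(wet))
        stop("duplicate knot WETs", call. = FALSE)
    ord <- order(wet)
    new("CalibrationCurve", method = method, wet = as.numeric(wet[ord]),
        alphaRed = as.numeric(alphaRed[ord]),
        alphaEan = as.numeric(alphaEan[ord]))
}

#' Evaluate a calibration curve at a WET
#'
#' @param curve a [CalibrationCurve-class].
#' @param wet WET in mm (vectorized, must be >= 0).
#' @return for scalar `wet` a named numeric `c(alpha_red, alpha_ean)`;
#'   for vector input a data frame.
#' @export
lookupAlpha <- function(curve, wet) {
    stopifnot(is(curve, "CalibrationCurve"))
    if (any(wet < 0)) stop("WET must be >= 0", call. = FALSE)
    ar <- stats::approx(curve@wet, curve@alphaRed, xout = wet,
        rule = 2)$y
    ae <- stats::approx(curve@wet, curve@alphaEan, xout = wet,
        rule = 2)$y
    if (length(wet) == 1L) c(alpha_red = ar, alpha_ean = ae)
    else data.frame(wet_mm = wet, alpha_red = ar, alpha_ean = ae)
}

#' Calibrate a TEM-specific curve from a phantom sweep
#'
#' Fits `alpha_red`/`alpha_ean` per phantom size from the sweep's
#' surrogate measurements and anchors each knot at the WET estimated for
#' that phantom by the chosen thickness estimation method, yielding the
#' method-specific size-dependent calibration curve.
#'
#' @param sweep result of [phantomSweep()] (at least two sizes).
#' @param method TEM tag selecting the WET axis.
#' @param boneWeight weight applied to measurements with
#'   `reference_ean` above `zSoft` (default 1; larger values emphasise
#'   bone surrogates).
#' @param zSoft EAN threshold separating soft and bone class.
#' @param n,zw see [fitAlphaEan()].
#' @param exclude optional character vector of insert names withheld
#'   from the fits (e.g. for hold-out validation).
#' @return a [CalibrationCurve-class].
#' @export
calibrateSweep <- function(sweep, method = c("tem-a", "tem-b1", "tem-b2"),
                           boneWeight = 1, zSoft = 8.8, n = 3.1,
                           zw = 7.45, exclude = NULL) {
    method <- match.arg(method)
    if (length(sweep) < 2L)
        stop("calibration needs at least two phantom sizes",
            call. = FALSE)
    fits <- lapply(sweep, function(s) {
        m <- s$measurements
        if (!is.null(exclude))
            m <- m[!m$insert %in% exclude, , drop = FALSE]
        m$weight <- ifelse(m$reference_ean > zSoft, boneWeight, 1)
        data.frame(wet = unname(s$wetByMethod[method]),
            alphaRed = fitAlphaRed(m),
            alphaEan = fitAlphaEan(m, n = n, zw = zw))
    })
    fits <- do.call(rbind, fits)
    buildCurve(fits$wet, fits$alphaRed, fits$alphaEan, method)
}

#' Calibration-curve CSV I/O
#'
#' Curves are serialized as CSV with columns `wet_mm`, `alpha_red`,
#' `alpha_ean`, `method` plus `#`-prefixed provenance header lines
#' (interpolation is always piecewise linear with clamping).
#'
#' @param curve a [CalibrationCurve-class].
#' @param path file path.
#' @param extraHeader optional named character vector of provenance
#'   fields.
#' @return `readCurve()` returns the curve; `writeCurve()` the path,
#'   invisibly.
#' @export
writeCurve <- function(curve, path, extraHeader = NULL) {
    stopifnot(is(curve, "CalibrationCurve"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# wetspr calibration curve",
        "# interpolation: piecewise-linear, clamped",
        if (length(extraHeader))
            sprintf("# %s: %s", names(extraHeader), extraHeader),
        "wet_mm,alpha_red,alpha_ean,method",
        sprintf("%.12g,%.12g,%.12g,%s", curve@wet, curve@alphaRed,
            curve@alphaEan, curve@method)), con)
    invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
    tab <- utils::read.csv(path, comment.char = "#",
        stringsAsFactors = FALSE)
    need <- c("wet_mm", "alpha_red", "alpha_ean", "method")
    if (!all(need %in% names(tab)))
        stop("malformed curve file: ", path, call. = FALSE)
    method <- unique(tab$method)
    if (length(method) != 1L)
        stop("curve file mixes methods: ", path, call. = FALSE)
    buildCurve(tab$wet_mm, tab$alpha_red, tab$alpha_ean, method)
}
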