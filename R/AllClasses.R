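#' @import methods
NULL

## ---- image containers -------------------------------------------------------

.validCTSlice <- function(object) {
    msg <- NULL
    px <- object@pixels
    if (!is.matrix(px) || !is.numeric(px))
        msg <- c(msg, "'pixels' must be a numeric matrix")
    sp <- object@spacing
    if (length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0))
        msg <- c(msg, "'spacing' must be two positive finite values (x, y) in mm")
    if (length(object@sliceIndex) != 1L || is.na(object@sliceIndex) ||
        object@sliceIndex < 0L)
        msg <- c(msg, "'sliceIndex' must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
}

#' Virtual parent of single-slice CT images
#'
#' A rectangular pixel grid with physical pixel spacing.  Rows run along the
#' vertical (y) direction, columns along the horizontal (x) direction, as
#' stored in reconstructed axial CT slices.  Pixel index ranges are 1-based
#' and inclusive throughout the package.
#'
#' @slot pixels numeric matrix of pixel values.
#' @slot spacing numeric(2), pixel size in mm along x (columns) and y (rows).
#' @slot sliceIndex single non-negative integer identifying the axial slice.
#' @name CTSlice-class
#' @aliases CTSlice
#' @exportClass CTSlice
setClass("CTSlice",
    representation("VIRTUAL",
        pixels = "matrix",
        spacing = "numeric",
        sliceIndex = "integer"),
    prototype(spacing = c(1, 1), sliceIndex = 0L),
    validity = .validCTSlice)

#' CT image in Hounsfield units
#'
#' @slot pixels matrix of CT numbers H in HU; all values must be finite.
#' @seealso [HUImage()], [huToMu()]
#' @name HUImage-class
#' @aliases HUImage-class
#' @exportClass HUImage
setClass("HUImage", contains = "CTSlice",
    validity = function(object) {
        if (anyNA(object@pixels) || any(!is.finite(object@pixels))) {
            bad <- which(!is.finite(object@pixels), arr.ind = TRUE)[1L, ]
            sprintf("non-finite HU value at pixel (row %d, col %d)",
                bad[1L], bad[2L])
        } else TRUE
    })

#' Linear attenuation image relative to water
#'
#' Pixel values are the linear x-ray attenuation coefficient divided by that
#' of water (dimensionless), so water is 1 and vacuum 0.  Values may be
#' negative only when produced with clipping disabled (diagnostics).
#'
#' @slot pixels matrix of relative attenuation values; finite.
#' @seealso [huToMu()], [temA()]
#' @name AttenuationImage-class
#' @aliases AttenuationImage-class
#' @exportClass AttenuationImage
setClass("AttenuationImage", contains = "CTSlice",
    validity = function(object) {
        if (anyNA(object@pixels) || any(!is.finite(object@pixels))) {
            bad <- which(!is.finite(object@pixels), arr.ind = TRUE)[1L, ]
            sprintf("non-finite attenuation value at pixel (row %d, col %d)",
                bad[1L], bad[2L])
        } else TRUE
    })

#' Paired low/high tube-voltage CT slice
#'
#' Holds the 80 kVp ("low") and 140 kVp ("high") reconstructions of one
#' axial position; both grids must share shape, spacing and slice index.
#'
#' @slot low,high [HUImage-class] objects for the low/high tube voltage.
#' @name DualEnergyImage-class
#' @aliases DualEnergyImage-class
#' @exportClass DualEnergyImage
setClass("DualEnergyImage",
    representation(low = "HUImage", high = "HUImage"),
    validity = function(object) {
        msg <- NULL
        if (!identical(dim(object@low@pixels), dim(object@high@pixels)))
            msg <- c(msg, "low and high images must have identical shape")
        if (!isTRUE(all.equal(object@low@spacing, object@high@spacing)))
            msg <- c(msg, "low and high images must share pixel spacing")
        if (object@low@sliceIndex != object@high@sliceIndex)
            msg <- c(msg, "low and high images must share the slice index")
        if (is.null(msg)) TRUE else msg
    })

#' Stopping-power-ratio image
#'
#' Result of the voxel-wise RED/EAN/I-value/Bethe chain.  `provenance`
#' records the thickness-estimation method tag, the WET (mm) used for the
#' calibration lookup and the proton energy.
#'
#' @slot provenance named list of provenance fields.
#' @name SprImage-class
#' @aliases SprImage-class
#' @exportClass SprImage
setClass("SprImage", contains = "CTSlice",
    representation(provenance = "list"))

## ---- calibration ------------------------------------------------------------

#' Size-dependent calibration curve
#'
#' Per-TEM mapping from the slice WET (mm) to the dual-energy weighting
#' factors \eqn{\alpha_{RED}} and \eqn{\alpha_{EAN}}.  Evaluation is
#' piecewise linear between knots with constant (clamped) extrapolation.
#'
#' @slot method TEM tag ("tem-a", "tem-b1" or "tem-b2") that produced the
#'   WET axis.
#' @slot wet strictly increasing knot positions in mm (at least two).
#' @slot alphaRed,alphaEan weighting factors at the knots.
#' @seealso [buildCurve()], [lookupAlpha()]
#' @name CalibrationCurve-class
#' @aliases CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
    representation(method = "character", wet = "numeric",
        alphaRed = "numeric", alphaEan = "numeric"),
    validity = function(object) {
        msg <- NULL
        n <- length(object@wet)
        if (n < 2L)
            msg <- c(msg, "calibration curve needs at least two knots")
        if (n >= 2L && any(diff(object@wet) <= 0))
            msg <- c(msg, "knot WETs must be strictly increasing")
        if (length(object@alphaRed) != n || length(object@alphaEan) != n)
            msg <- c(msg, "alphaRed/alphaEan must match the number of knots")
        if (any(!is.finite(object@wet)) || any(object@wet < 0))
            msg <- c(msg, "knot WETs must be finite and non-negative")
        if (length(object@method) != 1L)
            msg <- c(msg, "'method' must be a single tag")
        if (is.null(msg)) TRUE else msg
    })

#' Bethe-equation settings
#'
#' Physical constants and the proton kinetic energy used for stopping-power
#' evaluation.  The relativistic \eqn{\beta^2} is derived from the kinetic
#' energy and proton rest energy.
#'
#' @slot energyMeV proton kinetic energy in MeV (default 100).
#' @slot electronRestMeV electron rest energy (0.511 MeV).
#' @slot protonRestMeV proton rest energy (938.272 MeV).
#' @slot waterIvalueEV mean excitation energy of water in eV (default 75).
#' @seealso [betheSettings()], [betheSpr()]
#' @name BetheSettings-class
#' @aliases BetheSettings-class
#' @exportClass BetheSettings
setClass("BetheSettings",
    representation(energyMeV = "numeric", electronRestMeV = "numeric",
        protonRestMeV = "numeric", waterIvalueEV = "numeric"),
    prototype(energyMeV = 100, electronRestMeV = 0.511,
        protonRestMeV = 938.272, waterIvalueEV = 75),
    validity = function(object) {
        msg <- NULL
        if (object@energyMeV <= 0) msg <- c(msg, "energyMeV must be > 0")
        if (object@waterIvalueEV <= 0)
            msg <- c(msg, "waterIvalueEV must be > 0")
        bsq <- 1 - (1 + object@energyMeV / object@protonRestMeV)^-2
        if (!(bsq > 0 && bsq < 1))
            msg <- c(msg, "derived beta^2 must lie in (0, 1)")
        if (is.null(msg)) TRUE else msg
    })

## ---- phantom description ----------------------------------------------------

#' Uniform (optionally rotated) ellipse
#'
#' Geometry is expressed in mm in a coordinate frame centred on the image
#' grid, x increasing with columns and y increasing downwards with rows.
#' A circle is the `semiA == semiB` special case.  `muLow` is the relative
#' attenuation at the low tube voltage (the value rasterized by default and
#' used for ground-truth WET); `muHigh` defaults to `muLow`.
#'
#' @slot centerX,centerY centre position (mm).
#' @slot semiA,semiB semi-axes (mm), positive.
#' @slot rotationDeg rotation of the `semiA` axis from horizontal (deg).
#' @slot muLow,muHigh relative attenuation at the two tube voltages.
#' @name EllipseShape-class
#' @aliases EllipseShape-class
#' @exportClass EllipseShape
setClass("EllipseShape",
    representation(centerX = "numeric", centerY = "numeric",
        semiA = "numeric", semiB = "numeric", rotationDeg = "numeric",
        muLow = "numeric", muHigh = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@semiA <= 0 || object@semiB <= 0)
            msg <- c(msg, "semi-axes must be positive")
        if (object@muLow < 0 || object@muHigh < 0)
            msg <- c(msg, "attenuation values must be non-negative")
        if (is.null(msg)) TRUE else msg
    })

#' Patient couch model
#'
#' Rectangular slab of uniform attenuation rendered below the lowest shape,
#' spanning `width` horizontally, separated from the object by `gap`.
#'
#' @slot width,thickness slab extent (mm), positive.
#' @slot mu relative attenuation of the slab.
#' @slot gap vertical air gap between object and couch surface (mm).
#' @name CouchSpec-class
#' @aliases CouchSpec-class
#' @exportClass CouchSpec
setClass("CouchSpec",
    representation(width = "numeric", thickness = "numeric",
        mu = "numeric", gap = "numeric"),
    validity = function(object) {
        if (object@width <= 0 || object@thickness <= 0 || object@mu <= 0 ||
            object@gap <= 0)
            "all couch parameters must be positive"
        else TRUE
    })

#' Tissue-surrogate insert
#'
#' A cylindrical (disk in-slice) tissue-equivalent insert with reference
#' electron density and effective atomic number and its nominal unbiased
#' dual-energy attenuation values.
#'
#' @slot name insert label.
#' @slot centerX,centerY disk centre (mm, grid-centred frame).
#' @slot radius disk radius (mm), positive.
#' @slot referenceRed reference relative electron density (> 0).
#' @slot referenceEan reference effective atomic number.
#' @slot muLow,muHigh nominal relative attenuation (no beam hardening).
#' @name SurrogateInsert-class
#' @aliases SurrogateInsert-class
#' @exportClass SurrogateInsert
setClass("SurrogateInsert",
    representation(name = "character", centerX = "numeric",
        centerY = "numeric", radius = "numeric", referenceRed = "numeric",
        referenceEan = "numeric", muLow = "numeric", muHigh = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@radius <= 0) msg <- c(msg, "radius must be positive")
        if (object@referenceRed <= 0)
            msg <- c(msg, "referenceRed must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' Parametric size-dependent CT-number bias
#'
#' Deterministic multiplicative bias emulating beam hardening: attenuation
#' at energy E is scaled by \eqn{1 + g_E (W - W_0)} and, for bone-class
#' materials (effective atomic number above `zSoft`), additionally by
#' \eqn{1 + b_E (W - W_0)}, where W is the object's ground-truth WET.  At
#' `W == w0` the bias is exactly zero.
#'
#' @slot w0 reference WET (mm).
#' @slot gLow,gHigh relative slope per mm at low/high tube voltage.
#' @slot bLow,bHigh extra bone slope per mm.
#' @slot zSoft soft-tissue EAN threshold above which the bone term applies.
#' @name HardeningModel-class
#' @aliases HardeningModel-class
#' @exportClass HardeningModel
setClass("HardeningModel",
    representation(w0 = "numeric", gLow = "numeric", gHigh = "numeric",
        bLow = "numeric", bHigh = "numeric", zSoft = "numeric"),
    validity = function(object) {
        if (object@w0 <= 0) "w0 must be positive" else TRUE
    })

setClassUnion("CouchSpecOrNULL", c("CouchSpec", "NULL"))
setClassUnion("HardeningModelOrNULL", c("HardeningModel", "NULL"))

#' Declarative phantom description
#'
#' All synthetic inputs are generated from a `PhantomSpec`: a pixel grid, a
#' stack of ellipse shapes (later shapes overwrite earlier ones where they
#' overlap — inhomogeneities), optional tissue-surrogate inserts, an
#' optional couch, Gaussian HU noise and an optional beam-hardening bias
#' model.  The random seed is part of the spec so every derived artifact is
#' reproducible.
#'
#' @slot nRow,nCol grid shape.
#' @slot spacing pixel size (mm) along x and y.
#' @slot shapes list of [EllipseShape-class]; the first is the primary
#'   object for ground-truth purposes.
#' @slot couch optional [CouchSpec-class].
#' @slot inserts list of [SurrogateInsert-class].
#' @slot noiseSigmaHu Gaussian HU noise standard deviation (>= 0).
#' @slot seed integer random seed recorded in all outputs.
#' @slot hardening optional [HardeningModel-class].
#' @slot supersample sub-pixel sampling factor per axis for rasterization.
#' @slot antialias if `TRUE`, boundary pixels get area-weighted
#'   (partial-volume) attenuation; if `FALSE` (default) coverage is
#'   majority-rounded so uniform objects stay piecewise-constant.
#' @name PhantomSpec-class
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(nRow = "integer", nCol = "integer", spacing = "numeric",
        shapes = "list", couch = "CouchSpecOrNULL", inserts = "list",
        noiseSigmaHu = "numeric", seed = "integer",
        hardening = "HardeningModelOrNULL", supersample = "integer",
        antialias = "logical"),
    prototype(spacing = c(1, 1), couch = NULL, inserts = list(),
        noiseSigmaHu = 0, seed = 1L, hardening = NULL, supersample = 4L,
        antialias = FALSE),
    validity = function(object) {
        msg <- NULL
        if (object@nRow < 1L || object@nCol < 1L)
            msg <- c(msg, "grid shape must be at least 1x1")
        if (length(object@spacing) != 2L || any(object@spacing <= 0))
            msg <- c(msg, "'spacing' must be two positive values (x, y)")
        if (!all(vapply(object@shapes, is, TRUE, "EllipseShape")))
            msg <- c(msg, "'shapes' must be a list of EllipseShape")
        if (!all(vapply(object@inserts, is, TRUE, "SurrogateInsert")))
            msg <- c(msg, "'inserts' must be a list of SurrogateInsert")
        if (object@noiseSigmaHu < 0)
            msg <- c(msg, "'noiseSigmaHu' must be >= 0")
        if (object@supersample < 1L)
            msg <- c(msg, "'supersample' must be >= 1")
        if (is.null(msg)) TRUE else msg
    })

## ---- WET estimates ----------------------------------------------------------

.TEM_METHODS <- c("tem-a", "tem-b1", "tem-b2")

#' Slice-wise WET profile of one thickness-estimation method
#'
#' One WET estimate (mm) per axial slice, all produced by the same method.
#' The scalar summary used for per-scan calibration lookup is the median.
#'
#' @slot method one of "tem-a", "tem-b1", "tem-b2".
#' @slot sliceIndex integer slice indices.
#' @slot wet WET estimates (mm), non-negative, one per slice.
#' @seealso [estimateProfile()], [maxPairwiseDeviation()]
#' @name WetProfile-class
#' @aliases WetProfile-class
#' @exportClass WetProfile
setClass("WetProfile",
    representation(method = "character", sliceIndex = "integer",
        wet = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@method) != 1L ||
            !object@method %in% .TEM_METHODS)
            msg <- c(msg, "'method' must be one of tem-a, tem-b1, tem-b2")
        if (length(object@wet) != length(object@sliceIndex))
            msg <- c(msg, "one WET estimate per slice required")
        if (length(object@wet) < 1L)
            msg <- c(msg, "profile must contain at least one slice")
        if (any(object@wet < 0))
            msg <- c(msg, "WET estimates must be non-negative")
        if (is.null(msg)) TRUE else msg
    })
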