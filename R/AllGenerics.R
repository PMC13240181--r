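## Accessor generics and show methods.

#' Pixel matrix of an image
#' @param object a [CTSlice-class] derivative.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "CTSlice", function(object) object@pixels)

#' Pixel spacing in mm
#'
#' `spacingX()`/`spacingY()` return the pixel size along columns (x) and
#' rows (y) respectively; `pixelSpacing()` returns both as a named vector.
#'
#' @param object a [CTSlice-class] derivative or [DualEnergyImage-class].
#' @return numeric.
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "CTSlice",
    function(object) c(x = object@spacing[1L], y = object@spacing[2L]))

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "DualEnergyImage",
    function(object) pixelSpacing(object@low))

#' @rdname pixelSpacing
#' @export
spacingX <- function(object) unname(pixelSpacing(object)["x"])

#' @rdname pixelSpacing
#' @export
spacingY <- function(object) unname(pixelSpacing(object)["y"])

#' Axial slice index
#' @param object a [CTSlice-class] derivative or [DualEnergyImage-class].
#' @return integer.
#' @export
setGeneric("sliceIndex", function(object) standardGeneric("sliceIndex"))

#' @rdname sliceIndex
#' @export
setMethod("sliceIndex", "CTSlice", function(object) object@sliceIndex)

#' @rdname sliceIndex
#' @export
setMethod("sliceIndex", "DualEnergyImage",
    function(object) object@low@sliceIndex)

#' Low/high tube-voltage components of a dual-energy image
#' @param object a [DualEnergyImage-class].
#' @return an [HUImage-class].
#' @export
setGeneric("lowEnergy", function(object) standardGeneric("lowEnergy"))

#' @rdname lowEnergy
#' @export
setMethod("lowEnergy", "DualEnergyImage", function(object) object@low)

#' @rdname lowEnergy
#' @export
setGeneric("highEnergy", function(object) standardGeneric("highEnergy"))

#' @rdname lowEnergy
#' @export
setMethod("highEnergy", "DualEnergyImage", function(object) object@high)

#' Crop an image to a pixel box
#'
#' Index ranges are 1-based and inclusive; the crop must be non-empty and
#' within bounds.  Cropping preserves spacing and slice index and commutes
#' with HU/attenuation conversion.
#'
#' @param object image to crop.
#' @param rows,cols integer(2) inclusive index ranges.
#' @return object of the same class.
#' @examples
#' img <- HUImage(matrix(0, 10, 10))
#' dim(pixels(cropImage(img, rows = c(1, 5), cols = c(1, 10))))
#' @export
setGeneric("cropImage",
    function(object, rows, cols) standardGeneric("cropImage"))

#' Method tag of a WET profile or calibration curve
#' @param object a [WetProfile-class] or [CalibrationCurve-class].
#' @return character tag.
#' @export
setGeneric("temMethod", function(object) standardGeneric("temMethod"))

#' @rdname temMethod
#' @export
setMethod("temMethod", "WetProfile", function(object) object@method)

#' @rdname temMethod
#' @export
setMethod("temMethod", "CalibrationCurve", function(object) object@method)

#' WET estimates of a profile
#' @param object a [WetProfile-class].
#' @return numeric vector (mm), named by slice index.
#' @export
setGeneric("wetValues", function(object) standardGeneric("wetValues"))

#' @rdname wetValues
#' @export
setMethod("wetValues", "WetProfile", function(object) {
    w <- object@wet
    names(w) <- object@sliceIndex
    w
})

#' Scalar WET summary (median over slices)
#' @param object a [WetProfile-class].
#' @return numeric (mm).
#' @export
setGeneric("wetSummary", function(object) standardGeneric("wetSummary"))

#' @rdname wetSummary
#' @export
setMethod("wetSummary", "WetProfile",
    function(object) stats::median(object@wet))

setMethod("show", "CTSlice", function(object) {
    cat(sprintf("%s: %d x %d pixels, spacing %.4g x %.4g mm, slice %d\n",
        class(object), nrow(object@pixels), ncol(object@pixels),
        object@spacing[1L], object@spacing[2L], object@sliceIndex))
    rng <- range(object@pixels)
    cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1L], rng[2L]))
})

setMethod("show", "DualEnergyImage", function(object) {
    cat(sprintf(
        "DualEnergyImage: %d x %d pixels, spacing %.4g x %.4g mm, slice %d\n",
        nrow(object@low@pixels), ncol(object@low@pixels),
        object@low@spacing[1L], object@low@spacing[2L],
        object@low@sliceIndex))
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve (%s): %d knots, WET %.4g..%.4g mm\n",
        object@method, length(object@wet), min(object@wet),
        max(object@wet)))
    cat(sprintf("  alphaRed %.6g..%.6g, alphaEan %.6g..%.6g\n",
        min(object@alphaRed), max(object@alphaRed),
        min(object@alphaEan), max(object@alphaEan)))
})

setMethod("show", "WetProfile", function(object) {
    cat(sprintf("WetProfile (%s): %d slice(s), median WET %.4g mm\n",
        object@method, length(object@wet), stats::median(object@wet)))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %d x %d grid @ %.4g x %.4g mm, %d shape(s), %d insert(s)%s%s\n",
        object@nRow, object@nCol, object@spacing[1L], object@spacing[2L],
        length(object@shapes), length(object@inserts),
        if (is.null(object@couch)) "" else ", couch",
        if (is.null(object@hardening)) "" else ", hardening bias"))
    cat(sprintf("  noise sigma %.4g HU, seed %d\n", object@noiseSigmaHu,
        object@seed))
})
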