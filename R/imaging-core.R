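## Image containers, HU <-> attenuation conversion, cropping and the
## plain-text matrix fixture format.

#' Construct a CT image in Hounsfield units
#'
#' @param pixels numeric matrix of CT numbers (HU).
#' @param spacing numeric(2), pixel size in mm along x (columns) and
#'   y (rows).  Default 1 mm isotropic.
#' @param sliceIndex non-negative integer slice identifier.
#' @return an [HUImage-class].
#' @examples
#' HUImage(matrix(0, 4, 4), spacing = c(1, 1))
#' @export
HUImage <- function(pixels, spacing = c(1, 1), sliceIndex = 0L) {
    .checkFinitePixels(pixels, "HU")
    new("HUImage", pixels = pixels, spacing = as.numeric(spacing),
        sliceIndex = as.integer(sliceIndex))
}

#' Construct a relative attenuation image
#'
#' @inheritParams HUImage
#' @param pixels numeric matrix of linear attenuation relative to water.
#' @return an [AttenuationImage-class].
#' @export
AttenuationImage <- function(pixels, spacing = c(1, 1), sliceIndex = 0L) {
    .checkFinitePixels(pixels, "attenuation")
    new("AttenuationImage", pixels = pixels, spacing = as.numeric(spacing),
        sliceIndex = as.integer(sliceIndex))
}

#' Construct a dual-energy CT slice
#'
#' @param low,high [HUImage-class] objects for the 80 and 140 kVp roles;
#'   must share shape, spacing and slice index.
#' @return a [DualEnergyImage-class].
#' @export
DualEnergyImage <- function(low, high) new("DualEnergyImage",
    low = low, high = high)

.checkFinitePixels <- function(pixels, what) {
    if (!is.matrix(pixels) || !is.numeric(pixels))
        stop("'pixels' must be a numeric matrix", call. = FALSE)
    if (anyNA(pixels) || any(!is.finite(pixels))) {
        bad <- which(!is.finite(pixels), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-finite %s value at pixel (row %d, col %d)",
            what, bad[1L], bad[2L]), call. = FALSE)
    }
    invisible(TRUE)
}

#' Convert CT numbers to relative attenuation
#'
#' Applies \eqn{\mu = H/1000 + 1}, the inverse of the HU definition
#' \eqn{H = (\mu - 1) \cdot 1000}.  By default negative attenuation values
#' (HU below -1000, possible in noisy reconstructions) are clipped to zero,
#' since the attenuation-weighted extents entering WET estimation are
#' physically non-negative; set `clipNegative = FALSE` for diagnostics.
#'
#' @param image an [HUImage-class].
#' @param clipNegative clip \eqn{\mu < 0} to 0 (default `TRUE`).
#' @return an [AttenuationImage-class] with spacing and slice index
#'   preserved.
#' @examples
#' img <- HUImage(matrix(c(0, -1000, 1000, 50), 2, 2))
#' pixels(huToMu(img))      # water = 1, air = 0
#' @seealso [muToHu()]
#' @export
huToMu <- function(image, clipNegative = TRUE) {
    stopifnot(is(image, "HUImage"))
    mu <- image@pixels / 1000 + 1
    if (clipNegative)
        mu[mu < 0] <- 0
    new("AttenuationImage", pixels = mu, spacing = image@spacing,
        sliceIndex = image@sliceIndex)
}

#' Convert relative attenuation to CT numbers
#'
#' Applies \eqn{H = (\mu - 1) \cdot 1000}; exact round trip with
#' [huToMu()] (clipping off) to machine precision.
#'
#' @param image an [AttenuationImage-class].
#' @return an [HUImage-class].
#' @export
muToHu <- function(image) {
    stopifnot(is(image, "AttenuationImage"))
    new("HUImage", pixels = (image@pixels - 1) * 1000,
        spacing = image@spacing, sliceIndex = image@sliceIndex)
}

.cropPixels <- function(px, rows, cols) {
    if (length(rows) != 2L || length(cols) != 2L)
        stop("'rows' and 'cols' must each be two indices", call. = FALSE)
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (rows[1L] > rows[2L] || cols[1L] > cols[2L])
        stop("empty crop box", call. = FALSE)
    if (rows[1L] < 1L || rows[2L] > nrow(px) ||
        cols[1L] < 1L || cols[2L] > ncol(px))
        stop("crop box out of image bounds", call. = FALSE)
    px[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
}

#' @rdname cropImage
#' @export
setMethod("cropImage", "CTSlice", function(object, rows, cols) {
    initialize(object,
        pixels = .cropPixels(object@pixels, rows, cols))
})

#' @rdname cropImage
#' @export
setMethod("cropImage", "DualEnergyImage", function(object, rows, cols) {
    new("DualEnergyImage",
        low = cropImage(object@low, rows, cols),
        high = cropImage(object@high, rows, cols))
})

## ---- matrix fixture format --------------------------------------------------

#' Plain-text matrix fixture I/O
#'
#' A dependency-free single-slice image format used for fixtures and SPR
#' map output: comment-prefixed header lines (`# key: value`) carrying
#' `spacing_x`, `spacing_y` and `slice_index`, followed by the pixel matrix
#' as whitespace-separated rows.  Values are written with 17 significant
#' digits so a write/read round trip is lossless.
#'
#' @param path file path.
#' @param image image to write; an [HUImage-class] or
#'   [AttenuationImage-class].
#' @param type class of image to construct on read: `"hu"` or `"mu"`.
#' @param extraHeader optional named character vector of additional header
#'   fields (provenance).
#' @return `readMatrixFixture()` returns the image;
#'   `writeMatrixFixture()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeMatrixFixture(HUImage(matrix(1:6 / 7, 2, 3)), p)
#' readMatrixFixture(p)
#' @export
writeMatrixFixture <- function(image, path, extraHeader = NULL) {
    stopifnot(is(image, "CTSlice"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("# spacing_x: %.17g", image@spacing[1L]),
        sprintf("# spacing_y: %.17g", image@spacing[2L]),
        sprintf("# slice_index: %d", image@sliceIndex),
        if (length(extraHeader))
            sprintf("# %s: %s", names(extraHeader), extraHeader)), con)
    writeLines(apply(image@pixels, 1L,
        function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    invisible(path)
}

#' @rdname writeMatrixFixture
#' @export
readMatrixFixture <- function(path, type = c("hu", "mu")) {
    type <- match.arg(type)
    lines <- readLines(path)
    isHeader <- startsWith(lines, "#")
    header <- lines[isHeader]
    body <- lines[!isHeader & nzchar(trimws(lines))]
    getField <- function(key) {
        hit <- grep(sprintf("^#\\s*%s\\s*:", key), header, value = TRUE)
        if (length(hit) != 1L)
            stop(sprintf("fixture header missing field '%s' in %s",
                key, path), call. = FALSE)
        trimws(sub("^#[^:]*:", "", hit[1L]))
    }
    sx <- as.numeric(getField("spacing_x"))
    sy <- as.numeric(getField("spacing_y"))
    si <- as.integer(getField("slice_index"))
    if (is.na(sx) || is.na(sy) || is.na(si))
        stop("malformed fixture header in ", path, call. = FALSE)
    if (!length(body))
        stop("fixture contains no matrix body: ", path, call. = FALSE)
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    nc <- unique(lengths(rows))
    if (length(nc) != 1L)
        stop("ragged matrix rows in fixture ", path, call. = FALSE)
    px <- do.call(rbind, rows)
    if (type == "hu")
        HUImage(px, spacing = c(sx, sy), sliceIndex = si)
    else
        AttenuationImage(px, spacing = c(sx, sy), sliceIndex = si)
}
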