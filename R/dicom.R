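## Minimal single-frame CT DICOM I/O (Explicit VR Little Endian only).
## Covers exactly the subset needed for HU image exchange: pixel matrix,
## pixel spacing, rescale slope/intercept and slice ordering.  Not a
## general DICOM implementation.

.DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
    endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
    endian = "little")

.dcmElement <- function(group, elem, vr, value) {
    if (is.character(value)) {
        value <- charToRaw(value)
        if (length(value) %% 2L == 1L)
            value <- c(value, if (vr == "UI") as.raw(0L)
                else charToRaw(" "))
    }
    len <- length(value)
    c(.u16le(group), .u16le(elem), charToRaw(vr),
        if (vr %in% .VR_LONG) c(as.raw(c(0, 0)), .u32le(len))
        else .u16le(len),
        value)
}

#' Write a synthetic single-frame CT DICOM series
#'
#' Writes one Explicit-VR-little-endian DICOM file per slice with signed
#' 16-bit stored values, rescale metadata and pixel spacing.  Intended for
#' producing test inputs for [readDicomSeries()]; it is not a clinically
#' complete DICOM writer.
#'
#' @param images list of [HUImage-class] slices (shared shape/spacing).
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale transform: stored value
#'   `v = (H - intercept)/slope` (must be integral in `[-32768, 32767]`).
#' @param sliceSpacing axial distance between consecutive slices (mm),
#'   used for the slice-location tag.
#' @return character vector of file paths, invisibly.
#' @export
writeDicomSeries <- function(images, dir, slope = 1, intercept = -1024,
                             sliceSpacing = 2.5) {
    if (is(images, "HUImage"))
        images <- list(images)
    stopifnot(length(images) >= 1L,
        all(vapply(images, is, TRUE, "HUImage")))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- character(length(images))
    for (i in seq_along(images)) {
        img <- images[[i]]
        stored <- round((img@pixels - intercept) / slope)
        if (any(stored < -32768 | stored > 32767))
            stop("stored values exceed the signed 16-bit range",
                call. = FALSE)
        ## DICOM pixel data is row-major
        pxRaw <- writeBin(as.integer(t(stored)), raw(), size = 2L,
            endian = "little")
        uid <- sprintf("1.2.826.0.1.3680043.9999.%d.%d",
            i, nrow(img@pixels) * ncol(img@pixels))
        meta <- c(
            .dcmElement(0x0002, 0x0010, "UI", .DICOM_TS_EXPLICIT_LE))
        body <- c(
            .dcmElement(0x0008, 0x0016, "UI",
                "1.2.840.10008.5.1.4.1.1.2"),
            .dcmElement(0x0008, 0x0018, "UI", uid),
            .dcmElement(0x0008, 0x0060, "CS", "CT"),
            .dcmElement(0x0020, 0x0013, "IS", as.character(i)),
            .dcmElement(0x0020, 0x1041, "DS",
                sprintf("%.6f", (i - 1L) * sliceSpacing)),
            .dcmElement(0x0028, 0x0002, "US", .u16le(1L)),
            .dcmElement(0x0028, 0x0010, "US", .u16le(nrow(img@pixels))),
            .dcmElement(0x0028, 0x0011, "US", .u16le(ncol(img@pixels))),
            ## PixelSpacing is row spacing (y) then column spacing (x)
            .dcmElement(0x0028, 0x0030, "DS",
                sprintf("%.10g\\%.10g", img@spacing[2L],
                    img@spacing[1L])),
            .dcmElement(0x0028, 0x0100, "US", .u16le(16L)),
            .dcmElement(0x0028, 0x0101, "US", .u16le(16L)),
            .dcmElement(0x0028, 0x0102, "US", .u16le(15L)),
            .dcmElement(0x0028, 0x0103, "US", .u16le(1L)),
            .dcmElement(0x0028, 0x1052, "DS", sprintf("%.10g", intercept)),
            .dcmElement(0x0028, 0x1053, "DS", sprintf("%.10g", slope)),
            .dcmElement(0x7FE0, 0x0010, "OW", pxRaw))
        paths[i] <- file.path(dir, sprintf("slice_%03d.dcm", i))
        con <- file(paths[i], "wb")
        writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
        close(con)
    }
    invisible(paths)
}

.parseDicomFile <- function(path) {
    bytes <- readBin(path, "raw", n = file.info(path)$size)
    if (length(bytes) < 140L ||
        rawToChar(bytes[129:132]) != "DICM")
        stop("not a DICOM (part-10) file: ", path, call. = FALSE)
    pos <- 133L
    tags <- list()
    n <- length(bytes)
    rd16 <- function(at) readBin(bytes[at:(at + 1L)], "integer",
        size = 2L, signed = FALSE, endian = "little")
    while (pos + 7L <= n) {
        group <- rd16(pos); elem <- rd16(pos + 2L)
        vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
        if (!grepl("^[A-Z]{2}$", vr))
            stop("unsupported (implicit VR?) DICOM encoding in ", path,
                call. = FALSE)
        if (vr %in% .VR_LONG) {
            len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer",
                size = 4L, endian = "little")
            valAt <- pos + 12L
        } else {
            len <- rd16(pos + 6L)
            valAt <- pos + 8L
        }
        if (len < 0L || valAt + len - 1L > n)
            stop("truncated DICOM element in ", path, call. = FALSE)
        key <- sprintf("%04X%04X", group, elem)
        tags[[key]] <- list(vr = vr,
            value = if (len > 0L) bytes[valAt:(valAt + len - 1L)]
                else raw(0L))
        pos <- valAt + len
    }
    tags
}

.dcmString <- function(tags, key) {
    if (is.null(tags[[key]])) return(NULL)
    v <- tags[[key]]$value
    trimws(rawToChar(v[v != as.raw(0L)]))
}

.dcmUS <- function(tags, key) {
    if (is.null(tags[[key]])) return(NULL)
    readBin(tags[[key]]$value, "integer", size = 2L, signed = FALSE,
        endian = "little")
}

#' Read a directory of single-frame CT DICOM files
#'
#' Reads every `*.dcm` file in `path` (Explicit VR Little Endian), rescales
#' stored values to HU with the rescale slope/intercept metadata, orders
#' slices by axial position (slice location) and returns them as a list of
#' [HUImage-class] objects with 0-based slice indices in axial order.
#'
#' @param path directory containing the series.
#' @return list of [HUImage-class], ordered by axial position.
#' @seealso [writeDicomSeries()]
#' @export
readDicomSeries <- function(path) {
    files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
        full.names = TRUE)
    if (!length(files))
        stop("no DICOM files found in ", path, call. = FALSE)
    slices <- lapply(files, function(f) {
        tags <- .parseDicomFile(f)
        ts <- .dcmString(tags, "00020010")
        if (!is.null(ts) && ts != .DICOM_TS_EXPLICIT_LE)
            stop("unsupported transfer syntax ", ts, " in ", f,
                call. = FALSE)
        nr <- .dcmUS(tags, "00280010"); nc <- .dcmUS(tags, "00280011")
        if (is.null(nr) || is.null(nc))
            stop("missing Rows/Columns in ", f, call. = FALSE)
        spacingStr <- .dcmString(tags, "00280030")
        if (is.null(spacingStr))
            stop("missing PixelSpacing in ", f, call. = FALSE)
        sp <- as.numeric(strsplit(spacingStr, "\\\\")[[1L]])
        if (length(sp) != 2L || anyNA(sp))
            stop("malformed PixelSpacing in ", f, call. = FALSE)
        slope <- .dcmString(tags, "00281053")
        intercept <- .dcmString(tags, "00281052")
        if (is.null(slope) || is.null(intercept))
            stop("missing rescale slope/intercept metadata in ", f,
                call. = FALSE)
        signed <- .dcmUS(tags, "00280103")
        if (is.null(tags[["7FE00010"]]))
            stop("missing pixel data in ", f, call. = FALSE)
        stored <- readBin(tags[["7FE00010"]]$value, "integer", size = 2L,
            signed = !identical(signed, 0L), endian = "little",
            n = nr * nc)
        if (length(stored) != nr * nc)
            stop("pixel data length mismatch in ", f, call. = FALSE)
        hu <- matrix(stored, nrow = nr, ncol = nc, byrow = TRUE) *
            as.numeric(slope) + as.numeric(intercept)
        loc <- .dcmString(tags, "00201041")
        inst <- .dcmString(tags, "00200013")
        list(hu = hu, spacing = c(x = sp[2L], y = sp[1L]),
            z = if (!is.null(loc)) as.numeric(loc)
                else if (!is.null(inst)) as.numeric(inst) else NA_real_)
    })
    shapes <- vapply(slices, function(s) paste(dim(s$hu),
        collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
        stop("inconsistent image shape across the series", call. = FALSE)
    spacings <- vapply(slices, function(s)
        paste(format(s$spacing, digits = 12), collapse = ","), "")
    if (length(unique(spacings)) != 1L)
        stop("inconsistent pixel spacing across the series", call. = FALSE)
    ord <- order(vapply(slices, function(s) s$z, 0),
        na.last = TRUE)
    lapply(seq_along(ord), function(i) {
        s <- slices[[ord[i]]]
        HUImage(s$hu, spacing = unname(s$spacing), sliceIndex = i - 1L)
    })
}
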