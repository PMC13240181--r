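## Synthetic phantom generation: generic geometries (uniform/rotated
## ellipses with inhomogeneities), cylindrical insert phantoms with an
## optional patient couch, dual-energy CT simulation with a parametric
## size-dependent CT-number bias, and analytic ground-truth WET oracles.

#' Shape, couch, insert and hardening-model constructors
#'
#' @param centerX,centerY centre (mm) in the grid-centred frame
#'   (x → columns, y → rows, y increasing downward).
#' @param semiA,semiB ellipse semi-axes (mm).
#' @param rotationDeg rotation of the `semiA` axis from horizontal.
#' @param muLow,muHigh relative attenuation at low/high tube voltage
#'   (`muHigh` defaults to `muLow`).
#' @return the corresponding S4 object.
#' @examples
#' ellipseShape(semiA = 100, semiB = 50, rotationDeg = 45)
#' @export
ellipseShape <- function(centerX = 0, centerY = 0, semiA, semiB = semiA,
                         rotationDeg = 0, muLow = 1, muHigh = muLow) {
    new("EllipseShape", centerX = centerX, centerY = centerY,
        semiA = semiA, semiB = semiB, rotationDeg = rotationDeg,
        muLow = muLow, muHigh = muHigh)
}

#' @rdname ellipseShape
#' @param width,thickness,gap couch slab geometry (mm).
#' @param mu couch relative attenuation.
#' @export
couchSpec <- function(width = 500, thickness = 20, mu = 0.3, gap = 5) {
    new("CouchSpec", width = width, thickness = thickness, mu = mu,
        gap = gap)
}

#' @rdname ellipseShape
#' @param name insert label.
#' @param radius insert disk radius (mm).
#' @param referenceRed,referenceEan reference relative electron density
#'   and effective atomic number of the surrogate.
#' @export
surrogateInsert <- function(name, centerX, centerY, radius, referenceRed,
                            referenceEan, muLow, muHigh) {
    new("SurrogateInsert", name = name, centerX = centerX,
        centerY = centerY, radius = radius, referenceRed = referenceRed,
        referenceEan = referenceEan, muLow = muLow, muHigh = muHigh)
}

#' @rdname ellipseShape
#' @param w0 reference WET (mm) at which the CT-number bias vanishes.
#' @param gLow,gHigh relative bias slope per mm of WET.
#' @param bLow,bHigh additional bone-class slope per mm.
#' @param zSoft EAN threshold above which the bone term applies.
#' @export
hardeningModel <- function(w0 = 200, gLow = -5e-5, gHigh = -2e-5,
                           bLow = -8e-5, bHigh = -3e-5, zSoft = 8.8) {
    new("HardeningModel", w0 = w0, gLow = gLow, gHigh = gHigh,
        bLow = bLow, bHigh = bHigh, zSoft = zSoft)
}

#' @rdname ellipseShape
#' @export
defaultHardeningModel <- function() hardeningModel()

#' Construct a phantom specification
#'
#' @param nRow,nCol grid shape (pixels).
#' @param spacing pixel size (mm) along x and y.
#' @param shapes list of [EllipseShape-class]; later shapes overwrite
#'   earlier ones where they overlap.
#' @param couch optional [CouchSpec-class].
#' @param inserts list of [SurrogateInsert-class].
#' @param noiseSigmaHu Gaussian HU noise standard deviation.
#' @param seed integer seed recorded with all stochastic outputs.
#' @param hardening optional [HardeningModel-class].
#' @param supersample sub-pixel sampling factor per axis (default 4).
#' @param antialias boundary handling: `FALSE` (default) rounds the
#'   supersampled coverage to 0/1 so uniform objects rasterize
#'   piecewise-constant (the idealized-geometry convention; required for
#'   the squared-attenuation method to see sharp boundaries); `TRUE`
#'   assigns area-weighted partial-volume values at shape edges.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nRow, nCol, spacing = c(1, 1), shapes = list(),
                        couch = NULL, inserts = list(), noiseSigmaHu = 0,
                        seed = 1L, hardening = NULL, supersample = 4L,
                        antialias = FALSE) {
    if (length(spacing) == 1L) spacing <- c(spacing, spacing)
    new("PhantomSpec", nRow = as.integer(nRow), nCol = as.integer(nCol),
        spacing = as.numeric(spacing), shapes = shapes, couch = couch,
        inserts = inserts, noiseSigmaHu = noiseSigmaHu,
        seed = as.integer(seed), hardening = hardening,
        supersample = as.integer(supersample),
        antialias = isTRUE(antialias))
}

## ---- internal geometry ------------------------------------------------------

.shapeBounds <- function(e) {
    if (is(e, "EllipseShape")) {
        phi <- e@rotationDeg * pi / 180
        hx <- sqrt((e@semiA * cos(phi))^2 + (e@semiB * sin(phi))^2)
        hy <- sqrt((e@semiA * sin(phi))^2 + (e@semiB * cos(phi))^2)
        list(xmin = e@centerX - hx, xmax = e@centerX + hx,
            ymin = e@centerY - hy, ymax = e@centerY + hy)
    } else {
        stop("unknown shape class")
    }
}

## flat entry list used by the rasterizer: ellipse or axis-aligned rect
.entryEllipse <- function(cx, cy, a, b, phiDeg, mu)
    list(kind = "ellipse", cx = cx, cy = cy, a = a, b = b,
        phi = phiDeg * pi / 180, mu = mu,
        bounds = .shapeBounds(ellipseShape(cx, cy, a, b, phiDeg, 0)))

.entryRect <- function(x0, x1, y0, y1, mu)
    list(kind = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1, mu = mu,
        bounds = list(xmin = x0, xmax = x1, ymin = y0, ymax = y1))

.entryInside <- function(e, x, y) {
    if (e$kind == "ellipse") {
        dx <- x - e$cx; dy <- y - e$cy
        u <- dx * cos(e$phi) + dy * sin(e$phi)
        v <- -dx * sin(e$phi) + dy * cos(e$phi)
        (u / e$a)^2 + (v / e$b)^2 <= 1
    } else {
        x >= e$x0 & x <= e$x1 & y >= e$y0 & y <= e$y1
    }
}

## lowest y extent of all object shapes and inserts (for couch placement)
.objectBottom <- function(spec) {
    ys <- vapply(spec@shapes, function(s) .shapeBounds(s)$ymax, 0)
    if (length(spec@inserts))
        ys <- c(ys, vapply(spec@inserts,
            function(s) s@centerY + s@radius, 0))
    if (!length(ys))
        stop("couch placement needs at least one shape", call. = FALSE)
    max(ys)
}

.specEntries <- function(spec, energy = c("low", "high"),
                         biasFun = NULL) {
    energy <- match.arg(energy)
    muOf <- function(muLow, muHigh, ean) {
        mu <- if (energy == "low") muLow else muHigh
        if (is.null(biasFun)) mu else mu * biasFun(energy, ean)
    }
    entries <- lapply(spec@shapes, function(s)
        .entryEllipse(s@centerX, s@centerY, s@semiA, s@semiB,
            s@rotationDeg, muOf(s@muLow, s@muHigh, NA_real_)))
    entries <- c(entries, lapply(spec@inserts, function(s)
        .entryEllipse(s@centerX, s@centerY, s@radius, s@radius, 0,
            muOf(s@muLow, s@muHigh, s@referenceEan))))
    if (!is.null(spec@couch)) {
        top <- .objectBottom(spec) + spec@couch@gap
        entries <- c(entries, list(.entryRect(
            -spec@couch@width / 2, spec@couch@width / 2,
            top, top + spec@couch@thickness,
            muOf(spec@couch@mu, spec@couch@mu, NA_real_))))
    }
    entries
}

.rasterEntries <- function(entries, nRow, nCol, sx, sy, ss,
                           antialias = FALSE) {
    px <- matrix(0, nRow, nCol)
    halfW <- nCol * sx / 2
    halfH <- nRow * sy / 2
    offs <- (seq_len(ss) - 0.5) / ss - 0.5   # sub-pixel offsets, pixel units
    for (e in entries) {
        b <- e$bounds
        if (b$xmin < -halfW - 1e-9 || b$xmax > halfW + 1e-9 ||
            b$ymin < -halfH - 1e-9 || b$ymax > halfH + 1e-9)
            stop("shape exceeds the image grid", call. = FALSE)
        jlo <- max(1L, as.integer(floor((b$xmin + halfW) / sx)) + 1L)
        jhi <- min(nCol, as.integer(ceiling((b$xmax + halfW) / sx)))
        ilo <- max(1L, as.integer(floor((b$ymin + halfH) / sy)) + 1L)
        ihi <- min(nRow, as.integer(ceiling((b$ymax + halfH) / sy)))
        if (jlo > jhi || ilo > ihi) next
        jr <- jlo:jhi
        ir <- ilo:ihi
        xsub <- (rep(jr - 0.5, each = ss) +
            rep(offs, times = length(jr))) * sx - halfW
        ysub <- (rep(ir - 0.5, each = ss) +
            rep(offs, times = length(ir))) * sy - halfH
        inside <- outer(ysub, xsub, function(y, x) .entryInside(e, x, y))
        cov <- rowsum(inside + 0, rep(seq_along(ir), each = ss),
            reorder = FALSE)
        cov <- t(rowsum(t(cov), rep(seq_along(jr), each = ss),
            reorder = FALSE)) / ss^2
        if (!antialias)
            cov <- (cov >= 0.5) + 0    # majority vote per pixel
        px[ir, jr] <- cov * e$mu + (1 - cov) * px[ir, jr]
    }
    px
}

## ---- rasterization and ground truth -----------------------------------------

#' Rasterize a phantom specification into an attenuation image
#'
#' Pixel coverage is evaluated by supersampling (default 4x4 sub-pixels)
#' of the shape stack; inserts are rendered after the body shapes and the
#' couch last.  By default coverage is majority-rounded so that uniform
#' shapes rasterize piecewise-constant, matching the idealized-geometry
#' convention under which the analytic WET oracles hold for all three
#' estimation methods; with `antialias = TRUE` in the spec, boundary
#' pixels receive area-weighted partial-volume values instead.
#' Deterministic for a fixed spec.
#'
#' @param spec a [PhantomSpec-class].
#' @param energy which nominal attenuation to rasterize (`"low"` is the
#'   80 kVp role used for WET estimation).
#' @return an [AttenuationImage-class].
#' @examples
#' spec <- phantomSpec(64, 64, shapes = list(ellipseShape(semiA = 20)))
#' rasterize(spec)
#' @export
rasterize <- function(spec, energy = c("low", "high")) {
    energy <- match.arg(energy)
    stopifnot(is(spec, "PhantomSpec"))
    px <- .rasterEntries(.specEntries(spec, energy), spec@nRow, spec@nCol,
        spec@spacing[1L], spec@spacing[2L], spec@supersample,
        spec@antialias)
    AttenuationImage(px, spacing = spec@spacing, sliceIndex = 0L)
}

#' Analytic ground-truth WET of a phantom
#'
#' For a single primary ellipse (optionally containing fully enclosed
#' inhomogeneity shapes) the ground truth is the effective diameter
#' \eqn{2\sqrt{ab}} — the geometric mean of the major and minor axes —
#' multiplied by the object's area-weighted mean relative attenuation.
#' For a uniform cylinder of diameter D and material attenuation
#' \eqn{\mu_m} this reduces to \eqn{D\,\mu_m}.  Surrogate inserts are not
#' part of the ground-truth object (phantom ground truth is defined from
#' the body material alone).
#'
#' @param spec a [PhantomSpec-class] whose first shape is the primary
#'   object; any further shapes must lie fully inside it.
#' @return ground-truth WET in mm.
#' @examples
#' spec <- phantomSpec(256, 256,
#'     shapes = list(ellipseShape(semiA = 100, semiB = 50)))
#' groundTruthWet(spec)   # 2 * sqrt(100 * 50)
#' @export
groundTruthWet <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    if (!length(spec@shapes))
        stop("ground truth requires at least one shape", call. = FALSE)
    prim <- spec@shapes[[1L]]
    areaPrim <- pi * prim@semiA * prim@semiB
    muSum <- prim@muLow * areaPrim
    if (length(spec@shapes) > 1L) {
        for (s in spec@shapes[-1L]) {
            if (!.insidePrimary(s, prim))
                stop(paste("ground truth is defined for a single primary",
                    "ellipse with fully enclosed inhomogeneities"),
                    call. = FALSE)
            areaS <- pi * s@semiA * s@semiB
            muSum <- muSum + (s@muLow - prim@muLow) * areaS
        }
    }
    2 * sqrt(prim@semiA * prim@semiB) * (muSum / areaPrim)
}

## boundary-sampling containment check of shape s in primary ellipse
.insidePrimary <- function(s, prim) {
    th <- seq(0, 2 * pi, length.out = 73L)[-73L]
    phi <- s@rotationDeg * pi / 180
    bx <- s@centerX + s@semiA * cos(th) * cos(phi) -
        s@semiB * sin(th) * sin(phi)
    by <- s@centerY + s@semiA * cos(th) * sin(phi) +
        s@semiB * sin(th) * cos(phi)
    phip <- prim@rotationDeg * pi / 180
    dx <- bx - prim@centerX; dy <- by - prim@centerY
    u <- dx * cos(phip) + dy * sin(phip)
    v <- -dx * sin(phip) + dy * cos(phip)
    all((u / prim@semiA)^2 + (v / prim@semiB)^2 <= 1 + 1e-9)
}

## ---- dual-energy simulation -------------------------------------------------

#' Multiplicative CT-number bias factors of the hardening model
#'
#' @param model a [HardeningModel-class].
#' @param wet object ground-truth WET (mm).
#' @param ean material effective atomic number (`NA` for non-tissue
#'   materials, treated as soft).
#' @return named numeric `c(low =, high =)` bias factors.
#' @export
hardeningBias <- function(model, wet, ean = NA_real_) {
    dw <- wet - model@w0
    f <- c(low = 1 + model@gLow * dw, high = 1 + model@gHigh * dw)
    if (!is.na(ean) && ean > model@zSoft)
        f <- f * c(1 + model@bLow * dw, 1 + model@bHigh * dw)
    f
}

## run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
    hadSeed <- exists(".Random.seed", envir = globalenv(),
        inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Simulate a dual-energy CT acquisition of a phantom
#'
#' Each material's nominal low/high attenuation is scaled by the
#' size-dependent bias of the spec's [HardeningModel-class] evaluated at
#' the phantom's ground-truth WET (with the extra bone term for inserts
#' whose EAN exceeds the model's soft-tissue threshold), rasterized,
#' converted to CT numbers and degraded with seeded Gaussian HU noise.
#' ROI statistics are extracted per insert over the insert disk eroded by
#' one pixel.
#'
#' @param spec a [PhantomSpec-class] with a non-`NULL` hardening model
#'   (use zero slopes for an unbiased acquisition).
#' @return list with elements `image` ([DualEnergyImage-class]),
#'   `measurements` (data frame: insert, H_low, H_high, reference_red,
#'   reference_ean, wet_mm), `wetTrue` (mm) and `seed`.
#' @export
simulateDect <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    if (is.null(spec@hardening))
        stop(paste("simulateDect requires a hardening model;",
            "use hardeningModel(gLow = 0, gHigh = 0, bLow = 0, bHigh = 0)",
            "for an unbiased acquisition"), call. = FALSE)
    wet <- groundTruthWet(spec)
    biasFun <- function(energy, ean)
        unname(hardeningBias(spec@hardening, wet, ean)[energy])
    raster <- function(energy) .rasterEntries(
        .specEntries(spec, energy, biasFun), spec@nRow, spec@nCol,
        spec@spacing[1L], spec@spacing[2L], spec@supersample,
        spec@antialias)
    huLow <- (raster("low") - 1) * 1000
    huHigh <- (raster("high") - 1) * 1000
    noise <- .withSeed(spec@seed, list(
        low = matrix(stats::rnorm(length(huLow), 0, spec@noiseSigmaHu),
            nrow(huLow)),
        high = matrix(stats::rnorm(length(huHigh), 0, spec@noiseSigmaHu),
            nrow(huHigh))))
    huLow <- huLow + noise$low
    huHigh <- huHigh + noise$high
    de <- DualEnergyImage(
        HUImage(huLow, spacing = spec@spacing),
        HUImage(huHigh, spacing = spec@spacing))
    measurements <- .insertRoiMeans(spec, huLow, huHigh, wet)
    list(image = de, measurements = measurements, wetTrue = wet,
        seed = spec@seed)
}

.insertRoiMeans <- function(spec, huLow, huHigh, wet) {
    if (!length(spec@inserts))
        return(data.frame(insert = character(), H_low = numeric(),
            H_high = numeric(), reference_red = numeric(),
            reference_ean = numeric(), wet_mm = numeric()))
    sx <- spec@spacing[1L]; sy <- spec@spacing[2L]
    xc <- (seq_len(spec@nCol) - 0.5) * sx - spec@nCol * sx / 2
    yc <- (seq_len(spec@nRow) - 0.5) * sy - spec@nRow * sy / 2
    rows <- lapply(spec@inserts, function(ins) {
        rEff <- ins@radius - max(sx, sy)   # erode by one pixel
        d2 <- outer(yc - ins@centerY, xc - ins@centerX,
            function(y, x) x^2 + y^2)
        roi <- d2 <= rEff^2
        if (!any(roi))
            stop(sprintf("insert '%s' too small for an eroded ROI",
                ins@name), call. = FALSE)
        data.frame(insert = ins@name, H_low = mean(huLow[roi]),
            H_high = mean(huHigh[roi]), reference_red = ins@referenceRed,
            reference_ean = ins@referenceEan, wet_mm = wet)
    })
    do.call(rbind, rows)
}

## ---- surrogate catalogue ----------------------------------------------------

#' Nominal dual-energy attenuation of a tissue from RED and EAN
#'
#' Two-term forward model used for the packaged synthetic surrogates:
#' \deqn{\mu_E = \rho_e \left(c_{0,E} + c_{1,E} (Z/Z_w)^n\right),
#'   \quad c_{0,E} = 1 - c_{1,E},}
#' a photoelectric-like Z-dependent term on top of a Compton-like
#' electron-density term, normalised so water (\eqn{\rho_e = 1},
#' \eqn{Z = Z_w}) has \eqn{\mu = 1} at both energies.  The low-energy
#' channel is more Z-sensitive (`c1Low > c1High`).
#'
#' @param red relative electron density.
#' @param ean effective atomic number.
#' @param c1Low,c1High Z-term weights at low/high tube voltage.
#' @param n EAN exponent convention (3.1).
#' @param zw effective atomic number of water under that convention.
#' @return data frame with columns `muLow`, `muHigh` (vectorized).
#' @export
dectNominalMu <- function(red, ean, c1Low = 0.12, c1High = 0.04,
                          n = 3.1, zw = 7.45) {
    t <- (ean / zw)^n
    data.frame(muLow = red * ((1 - c1Low) + c1Low * t),
        muHigh = red * ((1 - c1High) + c1High * t))
}

#' Packaged synthetic tissue-surrogate catalogue
#'
#' Plausible lung/soft/bone surrogate reference values (synthetic, not
#' vendor-measured) read from `inst/extdata/surrogates_synthetic.csv`,
#' with nominal dual-energy attenuations generated by [dectNominalMu()].
#'
#' @param path CSV file with columns name, reference_red, reference_ean;
#'   defaults to the packaged synthetic table.
#' @return data frame with columns name, reference_red, reference_ean,
#'   muLow, muHigh.
#' @export
defaultSurrogates <- function(path = system.file("extdata",
        "surrogates_synthetic.csv", package = "wetspr")) {
    tab <- utils::read.csv(path, comment.char = "#",
        stringsAsFactors = FALSE)
    stopifnot(all(c("name", "reference_red", "reference_ean") %in%
        names(tab)))
    cbind(tab, dectNominalMu(tab$reference_red, tab$reference_ean))
}

## ---- phantom builders -------------------------------------------------------

#' Build a generic ellipse phantom spec
#'
#' Convenience constructor for the generic-geometry experiments: one
#' uniform (optionally rotated) ellipse, optional inhomogeneity shapes,
#' grid auto-sized to the object.
#'
#' @param semiA,semiB ellipse semi-axes (mm).
#' @param rotationDeg rotation (deg).
#' @param mu relative attenuation of the ellipse.
#' @param inhomogeneities list of [EllipseShape-class] inside the object.
#' @param spacing pixel size (mm).
#' @param margin air margin around the object (mm).
#' @param ... further arguments to [phantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
ellipsePhantom <- function(semiA, semiB = semiA, rotationDeg = 0, mu = 1,
                           inhomogeneities = list(), spacing = 1,
                           margin = 10, ...) {
    ext <- max(semiA, semiB) + margin
    n <- 2L * as.integer(ceiling(ext / spacing))
    phantomSpec(n, n, spacing = spacing,
        shapes = c(list(ellipseShape(0, 0, semiA, semiB, rotationDeg,
            muLow = mu)), inhomogeneities), ...)
}

#' Build a cylindrical insert phantom spec
#'
#' Emulates the cylindrical acrylic calibration phantoms: a uniform body
#' disk of the given diameter with tissue-surrogate inserts arranged on a
#' ring at 0.3 diameter radius (insert radius diameter/14), an optional
#' couch, and the default beam-hardening bias model.
#'
#' @param diameter body diameter (mm).
#' @param bodyRed,bodyEan body material relative electron density and
#'   effective atomic number (defaults emulate acrylic/PMMA).
#' @param surrogates surrogate catalogue data frame (see
#'   [defaultSurrogates()]); use `NULL` for a uniform phantom without
#'   inserts.
#' @param couch optional [CouchSpec-class].
#' @param hardening [HardeningModel-class] (default
#'   [defaultHardeningModel()]).
#' @param noiseSigmaHu,seed,spacing,supersample see [phantomSpec()].
#' @param margin air margin around the object (mm).
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- cylinderPhantom(150, surrogates = NULL)
#' groundTruthWet(spec) / 150    # body relative attenuation
#' @export
cylinderPhantom <- function(diameter, bodyRed = 1.147, bodyEan = 6.47,
                            surrogates = defaultSurrogates(),
                            couch = NULL,
                            hardening = defaultHardeningModel(),
                            noiseSigmaHu = 0, seed = 1L, spacing = 1,
                            supersample = 4L, margin = 20) {
    bodyMu <- dectNominalMu(bodyRed, bodyEan)
    body <- ellipseShape(0, 0, diameter / 2, diameter / 2, 0,
        muLow = bodyMu$muLow, muHigh = bodyMu$muHigh)
    inserts <- list()
    if (!is.null(surrogates) && nrow(surrogates)) {
        ringR <- 0.3 * diameter
        insR <- diameter / 14
        ang <- -pi / 2 + 2 * pi * (seq_len(nrow(surrogates)) - 1L) /
            nrow(surrogates)
        inserts <- lapply(seq_len(nrow(surrogates)), function(k)
            surrogateInsert(surrogates$name[k],
                ringR * cos(ang[k]), ringR * sin(ang[k]), insR,
                surrogates$reference_red[k], surrogates$reference_ean[k],
                surrogates$muLow[k], surrogates$muHigh[k]))
    }
    widthMm <- diameter + 2 * margin
    heightMm <- diameter + 2 * margin
    if (!is.null(couch)) {
        widthMm <- max(widthMm, couch@width + 2 * spacing)
        heightMm <- heightMm + couch@gap + couch@thickness
    }
    phantomSpec(
        nRow = as.integer(ceiling(heightMm / spacing)),
        nCol = as.integer(ceiling(widthMm / spacing)),
        spacing = spacing, shapes = list(body), couch = couch,
        inserts = inserts, noiseSigmaHu = noiseSigmaHu, seed = seed,
        hardening = hardening, supersample = supersample)
}

#' Simulate a diameter sweep of cylindrical insert phantoms
#'
#' One simulated dual-energy acquisition per diameter (spanning, by
#' default use, 75–400 mm), with seed policy `seed + index` so duplicate
#' diameters produce independent noise.  For every phantom the slice WET
#' is also estimated with each thickness estimation method from the
#' low-energy image (attenuation-clipped), providing the TEM-specific WET
#' axes used for calibration.
#'
#' @param diameters positive diameters (mm); must be non-empty.
#' @param seed base seed.
#' @param ... further arguments passed to [cylinderPhantom()].
#' @return list with one element per diameter: `diameter`, `spec`,
#'   `image`, `measurements`, `wetTrue`, `wetByMethod` (named numeric).
#' @export
phantomSweep <- function(diameters, seed = 1L, ...) {
    if (!length(diameters))
        stop("'diameters' must be a non-empty list of sizes",
            call. = FALSE)
    if (any(diameters <= 0))
        stop("diameters must be positive", call. = FALSE)
    lapply(seq_along(diameters), function(i) {
        spec <- cylinderPhantom(diameters[i],
            seed = as.integer(seed) + i, ...)
        sim <- simulateDect(spec)
        mu <- huToMu(lowEnergy(sim$image))
        wetByMethod <- c("tem-a" = temA(mu), "tem-b1" = temB1(mu),
            "tem-b2" = temB2(mu))
        list(diameter = diameters[i], spec = spec, image = sim$image,
            measurements = sim$measurements, wetTrue = sim$wetTrue,
            wetByMethod = wetByMethod)
    })
}
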