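## Independent oracles used across the suite.  These deliberately avoid
## the package's own code paths: explicit double loops, grid search and
## closed forms.

## brute-force double-loop TEM implementations
bruteTems <- function(px, sx = 1, sy = 1) {
    px[px < 0] <- 0
    nr <- nrow(px); nc <- ncol(px)
    rowMax <- 0
    for (i in seq_len(nr)) {
        s <- 0
        for (j in seq_len(nc)) s <- s + px[i, j] * sx
        if (s > rowMax) rowMax <- s
    }
    colMax <- 0
    for (j in seq_len(nc)) {
        s <- 0
        for (i in seq_len(nr)) s <- s + px[i, j] * sy
        if (s > colMax) colMax <- s
    }
    s1 <- 0; s2 <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        s1 <- s1 + px[i, j] * sx * sy
        s2 <- s2 + px[i, j]^2 * sx * sy
    }
    c("tem-a" = sqrt(rowMax * colMax), "tem-b1" = 2 * sqrt(s1 / pi),
        "tem-b2" = 2 * sqrt(s2 / pi))
}

## longest chord of an ellipse (semi-axes a, b) along direction theta
## (radians, measured from the a-axis): the central chord
ellipseChord <- function(theta, a, b)
    2 / sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)

## two-stage 1-D grid search minimising the weighted SSE of
## target ~ alpha*muL + (1-alpha)*muH; resolves alpha to ~5e-8
gridSearchAlpha <- function(muL, muH, target, w = rep(1, length(muL))) {
    d <- muL - muH
    r <- target - muH
    sse <- function(alpha)
        colSums(w * (matrix(r, length(r), length(alpha)) -
            outer(d, alpha))^2)
    coarse <- seq(-25, 25, by = 1e-3)
    a0 <- coarse[which.min(sse(coarse))]
    fine <- seq(a0 - 2e-3, a0 + 2e-3, by = 1e-7)
    fine[which.min(sse(fine))]
}

## independent Bethe evaluation (scalar, re-derived constants)
betheOracle <- function(red, iEv, energyMeV = 100, iwEv = 75) {
    bsq <- 1 - 1 / (1 + energyMeV / 938.272)^2
    num <- log(2 * 0.511e6 * bsq / (iEv * (1 - bsq))) - bsq
    den <- log(2 * 0.511e6 * bsq / (iwEv * (1 - bsq))) - bsq
    red * num / den
}

## sweeps reused by calibration, SPR and acceptance tests (expensive)
.sweepCache <- new.env(parent = emptyenv())
cachedSweep <- function(key = c("default", "flat")) {
    key <- match.arg(key)
    if (is.null(.sweepCache[[key]])) {
        .sweepCache[[key]] <- switch(key,
            default = phantomSweep(seq(75, 400, by = 25), seed = 11L),
            flat = phantomSweep(c(100, 200, 300), seed = 11L,
                hardening = hardeningModel(gLow = 0, gHigh = 0,
                    bLow = 0, bHigh = 0)))
    }
    .sweepCache[[key]]
}

softBoneSplit <- function(measurements, zSoft = 8.8)
    list(soft = measurements$reference_ean <= zSoft,
        bone = measurements$reference_ean > zSoft)
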