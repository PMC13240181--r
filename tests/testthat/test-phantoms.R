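test_that("rasterization reproduces analytic areas", {
    spec <- ellipsePhantom(semiA = 100, mu = 1, spacing = 1)
    img <- rasterize(spec)
    area <- sum(pixels(img)) * prod(pixelSpacing(img))
    expect_lt(abs(area - pi * 100^2) / (pi * 100^2), 0.002)
    rot <- ellipsePhantom(semiA = 80, semiB = 40, rotationDeg = 30,
        mu = 1.05)
    arearot <- sum(pixels(rasterize(rot)))
    expect_lt(abs(arearot - pi * 80 * 40 * 1.05) / (pi * 80 * 40 * 1.05),
        0.002)
})

test_that("empty specs rasterize to zero and disjoint shapes add", {
    expect_true(all(pixels(rasterize(phantomSpec(32, 32))) == 0))
    d1 <- ellipseShape(-30, 0, 10, muLow = 1)
    d2 <- ellipseShape(30, 0, 10, muLow = 2)
    s12 <- sum(pixels(rasterize(phantomSpec(100, 100,
        shapes = list(d1, d2)))))
    s1 <- sum(pixels(rasterize(phantomSpec(100, 100,
        shapes = list(d1)))))
    s2 <- sum(pixels(rasterize(phantomSpec(100, 100,
        shapes = list(d2)))))
    expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("shapes exceeding the grid are rejected", {
    spec <- phantomSpec(50, 50, shapes = list(ellipseShape(semiA = 40)))
    expect_error(rasterize(spec), "exceeds the image grid")
})

test_that("ground-truth WET is the effective diameter times mean mu", {
    ell <- ellipsePhantom(semiA = 100, semiB = 50, mu = 1)
    expect_equal(groundTruthWet(ell), 2 * sqrt(100 * 50),
        tolerance = 1e-12)                      # 141.4214 mm
    circ <- ellipsePhantom(semiA = 50, mu = 1.1)
    expect_equal(groundTruthWet(circ), 110, tolerance = 1e-12)
    rot <- ellipsePhantom(semiA = 100, semiB = 50, rotationDeg = 45)
    expect_identical(groundTruthWet(rot), groundTruthWet(ell))
})

test_that("ground truth accounts for enclosed inhomogeneities only", {
    inh <- list(ellipseShape(40, 40, 10, muLow = 1.5))
    spec <- ellipsePhantom(semiA = 100, mu = 1, inhomogeneities = inh)
    ## area-weighted mean mu: (pi*100^2 + 0.5*pi*10^2) / (pi*100^2)
    expect_equal(groundTruthWet(spec), 200 * (1 + 0.5 * 100 / 100^2),
        tolerance = 1e-12)
    outside <- list(ellipseShape(98, 0, 10, muLow = 1.5))
    bad <- ellipsePhantom(semiA = 100, mu = 1, margin = 20,
        inhomogeneities = outside)
    expect_error(groundTruthWet(bad), "single primary")
})

test_that("hardening bias is multiplicative and vanishes at W0", {
    hm <- defaultHardeningModel()   # gLow -5e-5 per mm, W0 200 mm
    b <- hardeningBias(hm, wet = 400)
    expect_equal(1.2 * b[["low"]], 1.188, tolerance = 1e-12)
    expect_identical(hardeningBias(hm, wet = 200),
        c(low = 1, high = 1))
    bone <- hardeningBias(hm, wet = 400, ean = 13.6)
    expect_equal(bone[["low"]], (1 - 5e-5 * 200) * (1 - 8e-5 * 200),
        tolerance = 1e-12)
    soft <- hardeningBias(hm, wet = 400, ean = 7.6)
    expect_identical(soft, b)   # below zSoft: no bone term
})

test_that("unbiased noise-free simulation reproduces exact CT numbers", {
    spec <- cylinderPhantom(120, surrogates = defaultSurrogates()[1:4, ],
        hardening = hardeningModel(gLow = 0, gHigh = 0, bLow = 0,
            bHigh = 0))
    sim <- simulateDect(spec)
    body <- spec@shapes[[1]]
    huLow <- pixels(lowEnergy(sim$image))
    ## pixel at the centre is pure body material
    ctr <- dim(huLow) %/% 2
    expect_equal(huLow[ctr[1], ctr[2]], (body@muLow - 1) * 1000,
        tolerance = 1e-12)
    ## ROI means equal the nominal insert CT numbers exactly
    surr <- defaultSurrogates()[1:4, ]
    expect_equal(sim$measurements$H_low, (surr$muLow - 1) * 1000,
        tolerance = 1e-9)
    expect_equal(sim$measurements$H_high, (surr$muHigh - 1) * 1000,
        tolerance = 1e-9)
})

test_that("biased ROI means equal the biased material CT numbers", {
    spec <- cylinderPhantom(300, surrogates = defaultSurrogates())
    sim <- simulateDect(spec)
    surr <- defaultSurrogates()
    hm <- spec@hardening
    expected <- vapply(seq_len(nrow(surr)), function(k) {
        b <- hardeningBias(hm, sim$wetTrue, surr$reference_ean[k])
        (surr$muLow[k] * b[["low"]] - 1) * 1000
    }, 0)
    expect_equal(sim$measurements$H_low, expected, tolerance = 1e-9)
    expect_equal(sim$measurements$wet_mm,
        rep(sim$wetTrue, nrow(surr)))
})

test_that("simulation is seeded and deterministic", {
    spec <- cylinderPhantom(100, surrogates = NULL, noiseSigmaHu = 10,
        seed = 42L)
    a <- simulateDect(spec)
    b <- simulateDect(spec)
    expect_identical(pixels(lowEnergy(a$image)),
        pixels(lowEnergy(b$image)))
    spec2 <- cylinderPhantom(100, surrogates = NULL, noiseSigmaHu = 10,
        seed = 43L)
    c <- simulateDect(spec2)
    expect_false(identical(pixels(lowEnergy(a$image)),
        pixels(lowEnergy(c$image))))
    ## noise does not disturb the caller's RNG stream
    set.seed(99); before <- rnorm(1)
    set.seed(99); invisible(simulateDect(spec)); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("simulation requires a hardening model", {
    spec <- cylinderPhantom(100, surrogates = NULL, hardening = NULL)
    expect_error(simulateDect(spec), "hardening model")
})

test_that("phantom sweeps cover the requested diameters", {
    sw <- phantomSweep(c(75, 400), seed = 5L, surrogates = NULL)
    expect_length(sw, 2L)
    bodyMu <- dectNominalMu(1.147, 6.47)$muLow
    expect_equal(vapply(sw, `[[`, 0, "wetTrue"),
        c(75, 400) * bodyMu, tolerance = 1e-12)
    expect_error(phantomSweep(numeric(0)), "non-empty")
    ## duplicate diameters get independent noise through the seed policy
    dup <- phantomSweep(c(100, 100), seed = 5L, surrogates = NULL,
        noiseSigmaHu = 10)
    expect_false(identical(pixels(lowEnergy(dup[[1]]$image)),
        pixels(lowEnergy(dup[[2]]$image))))
})
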