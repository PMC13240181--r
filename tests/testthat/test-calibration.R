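test_that("alpha_red closed form solves the single-surrogate case", {
    ## muL = 1.05, muH = 1.02, red 1.03 -> alpha = (1.03-1.02)/0.03
    m <- data.frame(H_low = 50, H_high = 20, reference_red = 1.03,
        reference_ean = 7.5)
    expect_equal(fitAlphaRed(m), 1 / 3, tolerance = 1e-12)
    ## references equal to muH leave no low-energy weight
    m2 <- data.frame(H_low = c(80, -30), H_high = c(40, -60),
        reference_red = c(1.04, 0.94), reference_ean = c(7.5, 7.5))
    expect_equal(fitAlphaRed(m2), 0, tolerance = 1e-12)
})

test_that("alpha_ean closed form solves the single-bone case", {
    ## muL 1.40, muH 1.25, red 1.30, (Z/Zw)^3.1 = 1.8 -> z = 2.34
    ean <- 7.45 * 1.8^(1 / 3.1)
    m <- data.frame(H_low = 400, H_high = 250, reference_red = 1.30,
        reference_ean = ean)
    expect_equal(fitAlphaEan(m), (2.34 - 1.25) / 0.15,
        tolerance = 1e-9)
})

test_that("degenerate measurements are rejected", {
    m <- data.frame(H_low = c(10, 20), H_high = c(10, 20),
        reference_red = c(1, 1.1), reference_ean = c(7.5, 8))
    expect_error(fitAlphaRed(m), "unidentifiable")
    expect_error(fitAlphaEan(m), "unidentifiable")
})

test_that("closed-form fits match a grid-search oracle", {
    set.seed(8)
    for (rep in 1:5) {
        n <- 5L
        muL <- runif(n, 0.3, 2.9)
        muH <- muL + runif(n, 0.02, 0.4) * sample(c(-1, 1), n, TRUE)
        m <- data.frame(H_low = (muL - 1) * 1000,
            H_high = (muH - 1) * 1000,
            reference_red = runif(n, 0.3, 1.8),
            reference_ean = runif(n, 6, 14),
            weight = runif(n, 0.5, 2))
        oracleRed <- gridSearchAlpha(muL, muH, m$reference_red,
            m$weight)
        expect_equal(fitAlphaRed(m), oracleRed, tolerance = 1e-6)
        z <- m$reference_red * (m$reference_ean / 7.45)^3.1
        oracleEan <- gridSearchAlpha(muL, muH, z, m$weight)
        expect_equal(fitAlphaEan(m), oracleEan, tolerance = 1e-6)
    }
})

test_that("curves interpolate linearly and clamp outside the knots", {
    cv <- buildCurve(c(100, 300), alphaRed = c(0.4, 0.6),
        alphaEan = c(10, 14), method = "tem-b1")
    expect_equal(lookupAlpha(cv, 200)[["alpha_red"]], 0.5)
    expect_equal(lookupAlpha(cv, 200)[["alpha_ean"]], 12)
    expect_equal(lookupAlpha(cv, 50)[["alpha_red"]], 0.4)   # clamped
    expect_equal(lookupAlpha(cv, 1000)[["alpha_red"]], 0.6) # clamped
    expect_equal(lookupAlpha(cv, 100)[["alpha_red"]], 0.4)  # knot exact
    expect_error(buildCurve(c(100, 100), c(1, 1), c(1, 1), "tem-a"),
        "duplicate")
    expect_error(new("CalibrationCurve", method = "tem-a", wet = 100,
        alphaRed = 1, alphaEan = 1))
    expect_error(lookupAlpha(cv, -5), ">= 0")
})

test_that("curve CSV serialization round-trips", {
    cv <- buildCurve(c(82.4, 219.6, 439.3),
        alphaRed = c(-0.496, -0.501, -0.508),
        alphaEan = c(13.26, 12.1, 11.45), method = "tem-b2")
    p <- withr::local_tempfile(fileext = ".csv")
    writeCurve(cv, p, extraHeader = c(seed = "1"))
    back <- readCurve(p)
    expect_equal(back@wet, cv@wet, tolerance = 1e-10)
    expect_equal(back@alphaRed, cv@alphaRed, tolerance = 1e-10)
    expect_identical(temMethod(back), "tem-b2")
})

test_that("per-size fits on the synthetic sweep match the grid oracle
           and predict held-out surrogates", {
    sw <- cachedSweep("default")
    for (s in sw[c(1, 8, 14)]) {
        m <- s$measurements
        muL <- m$H_low / 1000 + 1
        muH <- m$H_high / 1000 + 1
        expect_equal(fitAlphaRed(m),
            gridSearchAlpha(muL, muH, m$reference_red),
            tolerance = 1e-6)
        z <- m$reference_red * (m$reference_ean / 7.45)^3.1
        expect_equal(fitAlphaEan(m), gridSearchAlpha(muL, muH, z),
            tolerance = 1e-6)
    }
    ## hold out one soft and one bone surrogate from the fit
    for (held in c("liver", "cb2_30")) {
        cv <- calibrateSweep(sw, "tem-b1", exclude = held)
        for (s in sw[c(1, 8, 14)]) {
            m <- s$measurements
            alpha <- lookupAlpha(cv,
                unname(s$wetByMethod["tem-b1"]))
            row <- m[m$insert == held, ]
            pred <- redFromCtn(row$H_low / 1000 + 1,
                row$H_high / 1000 + 1, alpha[["alpha_red"]])
            expect_lt(abs(pred - row$reference_red) /
                row$reference_red, 0.005)
        }
    }
})

test_that("without beam hardening the calibration curve is flat", {
    sw <- cachedSweep("flat")
    cv <- calibrateSweep(sw, "tem-b1")
    expect_lt(diff(range(cv@alphaRed)), 1e-9)
    expect_lt(diff(range(cv@alphaEan)), 1e-9)
    ## and equals the forward model's exact weighting factors
    expect_equal(cv@alphaRed[1], -0.5, tolerance = 1e-9)
    expect_equal(cv@alphaEan[1], 12, tolerance = 1e-9)
})

test_that("curves are TEM-specific only through their WET axis", {
    sw <- cachedSweep("default")
    cb1 <- calibrateSweep(sw, "tem-b1")
    cb2 <- calibrateSweep(sw, "tem-b2")
    expect_equal(cb1@alphaRed, cb2@alphaRed, tolerance = 1e-12)
    expect_equal(cb1@alphaEan, cb2@alphaEan, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(cb1@wet, cb2@wet)))
})
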