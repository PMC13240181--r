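test_that("TEMs recover analytic WET of uniform circles and ellipses", {
    circ <- rasterize(ellipsePhantom(semiA = 100, mu = 1))
    expect_equal(temA(circ), 200, tolerance = 0.01)
    expect_equal(temB1(circ), 200, tolerance = 0.002)
    expect_equal(temB2(circ), 200, tolerance = 0.002)
    ell <- rasterize(ellipsePhantom(semiA = 100, semiB = 50, mu = 1))
    gt <- 2 * sqrt(100 * 50)
    expect_equal(temA(ell), gt, tolerance = 0.01)
    expect_equal(temB1(ell), gt, tolerance = 0.002)
    expect_equal(temB2(ell), gt, tolerance = 0.002)
    ## non-water uniform attenuation: closed forms differ per method
    c11 <- rasterize(ellipsePhantom(semiA = 50, mu = 1.1))
    expect_equal(temB1(c11), 100 * sqrt(1.1), tolerance = 0.002)
    expect_equal(temB2(c11), 110, tolerance = 0.002)
    zero <- AttenuationImage(matrix(0, 16, 16))
    expect_identical(temA(zero), 0)
    expect_identical(temB1(zero), 0)
    expect_identical(temB2(zero), 0)
})

test_that("rotated ellipses expose TEM-A's directional-chord bias", {
    e45 <- rasterize(ellipsePhantom(semiA = 100, semiB = 50,
        rotationDeg = 45))
    ## both row and column maxima equal the 45-degree central chord
    oracle <- ellipseChord(pi / 4, 100, 50)
    expect_equal(temA(e45), oracle, tolerance = 0.01)
    gt <- 2 * sqrt(100 * 50)
    dev <- 100 * (temA(e45) - gt) / gt
    expect_equal(dev, 100 * (oracle - gt) / gt, tolerance = 0.05)
    ## area methods are rotation-robust
    spread <- sapply(seq(0, 90, by = 15), function(r) {
        img <- rasterize(ellipsePhantom(semiA = 100, semiB = 50,
            rotationDeg = r))
        c(b1 = temB1(img), b2 = temB2(img))
    })
    expect_lt(100 * diff(range(spread["b1", ])) / mean(spread["b1", ]),
        0.2)
    expect_lt(100 * diff(range(spread["b2", ])) / mean(spread["b2", ]),
        0.2)
})

test_that("TEM-B1 and TEM-B2 coincide on binary images", {
    set.seed(4)
    px <- matrix(rbinom(900, 1, 0.4), 30, 30)
    img <- AttenuationImage(px + 0, spacing = c(0.8, 1.2))
    expect_equal(temB1(img), temB2(img), tolerance = 1e-12)
})

test_that("TEMs obey their exact attenuation scaling laws", {
    set.seed(5)
    px <- matrix(runif(400), 20, 20)
    img <- AttenuationImage(px, spacing = c(1.1, 0.9))
    for (k in c(0, 0.25, 1, 3.7)) {
        scaled <- AttenuationImage(k * px, spacing = c(1.1, 0.9))
        expect_equal(temA(scaled), k * temA(img), tolerance = 1e-9)
        expect_equal(temB2(scaled), k * temB2(img), tolerance = 1e-9)
        expect_equal(temB1(scaled), sqrt(k) * temB1(img),
            tolerance = 1e-9)
    }
})

test_that("TEMs match a brute-force double-loop oracle", {
    set.seed(6)
    for (rep in 1:25) {
        nr <- sample(2:32, 1); nc <- sample(2:32, 1)
        px <- matrix(runif(nr * nc, 0, 2), nr, nc)
        sx <- runif(1, 0.5, 2); sy <- runif(1, 0.5, 2)
        img <- AttenuationImage(px, spacing = c(sx, sy))
        oracle <- bruteTems(px, sx, sy)
        expect_equal(temA(img), oracle[["tem-a"]], tolerance = 1e-12)
        expect_equal(temB1(img), oracle[["tem-b1"]], tolerance = 1e-12)
        expect_equal(temB2(img), oracle[["tem-b2"]], tolerance = 1e-12)
    }
})

test_that("negative attenuation is clamped before the sums", {
    px <- matrix(c(-0.5, 1, 1, 1), 2, 2)
    img <- AttenuationImage(px)
    clamped <- AttenuationImage(pmax(px, 0))
    expect_identical(temA(img), temA(clamped))
    expect_identical(temB1(img), temB1(clamped))
    expect_identical(temB2(img), temB2(clamped))
})

test_that("off-centre inhomogeneities barely move TEM-A but shift TEM-B1", {
    base <- ellipsePhantom(semiA = 100, mu = 1)
    inh <- ellipsePhantom(semiA = 100, mu = 1,
        inhomogeneities = list(ellipseShape(40, 40, 10, muLow = 1.5)))
    i0 <- rasterize(base); i1 <- rasterize(inh)
    expect_lt(abs(temA(i1) - temA(i0)) / temA(i0), 0.001)
    ## equal-area analytic shift: 2*sqrt(100^2 + 0.5*10^2)
    expect_equal(temB1(i1), 2 * sqrt(100^2 + 0.5 * 10^2),
        tolerance = 0.002)
})

test_that("the couch inflates every TEM, most strongly TEM-A when its
           water-equivalent width dominates the row maximum", {
    for (D in c(75, 100, 150)) {
        base <- rasterize(cylinderPhantom(D, surrogates = NULL))
        couch <- rasterize(cylinderPhantom(D, surrogates = NULL,
            couch = couchSpec()))
        expect_gt(temA(couch), temA(base))
        expect_gt(temB1(couch), temB1(base))
        expect_gt(temB2(couch), temB2(base))
        ## the default couch spans 500 mm at mu 0.3 (150 mm water-
        ## equivalent): it out-weighs the body row maximum only for
        ## cylinders below ~135 mm of acrylic, where TEM-A is hit hardest
        if (D <= 100)
            expect_gt(temA(couch) - temA(base),
                temB1(couch) - temB1(base))
    }
})

test_that("profiles apply one method per slice and summarise by median", {
    img <- rasterize(ellipsePhantom(semiA = 40))
    prof <- estimateProfile(list(img, img, img), "tem-b1")
    expect_length(wetValues(prof), 3L)
    expect_equal(unname(unique(wetValues(prof))), wetSummary(prof))
    expect_identical(temMethod(prof), "tem-b1")
    single <- estimateProfile(list(img), "tem-a")
    expect_length(wetValues(single), 1L)
    expect_error(estimateProfile(list(), "tem-a"), "at least one")
    ## one profile cannot mix methods
    expect_error(new("WetProfile", method = c("tem-a", "tem-b1"),
        sliceIndex = c(0L, 1L), wet = c(1, 2)))
})

test_that("pairwise deviations report mm and percent of the mean", {
    p <- function(m, w) new("WetProfile", method = m,
        sliceIndex = seq_along(w) - 1L, wet = w)
    two <- maxPairwiseDeviation(list(p("tem-a", 200), p("tem-b1", 210)))
    expect_equal(two$maxMm, 10)
    expect_equal(two$maxPct, 100 * 10 / 205, tolerance = 1e-9)
    three <- maxPairwiseDeviation(list(p("tem-a", 200),
        p("tem-b1", 205), p("tem-b2", 210)))
    expect_equal(three$maxMm, 10)
    same <- maxPairwiseDeviation(list(p("tem-a", c(100, 150)),
        p("tem-b1", c(100, 150))))
    expect_equal(same$maxMm, 0)
    expect_error(maxPairwiseDeviation(list(p("tem-a", 200))),
        "at least two")
    expect_error(maxPairwiseDeviation(list(p("tem-a", c(1, 2)),
        p("tem-b1", 3))), "equal length")
})
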