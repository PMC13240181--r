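test_that("HU to attenuation conversion follows the HU definition", {
    img <- HUImage(matrix(c(0, -1000, -1200, 137.5), 2, 2))
    mu <- huToMu(img, clipNegative = FALSE)
    expect_identical(pixels(mu)[1, 1], 1)     # water
    expect_identical(pixels(mu)[2, 1], 0)     # air limit
    expect_equal(pixels(mu)[1, 2], -0.2)      # below air, unclipped
    expect_equal(pixels(huToMu(img))[1, 2], 0)  # clipped by default
    expect_s4_class(mu, "AttenuationImage")
    expect_identical(pixelSpacing(mu), pixelSpacing(img))
})

test_that("attenuation to HU and round trip are exact", {
    expect_identical(pixels(muToHu(AttenuationImage(matrix(1))))[1], 0)
    expect_identical(pixels(muToHu(AttenuationImage(matrix(2))))[1],
        1000)
    set.seed(7)
    hu <- matrix(runif(300, -1100, 2000), 15, 20)
    img <- HUImage(hu, spacing = c(0.7, 1.3), sliceIndex = 4L)
    back <- muToHu(huToMu(img, clipNegative = FALSE))
    expect_equal(pixels(back), hu, tolerance = 1e-12)
    expect_identical(sliceIndex(back), 4L)
})

test_that("non-finite pixels are rejected with their location", {
    hu <- matrix(0, 3, 3)
    hu[2, 3] <- NaN
    expect_error(HUImage(hu), "row 2, col 3")
})

test_that("cropping takes half-open-equivalent inclusive boxes", {
    set.seed(1)
    img <- HUImage(matrix(rnorm(100), 10, 10), spacing = c(2, 0.5))
    full <- cropImage(img, rows = c(1, 10), cols = c(1, 10))
    expect_identical(pixels(full), pixels(img))
    sub <- cropImage(img, rows = c(1, 5), cols = c(1, 10))
    expect_identical(dim(pixels(sub)), c(5L, 10L))
    expect_identical(pixelSpacing(sub), pixelSpacing(img))
    expect_error(cropImage(img, rows = c(6, 5), cols = c(1, 10)),
        "empty crop")
    expect_error(cropImage(img, rows = c(0, 5), cols = c(1, 10)),
        "out of image bounds")
    expect_error(cropImage(img, rows = c(1, 11), cols = c(1, 10)),
        "out of image bounds")
})

test_that("cropping commutes with HU/attenuation conversion", {
    set.seed(2)
    img <- HUImage(matrix(rnorm(96, 0, 300), 12, 8))
    a <- pixels(cropImage(huToMu(img), rows = c(3, 9), cols = c(2, 7)))
    b <- pixels(huToMu(cropImage(img, rows = c(3, 9), cols = c(2, 7))))
    expect_identical(a, b)
})

test_that("matrix fixture round trip is lossless", {
    set.seed(3)
    img <- HUImage(matrix(rnorm(9, 0, 1000), 3, 3),
        spacing = c(0.9765625, 1.171875), sliceIndex = 7L)
    p <- withr::local_tempfile(fileext = ".txt")
    writeMatrixFixture(img, p)
    back <- readMatrixFixture(p, type = "hu")
    expect_identical(pixels(back), pixels(img))
    expect_identical(pixelSpacing(back), pixelSpacing(img))
    expect_identical(sliceIndex(back), 7L)
})

test_that("malformed fixtures are rejected", {
    p <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# spacing_x: 1", "# spacing_y: 1",
        "# slice_index: 0", "1 2 3", "4 5"), p)
    expect_error(readMatrixFixture(p), "ragged")
    writeLines(c("# spacing_y: 1", "# slice_index: 0", "1 2"), p)
    expect_error(readMatrixFixture(p), "spacing_x")
})

test_that("DICOM series round trip applies rescale metadata", {
    slices <- list(
        HUImage(matrix(seq(-1000, 1000, length.out = 24), 4, 6),
            spacing = c(0.8, 0.8)),
        HUImage(matrix(0, 4, 6), spacing = c(0.8, 0.8)))
    d <- withr::local_tempdir()
    writeDicomSeries(slices, d, slope = 1, intercept = -1024)
    back <- readDicomSeries(d)
    expect_length(back, 2L)
    ## stored value 1024 with slope 1, intercept -1024 must read as 0 HU
    expect_true(all(pixels(back[[2]]) == 0))
    expect_equal(pixels(back[[1]]), round(pixels(slices[[1]])),
        tolerance = 1e-12)
    expect_identical(unname(pixelSpacing(back[[1]])), c(0.8, 0.8))
    expect_identical(vapply(back, sliceIndex, 0L), c(0L, 1L))
})

test_that("DICOM slices are ordered by axial position", {
    d <- withr::local_tempdir()
    imgs <- list(HUImage(matrix(1, 2, 2)), HUImage(matrix(2, 2, 2)),
        HUImage(matrix(3, 2, 2)))
    writeDicomSeries(imgs, d)
    ## renaming files must not change axial (slice-location) order
    file.rename(file.path(d, "slice_001.dcm"),
        file.path(d, "zzz_last.dcm"))
    back <- readDicomSeries(d)
    expect_equal(vapply(back, function(s) pixels(s)[1, 1], 0),
        c(1, 2, 3))
})

test_that("inconsistent series and empty directories are rejected", {
    d <- withr::local_tempdir()
    writeDicomSeries(HUImage(matrix(0, 2, 2), spacing = c(1, 1)), d)
    d2 <- withr::local_tempdir()
    writeDicomSeries(HUImage(matrix(0, 2, 2), spacing = c(2, 2)), d2)
    file.copy(file.path(d2, "slice_001.dcm"),
        file.path(d, "slice_002.dcm"))
    expect_error(readDicomSeries(d), "spacing")
    empty <- withr::local_tempdir()
    expect_error(readDicomSeries(empty), "no DICOM files")
})
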