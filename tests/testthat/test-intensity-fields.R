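test_that("ensurePositive clamps at the floor and is idempotent", {
    f <- ensurePositive(matrix(c(5, -3, 0, 10), 2, 2), floor = 1)
    expect_equal(intensityValues(f), matrix(c(5, 1, 1, 10), 2, 2))

    m <- matrix(c(2, 3, 4, 5), 2, 2)
    expect_equal(intensityValues(ensurePositive(m, floor = 1)), m)

    twice <- ensurePositive(ensurePositive(matrix(c(5, -3, 0, 10), 2, 2), 1), 1)
    expect_equal(intensityValues(twice), matrix(c(5, 1, 1, 10), 2, 2))

    expect_error(ensurePositive(matrix(c(1, NA, 1, 1), 2, 2), 1),
                 "non-finite")
    expect_error(ensurePositive(matrix(1, 2, 2), floor = -1))
})

test_that("a fully clamped field is constant and has zero TI", {
    f <- ensurePositive(matrix(-1, 8, 8), floor = 1)
    expect_true(all(intensityValues(f) == 1))
    expect_equal(transformationInformation(f, rotationSpec(30)), 0,
                 tolerance = 1e-12)
})

test_that("image loading reproduces luminance and greenness formulas", {
    skip_if_not_installed("EBImage")
    tmp <- withr::local_tempdir()

    ## uniform white RGB -> constant grey field
    white <- EBImage::Image(array(1, dim = c(6, 6, 3)), colormode = "Color")
    pw <- file.path(tmp, "white.png")
    EBImage::writeImage(white, pw, bits.per.sample = 8L)
    fw <- loadIntensity(pw, "grey")
    expect_equal(diff(range(intensityValues(fw))), 0)
    expect_equal(fieldCentre(fw), c(3.5, 3.5))

    ## one pure green and one pure red pixel under greenness
    arr <- array(0, dim = c(6, 6, 3))
    arr[2, 2, 2] <- 1   # green at (x=2, y=2 from top)
    arr[3, 3, 1] <- 1   # red
    pg <- file.path(tmp, "gr.png")
    EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), pg,
                        bits.per.sample = 8L)
    fg <- loadIntensity(pg, "greenness")
    ## 2g - r - b + 1 = 511 for the green pixel; red pixel raw -254 -> floor
    expect_equal(max(intensityValues(fg)), 511)
    expect_equal(min(intensityValues(fg)), 1)

    ## grey of an r=g=b image equals the greyscale file of the same values
    set.seed(4)
    gv <- matrix(round(runif(36) * 255) / 255, 6, 6)
    rgb <- array(rep(gv, 3), dim = c(6, 6, 3))
    p1 <- file.path(tmp, "rgb.png"); p2 <- file.path(tmp, "gy.png")
    EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), p1,
                        bits.per.sample = 8L)
    EBImage::writeImage(EBImage::Image(gv), p2, bits.per.sample = 8L)
    expect_equal(intensityValues(loadIntensity(p1, "grey")),
                 intensityValues(loadIntensity(p2, "grey")),
                 tolerance = 1e-6)

    expect_error(loadIntensity(p2, "greenness"), "RGB")
    expect_error(loadIntensity(file.path(tmp, "nope.png")), "read")
})

test_that("block-mean downsampling composes and rescales geometry", {
    f <- intensityField(matrix(7, 4, 4))
    d <- downsampleField(f, 2)
    expect_equal(dim(intensityValues(d)), c(2L, 2L))
    expect_true(all(intensityValues(d) == 7))
    expect_equal(pixelSize(d), 2)

    expect_identical(downsampleField(f, 1), f)

    g <- smoothTestField(size = 64, seed = 2)
    ab <- downsampleField(g, 8)
    a_b <- downsampleField(downsampleField(g, 2), 4)
    expect_equal(intensityValues(ab), intensityValues(a_b),
                 tolerance = 1e-12)
    expect_equal(fieldCentre(ab), fieldCentre(a_b))

    expect_error(downsampleField(f, 5), "grid")
})

test_that("downsampling preserves rotation-TI minima locations", {
    fx <- makeFixture("rosette", nFold = 5, size = 128)
    angles <- seq(0, 355, by = 5)
    cFull <- tiScan(fx$field, "rotation", angles)
    cDown <- tiScan(downsampleField(fx$field, 4), "rotation", angles)
    mFull <- findSymmetries(cFull, 0.02)
    mDown <- findSymmetries(cDown, 0.02)
    for (a in mFull$param1)
        expect_true(min(abs(mDown$param1 - a)) <= 5)
})

test_that("thresholding produces the expected masks", {
    f <- intensityField(matrix(5, 8, 8))
    expect_equal(sum(maskValues(thresholdMask(f, 10))), 0)
    expect_equal(sum(maskValues(thresholdMask(f, 1))), 64)
})
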