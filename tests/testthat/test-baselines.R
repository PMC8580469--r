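test_that("SI is 0 on mirror masks, 1 on one-sided masks, and in [0,1]", {
    fx <- makeFixture("bilateral_blob", axisAngle = 0, size = 128)
    m <- thresholdMask(fx$field, 100)
    axis <- reflectionSpec(0, c(64.5, 64.5))
    expect_lt(simpleIndicator(m, axis, 10), 1e-6)

    ## mask entirely above the axis
    v <- matrix(0, 32, 32); v[20:28, 5:30] <- 1
    oneSided <- new("BinaryMask", values = v)
    expect_equal(simpleIndicator(oneSided, reflectionSpec(0, c(16.5, 16.5)),
                                 8), 1)

    set.seed(21)
    rnd <- new("BinaryMask", values = matrix(rbinom(1024, 1, 0.4), 32, 32))
    si <- simpleIndicator(rnd, reflectionSpec(30, c(16, 16)), 12)
    expect_gte(si, 0); expect_lte(si, 1)

    expect_error(simpleIndicator(new("BinaryMask",
                                     values = matrix(0, 8, 8)), axis),
                 "empty")
})

test_that("SI on a notched rectangle matches per-pixel band counting", {
    ## 10 wide x 4 tall rectangle, one corner pixel removed on one side
    v <- matrix(0, 16, 20)
    v[6:9, 5:14] <- 1
    v[9, 14] <- 0                      # notch in the top-right corner
    m <- new("BinaryMask", values = v)
    axis <- reflectionSpec(0, c(9.5, 7.5))  # long midline of the rectangle
    n <- 10L

    ## independent oracle: explicit pixel counting per band
    fg <- which(v == 1, arr.ind = TRUE)
    t <- fg[, "col"] - 9.5
    s <- fg[, "row"] - 7.5
    edges <- seq(min(t), max(t), length.out = n + 1)
    band <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1), n)
    expected <- mean(vapply(seq_len(n), function(i) {
        A <- sum(band == i & s > 0); B <- sum(band == i & s < 0)
        abs(A - B) / (A + B)
    }, numeric(1)))

    expect_equal(simpleIndicator(m, axis, n), expected, tolerance = 1e-12)
    expect_gt(expected, 0)
})

test_that("SI is invariant under a joint rigid motion of mask and axis", {
    v <- matrix(0, 32, 32); v[10:20, 8:26] <- 1; v[10, 8:12] <- 0
    m <- new("BinaryMask", values = v)
    ## n = 7 keeps band edges off the half-integer pixel coordinates so
    ## no pixel sits on a knife-edge between bands
    si0 <- simpleIndicator(m, reflectionSpec(0, c(16.5, 15)), 7)
    ## rotate mask and axis by 90 degrees (lattice-exact)
    v90 <- t(v)[, rev(seq_len(32))]
    m90 <- new("BinaryMask", values = v90)
    ## the axis point (16.5, 15) rotates to (18, 16.5)
    si90 <- simpleIndicator(m90, reflectionSpec(90, c(18, 16.5)), 7)
    expect_equal(si90, si0, tolerance = 1e-12)
})

test_that("ZI vanishes exactly at the rotations of a regular n-gon", {
    for (n in c(4, 5, 7)) {
        th <- 2 * pi * (seq_len(n) - 1) / n
        lm <- landmarkSet(cbind(cos(th), sin(th)), c(0, 0))
        expect_identical(ziRotation(lm, 0), 0)
        for (k in seq_len(n - 1))
            expect_lt(ziRotation(lm, 360 * k / n), 1e-24)
        ## off-symmetry angles are strictly positive
        expect_gt(ziRotation(lm, 180 / n), 1e-3)
    }
})

test_that("ZI nearest matching handles ties and ignores labelling", {
    ## two points at (+-1, 0) rotated by 90: each lands equidistant from
    ## both originals at distance^2 = 2, so the sum is 4
    lm <- landmarkSet(rbind(c(1, 0), c(-1, 0)), c(0, 0))
    expect_equal(ziRotation(lm, 90), 4, tolerance = 1e-12)

    set.seed(5)
    pts <- matrix(runif(10, -2, 2), 5, 2)
    a <- ziRotation(landmarkSet(pts, c(0, 0)), 33)
    b <- ziRotation(landmarkSet(pts[sample(5), ], c(0, 0)), 33)
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("landmark CSV import round-trips and validates", {
    tmp <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(x = c(0, 1, 2), y = c(0, 0, 1)), tmp,
              row.names = FALSE)
    lm <- readLandmarks(tmp)
    expect_equal(nrow(lm@points), 3L)
    expect_equal(lm@centre, c(1, 1 / 3))
    bad <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
    expect_error(readLandmarks(bad), "columns")
})
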