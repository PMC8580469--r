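test_that("rosette rotation minima are found, ranked and identity-free", {
    fx <- makeFixture("rosette", nFold = 5, size = 128)
    cur <- tiScan(fx$field, "rotation", angles = seq(0, 359, 1))
    cand <- findSymmetries(cur, 0.02)
    expect_equal(nrow(cand), 4L)
    expect_setequal(cand$param1, c(72, 144, 216, 288))
    expect_false(any(cand$param1 %% 360 == 0))
    expect_true(all(diff(cand$ti) >= 0))      # ranked ascending by TI
    expect_equal(cand$rank, 1:4)
})

test_that("monotone curves yield no candidates and all-NA curves error", {
    cur <- new("TICurve", family = "rotation", param1 = seq(0, 90, 10),
               values = seq(0, 9))
    expect_equal(nrow(findSymmetries(cur)), 0L)
    curNA <- new("TICurve", family = "rotation", param1 = 1:5,
                 values = rep(NA_real_, 5))
    expect_error(findSymmetries(curNA), "undefined")
})

test_that("rotation symmetries outrank reflections for chiral petals", {
    ## one-sided petal lobes kill mirror symmetry but keep the rotations
    fx <- makeFixture("rosette", nFold = 5, asymmetry = 0.6, size = 128)
    rot <- findSymmetries(tiScan(fx$field, "rotation", seq(0, 359, 1)),
                          0.02)
    refl <- tiScan(fx$field, "reflection", seq(0, 179, 1))
    expect_gt(nrow(rot), 0L)
    expect_gt(min(tiValues(refl)), min(rot$ti))
})

test_that("the dTI/dtheta criterion recovers rotation centres", {
    fx <- makeFixture("rosette", nFold = 5, size = 256)
    est <- estimateCenterRotational(fx$field, window = c(97, 160, 97, 160),
                                    nAngles = 12, downsampleFactor = 8)
    expect_true(est@found)
    ## within one downsampled pixel of the true centre (128.5, 128.5)
    expect_lt(max(abs(est@coordinates - c(128.5, 128.5))), 8)

    ## argmax is stable under doubling the intensity (scale covariance)
    f2 <- intensityField(2 * intensityValues(fx$field),
                         centre = fieldCentre(fx$field))
    est2 <- estimateCenterRotational(f2, window = c(97, 160, 97, 160),
                                     nAngles = 12, downsampleFactor = 8)
    expect_equal(est2@coordinates, est@coordinates)
})

test_that("an off-centre rosette shifts the centre estimate with it", {
    fx <- makeFixture("rosette", nFold = 5, size = 128)
    big <- matrix(1, 224, 224)
    big[33:160, 49:176] <- intensityValues(fx$field)   # offset (+48, +32)
    f <- intensityField(big)
    ## window kept inside the petal ring: off the object the overall TI
    ## level dwarfs the angular variation the criterion relies on
    trueCtr <- c(64.5 + 48, 64.5 + 32)
    est <- estimateCenterRotational(f, window = c(trueCtr[1] - 16,
        trueCtr[1] + 16, trueCtr[2] - 16, trueCtr[2] + 16),
        downsampleFactor = 4)
    expect_lte(max(abs(est@coordinates - trueCtr)), 4)
})

test_that("constant fields give a flat criterion and no centre", {
    f <- intensityField(matrix(2, 96, 96))
    estR <- estimateCenterRotational(f, window = c(33, 64, 33, 64),
                                     downsampleFactor = 4)
    expect_false(estR@found)
    estF <- estimateCenterReflection(f, window = c(40, 56, 40, 56))
    expect_false(estF@found)
})

test_that("reflection TI finds the bilateral axis but biases the other coordinate", {
    ## vertical axis: mirror in x is exact, but the leaf profile along the
    ## axis is asymmetric, so the y estimate drifts off the centre
    fx <- makeFixture("bilateral_blob", axisAngle = 90, size = 128)
    est <- estimateCenterReflection(fx$field, window = c(44, 84, 44, 84))
    expect_true(est@found)
    expect_lt(abs(est@coordinates[1] - 64.5), 1)
    expect_gt(abs(est@coordinates[2] - 64.5), 2)
})

test_that("area balance matches a brute-force split scan", {
    ## centred disc: geometric centre
    disc <- (pixelRadius(64) < 20) * 1
    est <- estimateCenterArea(new("BinaryMask", values = disc))
    expect_equal(est@coordinates, c(32.5, 32.5))

    ## single pixel: the balanced split runs through that pixel
    one <- matrix(0, 64, 64); one[10, 42] <- 1
    e1 <- estimateCenterArea(new("BinaryMask", values = one))
    expect_equal(e1@coordinates, c(42, 10))

    ## half-disc vs an independent brute-force oracle over all split
    ## lines (between pixels and through pixels, median of ties)
    half <- disc
    half[, 33:64] <- 0
    bruteSplit <- function(counts) {
        n <- length(counts)
        pos <- seq(1, n, by = 0.5)
        imb <- vapply(pos, function(p) {
            left <- 0; right <- 0
            for (j in seq_len(n)) {
                if (j < p) left <- left + counts[j]
                if (j > p) right <- right + counts[j]
            }
            abs(left - right)
        }, numeric(1))
        median(pos[imb == min(imb)])
    }
    eh <- estimateCenterArea(new("BinaryMask", values = half))
    expect_equal(eh@coordinates[1], bruteSplit(colSums(half)))
    expect_equal(eh@coordinates[2], bruteSplit(rowSums(half)))
    expect_error(estimateCenterArea(new("BinaryMask",
                                        values = matrix(0, 4, 4))),
                 "empty")
})

test_that("bilateral axis search recovers construction angles, agreeing with SI", {
    fx0 <- makeFixture("bilateral_blob", axisAngle = 0, size = 128)
    s0 <- bilateralAxisSearch(fx0$field, step = 0.5)
    expect_lt(abs(s0$bestAngle - 0), 0.5 + 1e-9)

    fx <- makeFixture("bilateral_blob", axisAngle = 4.5, size = 128)
    s <- bilateralAxisSearch(fx$field, step = 0.5)
    expect_lt(abs(s$bestAngle - 4.5), 0.5 + 1e-9)

    ## the area-based Simple Indicator picks the same axis angle
    m <- thresholdMask(fx$field, 100)
    angles <- seq(-10, 20, by = 0.5)
    si <- vapply(angles, function(a)
        simpleIndicator(m, reflectionSpec(a, fieldCentre(fx$field)), 20),
        numeric(1))
    expect_lt(abs(angles[which.min(si)] - s$bestAngle), 0.5 + 1e-9)
})
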