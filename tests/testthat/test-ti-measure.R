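## independent scalar reference: TI of a periodic integer shift by
## explicit per-pixel loops, no shared code with translationTI
referenceShiftTI <- function(v, sx, sy) {
    nr <- nrow(v); nc <- ncol(v)
    acc <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        ip <- ((i - 1 - sy) %% nr) + 1
        jp <- ((j - 1 - sx) %% nc) + 1
        acc <- acc + v[i, j] * log(v[i, j] / v[ip, jp])
    }
    acc / (nr * nc)
}

test_that("TI matches the hand-evaluated quadrature on a 2x2 field", {
    v <- matrix(c(2, 1, 1, 1), 2, 2, byrow = TRUE)
    f <- intensityField(v)
    tc <- translationTI(f, method = "direct")
    ## on the centred 2-grid the +1 shift is reported as -1 (period 2)
    got <- tiValues(tc)[tiParams(tc)$param1 == -1, tiParams(tc)$param2 == 0]
    ## (1/4)(2 ln 2 + ln(1/2)) = ln(2)/4
    expect_equal(got, log(2) / 4, tolerance = 1e-14)
    expect_equal(got, referenceShiftTI(v, 1, 0), tolerance = 1e-14)
})

test_that("identity and symmetric transforms give exactly zero TI", {
    f <- roughTestField(12, seed = 2)
    expect_identical(transformationInformation(f, identitySpec()), 0)
    tc <- translationTI(f)
    z <- tiValues(tc)[tiParams(tc)$param1 == 0, tiParams(tc)$param2 == 0]
    expect_identical(z, 0)

    cf <- intensityField(matrix(3.7, 16, 16))
    expect_equal(transformationInformation(cf, rotationSpec(123)), 0,
                 tolerance = 1e-12)
})

test_that("TI is scale covariant: TI(c*mu) = c*TI(mu)", {
    f <- smoothTestField(48, seed = 9)
    sp <- rotationSpec(40)
    base <- transformationInformation(f, sp)
    for (cc in c(0.25, 3, 117)) {
        fc <- intensityField(cc * intensityValues(f),
                             centre = fieldCentre(f))
        expect_equal(transformationInformation(fc, sp), cc * base,
                     tolerance = 1e-12)
    }
})

test_that("FFT translation TI equals direct summation and the oracle", {
    f <- roughTestField(64, seed = 11)
    d <- translationTI(f, "direct")
    h <- translationTI(f, "fft")
    expect_equal(tiValues(h), tiValues(d),
                 tolerance = 1e-9)
    ## spot-check a few shifts against the scalar reference
    v <- intensityValues(f)
    p <- tiParams(h)
    for (s in list(c(3, 5), c(-7, 2), c(0, 9))) {
        got <- tiValues(h)[p$param1 == s[1], p$param2 == s[2]]
        expect_equal(got, referenceShiftTI(v, s[1], s[2]),
                     tolerance = 1e-9)
    }
})

test_that("periodic shifts keep TI non-negative and obey the role swap", {
    f <- roughTestField(10, seed = 3)
    tc <- translationTI(f, "direct")
    ## equal-mass periodic shifts: log-sum inequality forces TI >= 0
    expect_gte(min(tiValues(tc)), -1e-12)

    ## exchanging mu and T(mu) at shift s equals TI at -s
    v <- intensityValues(f)
    p <- tiParams(tc)
    for (s in list(c(2, 3), c(-4, 1))) {
        shifted <- v[((seq_len(10) - 1 - s[2]) %% 10) + 1,
                     ((seq_len(10) - 1 - s[1]) %% 10) + 1]
        swapped <- mean(shifted * log(shifted / v))
        atMinus <- tiValues(tc)[p$param1 == -s[1], p$param2 == -s[2]]
        expect_equal(swapped, atMinus, tolerance = 1e-12)
    }
})

test_that("reflection TI is exchange-symmetric when the domain maps onto itself", {
    ## odd-size grid, axis along the middle row: exact lattice mapping
    set.seed(8)
    v <- matrix(runif(81, 1, 3), 9, 9)
    f <- intensityField(v)
    sp <- reflectionSpec(0, c(5, 5))
    fRef <- intensityField(v[rev(seq_len(9)), ], centre = c(5, 5))
    expect_equal(transformationInformation(f, sp),
                 transformationInformation(fRef, sp), tolerance = 1e-12)
})

test_that("tiScan records empty-overlap grid points as NA", {
    f <- smoothTestField(64, seed = 1)
    cur <- tiScan(f, "rotation_scale", angles = c(0, 45),
                  scales = c(1e-4, 1))
    v <- tiValues(cur)
    expect_true(all(is.na(v[, 1])))          # collapse to a point: empty
    expect_equal(v[1, 2], 0, tolerance = 1e-12)   # identity on the grid
    expect_true(is.finite(v[2, 2]))
})

test_that("difference maps vanish for exact symmetries and spike at antiphase", {
    fx <- makeFixture("rosette", nFold = 5, size = 128)
    rng <- diff(range(intensityValues(fx$field)))

    dm0 <- differenceMap(fx$field, identitySpec())
    expect_equal(max(abs(dm0@values), na.rm = TRUE), 0)

    dmSym <- differenceMap(fx$field, fx$truth[[1]])
    expect_lt(max(abs(dmSym@values), na.rm = TRUE), 0.02 * rng)

    dmAnti <- differenceMap(fx$field,
                            rotationSpec(36, fieldCentre(fx$field)))
    expect_gt(max(abs(dmAnti@values), na.rm = TRUE), 0.5 * rng)
})

test_that("TICurve coercion and CSV round-trip preserve values", {
    f <- roughTestField(8)
    cur <- tiScan(f, "rotation", angles = c(0, 90, 180, 270))
    df <- as.data.frame(cur)
    expect_equal(df$ti, as.numeric(tiValues(cur)))
    tmp <- withr::local_tempfile(fileext = ".csv")
    writeTICurve(cur, tmp)
    back <- read.csv(tmp)
    expect_equal(back$ti, df$ti, tolerance = 1e-12)
})
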