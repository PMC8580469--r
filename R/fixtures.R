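#' Generate synthetic images with known ground-truth symmetries
#'
#' Renders smooth (Gaussian-edged) test patterns whose exact symmetries are
#' known by construction, emulating the specimen classes the package's
#' analyses target: an n-fold rosette of petals (flowers, radial Turing
#' patterns), a bilateral leaf-like blob with a single mirror axis, a
#' regular-pentagon landmark set (pentamerous flower petal tips), a
#' decussate whorl with discrete rotation-rescale self-similarity
#' (stem cross-section with opposite leaf pairs), and a plane wave
#' (periodic stripes). Soft edges keep interpolation error from dominating
#' TI near the exact symmetries. Seeded uniform pixel noise can be added
#' after construction.
#'
#' Fixture geometry by kind:
#' \describe{
#'   \item{rosette}{\code{nFold} Gaussian petals equally spaced on a ring;
#'     \code{asymmetry > 0} adds a one-sided tangential lobe to every petal,
#'     preserving the n-fold rotations but destroying all reflections.
#'     Truth: rotations by 360k/nFold.}
#'   \item{bilateral_blob}{a leaf-like blob, mirror-symmetric about the
#'     axis through the centre at \code{axisAngle}, with a pointed tip and
#'     round base along the axis so no other symmetry survives. Truth: that
#'     one reflection.}
#'   \item{pentagon_landmarks}{five Gaussian dots at the vertices of a
#'     regular pentagon; the returned \code{landmarks} slot carries the
#'     exact coordinates. Truth: rotations by 72k.}
#'   \item{decussate_whorl}{\code{nLevels} levels of opposite leaf pairs,
#'     level l rotated by \code{l*levelRotation} and shrunk by
#'     \code{levelScale^l}. Truth: rotation-rescale by
#'     (levelRotation, levelScale) and (2*levelRotation, levelScale^2).}
#'   \item{plane_wave}{sinusoidal stripes of wavelength \code{wavelength}
#'     pixels along x. Truth: periodic translations by one wavelength.}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param size image edge, pixels (>= 64).
#' @param nFold rotation order of the rosette.
#' @param axisAngle bilateral axis angle, degrees from horizontal.
#' @param asymmetry one-sided petal lobe amplitude in [0, 1].
#' @param levelRotation,levelScale,nLevels whorl parameters.
#' @param wavelength plane-wave wavelength, pixels.
#' @param noiseAmplitude uniform pixel noise amplitude as a fraction of the
#'   noiseless dynamic range.
#' @param seed RNG seed for the noise.
#' @return a list with \code{field} (an \linkS4class{IntensityField}),
#'   \code{truth} (list of exact-symmetry \linkS4class{TransformSpec}s),
#'   and \code{landmarks} (a \linkS4class{LandmarkSet}, pentagon kind only,
#'   else NULL).
#' @examples
#' fx <- makeFixture("rosette", nFold = 5, size = 96)
#' transformationInformation(fx$field, fx$truth[[1]])  # ~0
#' @export
makeFixture <- function(kind = c("rosette", "bilateral_blob",
                                 "pentagon_landmarks", "decussate_whorl",
                                 "plane_wave"),
                        size = 128L, nFold = 5L, axisAngle = 0,
                        asymmetry = 0, levelRotation = 90,
                        levelScale = 0.6, nLevels = 4L, wavelength = 16,
                        noiseAmplitude = 0, seed = 1L) {
    kind <- match.arg(kind)
    size <- as.integer(size)
    if (size < 64L) stop("size must be at least 64 pixels")
    ctr <- c((size + 1) / 2, (size + 1) / 2)
    x <- matrix(rep(seq_len(size), each = size), size, size) - ctr[1]
    y <- matrix(rep(seq_len(size), times = size), size, size) - ctr[2]
    gauss <- function(cx, cy, sx, sy = sx, th = 0) {
        ## anisotropic Gaussian, principal axis at th degrees
        t <- th * pi / 180
        dx <- x - cx; dy <- y - cy
        a <- cos(t) * dx + sin(t) * dy
        b <- -sin(t) * dx + cos(t) * dy
        exp(-(a^2 / (2 * sx^2) + b^2 / (2 * sy^2)))
    }
    truth <- list()
    landmarks <- NULL
    v <- matrix(0, size, size)

    if (kind == "rosette") {
        stopifnot(nFold >= 2L)
        R <- 0.30 * size; sig <- 0.07 * size
        for (k in seq_len(nFold) - 1L) {
            th <- 2 * pi * k / nFold
            v <- v + gauss(R * cos(th), R * sin(th), sig)
            if (asymmetry > 0) {
                thl <- th + 0.45 * (2 * pi / nFold)
                v <- v + asymmetry *
                    gauss(0.8 * R * cos(thl), 0.8 * R * sin(thl), 0.6 * sig)
            }
        }
        truth <- lapply(360 * seq_len(nFold - 1L) / nFold,
                        function(a) rotationSpec(a, ctr))
    } else if (kind == "bilateral_blob") {
        ## leaf in the axis frame: t along the axis, s across it
        phi <- axisAngle * pi / 180
        t <- cos(phi) * x + sin(phi) * y
        s <- -sin(phi) * x + cos(phi) * y
        len <- 0.32 * size
        tt <- t / len
        ## asymmetric width profile (round base at tt < 0, tapered tip at
        ## tt > 0) kept smooth and wide so interpolation error stays small
        w <- 0.14 * size * (1 - 0.35 * tanh(2 * tt))
        v <- exp(-s^2 / (2 * w^2)) * exp(-tt^2 / (2 * 0.45^2))
        truth <- list(reflectionSpec(axisAngle, ctr))
    } else if (kind == "pentagon_landmarks") {
        R <- 0.35 * size
        th <- pi / 2 + 2 * pi * (0:4) / 5
        pts <- cbind(ctr[1] + R * cos(th), ctr[2] + R * sin(th))
        for (i in 1:5) v <- v + gauss(pts[i, 1] - ctr[1], pts[i, 2] - ctr[2],
                                      0.03 * size)
        landmarks <- landmarkSet(pts, centre = ctr)
        truth <- lapply(c(72, 144, 216, 288),
                        function(a) rotationSpec(a, ctr))
    } else if (kind == "decussate_whorl") {
        stopifnot(nLevels >= 2L, levelScale > 0, levelScale < 1)
        ## compact leaves: the outermost pair sits outside the
        ## rotation-rescale overlap domain, so its inward Gaussian tail
        ## must decay before reaching it or the tail dominates TI there
        R0 <- 0.38 * size
        for (l in seq_len(nLevels) - 1L) {
            sc <- levelScale^l
            thl <- (90 + l * levelRotation) * pi / 180
            for (side in c(0, pi)) {
                cx <- R0 * sc * cos(thl + side)
                cy <- R0 * sc * sin(thl + side)
                v <- v + gauss(cx, cy, 0.05 * size * sc, 0.018 * size * sc,
                               th = (thl + side) * 180 / pi)
            }
        }
        truth <- list(
            rotationScaleSpec(levelRotation, levelScale, ctr),
            rotationScaleSpec(2 * levelRotation, levelScale^2, ctr))
    } else if (kind == "plane_wave") {
        v <- cos(2 * pi * x / wavelength)
        truth <- list(translationSpec(c(wavelength, 0), "periodic"))
    }

    rng <- diff(range(v))
    if (rng == 0) rng <- 1
    if (noiseAmplitude > 0) {
        set.seed(as.integer(seed))
        v <- v + matrix(stats::runif(size^2, -1, 1), size, size) *
                 noiseAmplitude * rng
    }
    ## positive field on a 0-255-like scale with a quiet background
    field <- ensurePositive(1 + 200 * (v - min(v)) / rng, floor = 1,
                            centre = ctr, provenance = "fixture")
    list(field = field, truth = truth, landmarks = landmarks)
}

#' Construct a LandmarkSet
#'
#' @param points n-by-2 matrix or data.frame of \code{(x, y)} coordinates.
#' @param centre rotation centre \code{c(x, y)}.
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(points, centre = c(0, 0)) {
    pts <- as.matrix(points)
    colnames(pts) <- c("x", "y")
    new("LandmarkSet", points = pts, centre = as.numeric(centre))
}

#' Read landmarks from CSV
#'
#' Expects a header with columns \code{x} and \code{y} (e.g. manually
#' digitized petal tips).
#'
#' @param path CSV path.
#' @param centre rotation centre; NULL for the landmark centroid.
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path, centre = NULL) {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
        stop("landmark CSV must have columns 'x' and 'y'")
    if (is.null(centre)) centre <- c(mean(df$x), mean(df$y))
    landmarkSet(cbind(df$x, df$y), centre)
}
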