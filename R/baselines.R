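#' Simple Indicator of bilateral asymmetry
#'
#' The area-based baseline measure for bilateral symmetry: the object mask
#' is cut into \code{n} equal-width bands orthogonal to the reflection
#' axis, spanning the object's extent along the axis; within band i the
#' foreground areas on the two sides of the axis are \code{A[i]} and
#' \code{B[i]}, and
#' \deqn{SI = \frac{1}{n} \sum_i \frac{|A_i - B_i|}{A_i + B_i}.}
#' SI is 0 for a mask mirror-symmetric about the axis and 1 for a mask
#' lying entirely on one side; bands containing no foreground are excluded
#' from the mean. Pixels whose centres fall exactly on the axis belong to
#' neither side.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param axis a reflection \linkS4class{TransformSpec} defining the axis
#'   (its angle and axis point).
#' @param n number of bands (default 20).
#' @return a single numeric value in [0, 1].
#' @export
simpleIndicator <- function(mask, axis, n = 20L) {
    stopifnot(is(mask, "BinaryMask"), is(axis, "TransformSpec"),
              axis@family == "reflection", n >= 1L)
    v <- mask@values
    fg <- which(v == 1, arr.ind = TRUE)
    if (nrow(fg) == 0L) stop("empty mask")
    a <- axis@axisPoint
    if (any(is.na(a))) a <- c((ncol(v) + 1) / 2, (nrow(v) + 1) / 2)
    phi <- axis@angle * pi / 180
    dx <- fg[, "col"] - a[1]; dy <- fg[, "row"] - a[2]
    t <- cos(phi) * dx + sin(phi) * dy     # along the axis
    s <- -sin(phi) * dx + cos(phi) * dy    # signed offset across the axis
    tol <- 1e-9
    edges <- seq(min(t), max(t), length.out = n + 1L)
    band <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1L), n)
    A <- tapply(s > tol, band, sum)
    B <- tapply(s < -tol, band, sum)
    tot <- A + B
    keep <- tot > 0
    if (!any(keep)) stop("mask lies entirely on the axis")
    mean(abs(A[keep] - B[keep]) / tot[keep])
}

#' Landmark-based rotation asymmetry (ZI)
#'
#' The landmark baseline for rotational symmetry: all landmarks are
#' rotated about the centre by the given angle and each rotated point is
#' matched to its nearest original landmark (ties break by first index);
#' the measure is the sum of squared Euclidean distances of the matched
#' pairs. It is zero exactly at the rotations mapping the landmark set
#' onto itself, and is invariant under relabelling of the landmarks.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param angle rotation angle, degrees counterclockwise.
#' @return a single numeric value.
#' @export
ziRotation <- function(landmarks, angle) {
    stopifnot(is(landmarks, "LandmarkSet"))
    p <- landmarks@points
    ctr <- landmarks@centre
    th <- angle * pi / 180
    dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
    q <- cbind(ctr[1] + cos(th) * dx - sin(th) * dy,
               ctr[2] + sin(th) * dx + cos(th) * dy)
    d2 <- outer(q[, 1], p[, 1], "-")^2 + outer(q[, 2], p[, 2], "-")^2
    sum(apply(d2, 1, min))
}

#' ZI over a grid of rotation angles
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param angles angle grid, degrees.
#' @return a data.frame with columns \code{angle, zi}.
#' @export
ziCurve <- function(landmarks, angles) {
    data.frame(angle = angles,
               zi = vapply(angles, function(a) ziRotation(landmarks, a),
                           numeric(1)))
}
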