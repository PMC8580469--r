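#' Transform constructors
#'
#' Helpers building validated \linkS4class{TransformSpec} objects for each
#' family. Angles are degrees counterclockwise; points are in pixel units of
#' the field the spec will be applied to; translation shifts are in physical
#' units. A centre or axis point of \code{NA} resolves to the field's centre
#' at application time.
#'
#' @param angle rotation angle, or reflection-axis angle from horizontal
#'   (degrees).
#' @param centre rotation/scaling origin \code{c(x, y)} in pixel units.
#' @param axisPoint a point the reflection axis passes through.
#' @param shift translation vector \code{c(sx, sy)} in physical units.
#' @param scale isotropic rescale factor (rotation_scale only).
#' @param boundary \code{"crop_intersect"} (default) or \code{"periodic"}
#'   (translation only).
#' @return a \linkS4class{TransformSpec}.
#' @name transform-constructors
NULL

#' @rdname transform-constructors
#' @export
identitySpec <- function() new("TransformSpec", family = "identity")

#' @rdname transform-constructors
#' @export
rotationSpec <- function(angle, centre = c(NA, NA)) {
    new("TransformSpec", family = "rotation", angle = angle,
        centre = as.numeric(centre))
}

#' @rdname transform-constructors
#' @export
reflectionSpec <- function(angle, axisPoint = c(NA, NA)) {
    new("TransformSpec", family = "reflection", angle = angle,
        axisPoint = as.numeric(axisPoint))
}

#' @rdname transform-constructors
#' @export
translationSpec <- function(shift, boundary = c("crop_intersect", "periodic")) {
    new("TransformSpec", family = "translation", shift = as.numeric(shift),
        boundary = match.arg(boundary))
}

#' @rdname transform-constructors
#' @export
rotationScaleSpec <- function(angle, scale, centre = c(NA, NA)) {
    new("TransformSpec", family = "rotation_scale", angle = angle,
        scale = scale, centre = as.numeric(centre))
}

.resolveCentre <- function(point, field) {
    if (any(is.na(point))) field@centre else point
}

## Pre-image coordinates of every output pixel under the spec's inverse map.
## Returns list(px, py) as nrow x ncol matrices of pixel coordinates.
.preimageCoords <- function(field, spec) {
    v <- field@values
    nr <- nrow(v); nc <- ncol(v)
    x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    switch(spec@family,
        identity = list(px = x, py = y),
        rotation = {
            ctr <- .resolveCentre(spec@centre, field)
            th <- -spec@angle * pi / 180
            dx <- x - ctr[1]; dy <- y - ctr[2]
            list(px = ctr[1] + cos(th) * dx - sin(th) * dy,
                 py = ctr[2] + sin(th) * dx + cos(th) * dy)
        },
        reflection = {
            a <- .resolveCentre(spec@axisPoint, field)
            phi <- spec@angle * pi / 180
            c2 <- cos(2 * phi); s2 <- sin(2 * phi)
            dx <- x - a[1]; dy <- y - a[2]
            list(px = a[1] + c2 * dx + s2 * dy,
                 py = a[2] + s2 * dx - c2 * dy)
        },
        translation = {
            spx <- spec@shift / field@pixelSize
            list(px = x - spx[1], py = y - spx[2])
        },
        rotation_scale = {
            ctr <- .resolveCentre(spec@centre, field)
            th <- -spec@angle * pi / 180
            dx <- (x - ctr[1]) / spec@scale
            dy <- (y - ctr[2]) / spec@scale
            list(px = ctr[1] + cos(th) * dx - sin(th) * dy,
                 py = ctr[2] + sin(th) * dx + cos(th) * dy)
        },
        stop("unknown family: ", spec@family))
}

## Snap coordinates within 1e-9 px of an integer onto it, so that
## lattice transforms (90-degree rotations, integer shifts) are exact
## despite trigonometric roundoff.
.snapLattice <- function(p) {
    r <- round(p)
    near <- abs(p - r) < 1e-9
    p[near] <- r[near]
    p
}

## Bilinear sampling of matrix v at pixel coordinates (px, py).
## A sample is defined only when every interpolation neighbour it actually
## uses lies inside the grid, so interpolated values never touch undefined
## data (a pixel with fractional pre-image needs all four neighbours).
.bilinearSample <- function(v, px, py) {
    nr <- nrow(v); nc <- ncol(v)
    px <- .snapLattice(px); py <- .snapLattice(py)
    j0 <- floor(px); i0 <- floor(py)
    fx <- px - j0; fy <- py - i0
    defined <- j0 >= 1 & i0 >= 1 &
               (j0 + (fx > 0)) <= nc & (i0 + (fy > 0)) <= nr
    out <- matrix(NA_real_, nr, nc)
    idx <- which(defined)
    if (length(idx)) {
        i0i <- i0[idx]; j0i <- j0[idx]
        fxi <- fx[idx]; fyi <- fy[idx]
        j1 <- pmin(j0i + 1L, nc); i1 <- pmin(i0i + 1L, nr)
        v00 <- v[cbind(i0i, j0i)]; v01 <- v[cbind(i0i, j1)]
        v10 <- v[cbind(i1, j0i)]; v11 <- v[cbind(i1, j1)]
        out[idx] <- (1 - fyi) * ((1 - fxi) * v00 + fxi * v01) +
                    fyi * ((1 - fxi) * v10 + fxi * v11)
    }
    list(values = out, defined = defined)
}

## Periodic bilinear sampling (translation with periodic boundary).
.bilinearSamplePeriodic <- function(v, px, py) {
    nr <- nrow(v); nc <- ncol(v)
    px <- .snapLattice(px); py <- .snapLattice(py)
    j0 <- floor(px); i0 <- floor(py)
    fx <- px - j0; fy <- py - i0
    w <- function(i, n) ((i - 1) %% n) + 1
    v00 <- v[cbind(w(i0, nr), w(j0, nc))]
    v01 <- v[cbind(w(i0, nr), w(j0 + 1, nc))]
    v10 <- v[cbind(w(i0 + 1, nr), w(j0, nc))]
    v11 <- v[cbind(w(i0 + 1, nr), w(j0 + 1, nc))]
    out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
           fy * ((1 - fx) * v10 + fx * v11)
    dim(out) <- dim(v)
    list(values = out, defined = matrix(TRUE, nr, nc))
}

#' Apply a transformation to an intensity field
#'
#' Resamples the field under the inverse map of the spec (bilinear
#' interpolation), marking pixels whose pre-image falls outside the grid as
#' undefined rather than zero-filling them. The overlap domain is the set
#' of pixels where both the original field and the transformed field are
#' defined; under a periodic translation it is the whole grid.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param spec a \linkS4class{TransformSpec}.
#' @return a list with \code{values} (transformed intensities, NA outside
#'   the overlap), \code{overlap} (logical matrix marking the overlap
#'   domain), and \code{area} (overlap area in physical units).
#' @export
applyTransform <- function(field, spec) {
    stopifnot(is(field, "IntensityField"), is(spec, "TransformSpec"))
    validObject(spec)
    v <- field@values
    if (spec@family == "translation" && spec@boundary == "periodic") {
        spx <- spec@shift / field@pixelSize
        if (all(abs(spx - round(spx)) < 1e-12)) {
            spx <- round(spx)
            nr <- nrow(v); nc <- ncol(v)
            ri <- ((seq_len(nr) - 1 - spx[2]) %% nr) + 1
            ci <- ((seq_len(nc) - 1 - spx[1]) %% nc) + 1
            smp <- list(values = v[ri, ci, drop = FALSE],
                        defined = matrix(TRUE, nr, nc))
        } else {
            co <- .preimageCoords(field, spec)
            smp <- .bilinearSamplePeriodic(v, co$px, co$py)
        }
    } else {
        co <- .preimageCoords(field, spec)
        smp <- .bilinearSample(v, co$px, co$py)
    }
    area <- sum(smp$defined) * field@pixelSize^2
    if (area == 0)
        stop("empty overlap: the transform maps the field entirely outside ",
             "its own domain")
    list(values = smp$values, overlap = smp$defined, area = area)
}
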