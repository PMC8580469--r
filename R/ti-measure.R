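#' Transformation Information of a field/transform pair
#'
#' The central measure of the package: for a strictly positive intensity
#' field mu and a transformation T, the Transformation Information is the
#' Kullback-Leibler-type divergence
#' \deqn{TI = \frac{1}{|\tilde D|} \int_{\tilde D} \mu(x)
#'   \ln\frac{\mu(x)}{T\mu(x)}\, dA,}
#' where the overlap domain \eqn{\tilde D} is the intersection of the
#' original and transformed image domains. TI is zero exactly when the
#' transform leaves the field invariant on the overlap; local minima of TI
#' over a transformation family are approximate symmetries. The discrete
#' quadrature is the midpoint rule (pixel sum times pixel area), which
#' reduces to the mean over overlap pixels of
#' \code{mu * log(mu / Tmu)}.
#'
#' TI scales covariantly with intensity: \code{TI(c*mu, T) = c*TI(mu, T)}
#' for constant \code{c > 0}, since the constant cancels inside the
#' logarithm. The optional \code{normalize} flag divides by the mean of mu
#' on the overlap so that fields of different overall intensity are
#' comparable; it is off by default, matching the raw definition.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param spec a \linkS4class{TransformSpec}.
#' @param normalize logical; normalize mean intensity on the overlap to 1.
#' @return a single numeric TI value.
#' @examples
#' f <- intensityField(matrix(c(2, 1, 1, 1), 2, 2))
#' transformationInformation(f, identitySpec())  # exactly 0
#' @export
transformationInformation <- function(field, spec, normalize = FALSE) {
    at <- applyTransform(field, spec)
    idx <- at$overlap
    mu <- field@values[idx]
    tmu <- at$values[idx]
    ti <- mean(mu * log(mu / tmu))
    if (normalize) ti <- ti / mean(mu)
    ti
}

#' Scan TI over a grid of transformation parameters
#'
#' Evaluates \code{\link{transformationInformation}} over a 1-D grid
#' (rotation angle; reflection-axis angle) or a 2-D grid (rotation angle by
#' rescale factor). Grid points whose overlap with the original field is
#' empty are recorded as NA, never as zero.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param family \code{"rotation"}, \code{"reflection"} or
#'   \code{"rotation_scale"}.
#' @param angles angle grid, degrees.
#' @param scales rescale-factor grid (rotation_scale only).
#' @param centre rotation centre / axis point; NULL for the field centre.
#' @param normalize passed to \code{\link{transformationInformation}}.
#' @return a \linkS4class{TICurve}.
#' @export
tiScan <- function(field, family = c("rotation", "reflection",
                                     "rotation_scale"),
                   angles, scales = NULL, centre = NULL,
                   normalize = FALSE) {
    family <- match.arg(family)
    stopifnot(length(angles) >= 1L)
    if (is.null(centre)) centre <- field@centre
    evalTI <- function(spec) {
        tryCatch(transformationInformation(field, spec, normalize = normalize),
                 error = function(e) NA_real_)
    }
    if (family == "rotation_scale") {
        stopifnot(!is.null(scales))
        vals <- matrix(NA_real_, length(angles), length(scales))
        for (i in seq_along(angles)) for (j in seq_along(scales))
            vals[i, j] <- evalTI(rotationScaleSpec(angles[i], scales[j],
                                                   centre))
        return(new("TICurve", family = family, param1 = as.numeric(angles),
                   param2 = as.numeric(scales), values = vals,
                   centre = centre, pixelSize = field@pixelSize))
    }
    mk <- if (family == "rotation") {
        function(a) rotationSpec(a, centre)
    } else {
        function(a) reflectionSpec(a, centre)
    }
    vals <- vapply(angles, function(a) evalTI(mk(a)), numeric(1))
    new("TICurve", family = family, param1 = as.numeric(angles),
        values = vals, centre = centre, pixelSize = field@pixelSize)
}

#' Scan reflection TI over axis offsets at fixed axis angle
#'
#' Moves the reflection axis perpendicular to itself through a range of
#' offsets from a reference point, at a fixed axis angle, and records TI at
#' each position. Used to locate a bilateral axis (offset scan at angle 90
#' finds the vertical axis x-position).
#'
#' @param field an \linkS4class{IntensityField}.
#' @param angle axis angle from horizontal, degrees.
#' @param offsets perpendicular offsets from \code{centre}, pixel units.
#' @param centre reference point; NULL for the field centre.
#' @return a \linkS4class{TICurve} with \code{param1 = offsets}.
#' @export
reflectionOffsetScan <- function(field, angle, offsets, centre = NULL) {
    if (is.null(centre)) centre <- field@centre
    phi <- angle * pi / 180
    perp <- c(-sin(phi), cos(phi))
    vals <- vapply(offsets, function(d) {
        pt <- centre + d * perp
        tryCatch(transformationInformation(field, reflectionSpec(angle, pt)),
                 error = function(e) NA_real_)
    }, numeric(1))
    new("TICurve", family = "reflection_offset",
        param1 = as.numeric(offsets), values = vals, centre = centre,
        pixelSize = field@pixelSize)
}

#' Periodic translation TI map
#'
#' TI as a function of translation over all integer-pixel shifts of a
#' periodically extended field. The overlap domain is the full grid for
#' every shift, so
#' \code{TI(s) = mean(mu*log(mu)) - mean(mu(x)*log(mu(x-s)))}.
#' The default path evaluates all shifts at once by FFT circular
#' cross-correlation of mu with log(mu); \code{method = "direct"} is the
#' reference per-shift summation (quadratic cost, small grids only). The
#' zero-shift entry is the identity transformation and is exactly 0.
#'
#' @param field an \linkS4class{IntensityField} on a periodic domain.
#' @param method \code{"fft"} or \code{"direct"}.
#' @return a \linkS4class{TICurve}, family \code{"translation"}, with
#'   \code{param1} the x-shift grid and \code{param2} the y-shift grid in
#'   physical units (fftshift-centred so shift 0 is in the interior), and
#'   \code{values[ix, iy]} the TI at shift \code{(param1[ix], param2[iy])}.
#' @export
translationTI <- function(field, method = c("fft", "direct")) {
    method <- match.arg(method)
    mu <- field@values
    g <- log(mu)
    nr <- nrow(mu); nc <- ncol(mu)
    m0 <- mean(mu * g)
    if (method == "fft") {
        h <- Re(fft(fft(mu) * Conj(fft(g)), inverse = TRUE)) / (nr * nc)
        ti <- m0 - h / (nr * nc)          # ti[1 + sy, 1 + sx]
    } else {
        ti <- matrix(0, nr, nc)
        for (sy in 0:(nr - 1)) {
            ri <- ((seq_len(nr) - 1 - sy) %% nr) + 1
            for (sx in 0:(nc - 1)) {
                ci <- ((seq_len(nc) - 1 - sx) %% nc) + 1
                ti[sy + 1, sx + 1] <- m0 - mean(mu * g[ri, ci])
            }
        }
    }
    ti[1, 1] <- 0   # identity transformation, exact by definition
    ## centre the shift axes: sx = -floor(nc/2) .. ceiling(nc/2)-1
    sx <- seq_len(nc) - 1L; sx[sx >= ceiling(nc / 2)] <- sx[sx >= ceiling(nc / 2)] - nc
    sy <- seq_len(nr) - 1L; sy[sy >= ceiling(nr / 2)] <- sy[sy >= ceiling(nr / 2)] - nr
    ox <- order(sx); oy <- order(sy)
    ti <- ti[oy, ox, drop = FALSE]
    ## values[ix, iy]: transpose so rows follow shift-x
    new("TICurve", family = "translation",
        param1 = sx[ox] * field@pixelSize,
        param2 = sy[oy] * field@pixelSize,
        values = t(ti), centre = field@centre, pixelSize = field@pixelSize)
}

#' Signed difference between a transformed field and the original
#'
#' \code{Tmu - mu} restricted to the overlap domain (NA outside); positive
#' where the transformed image is more intense. The map is identically zero
#' when the transform is an exact symmetry of the field.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param spec a \linkS4class{TransformSpec}.
#' @return a \linkS4class{DifferenceMap}.
#' @export
differenceMap <- function(field, spec) {
    at <- applyTransform(field, spec)
    vals <- at$values - field@values
    vals[!at$overlap] <- NA_real_
    new("DifferenceMap", values = vals, overlap = at$overlap, area = at$area)
}

#' Coerce a TICurve to a data.frame
#'
#' 1-D curves give columns \code{parameter, ti}; 2-D scans give the long
#' form \code{param1, param2, ti}.
#'
#' @param x a \linkS4class{TICurve}.
#' @param ... ignored.
#' @export
as.data.frame.TICurve <- function(x, ...) {
    if (length(x@param2) == 0L) {
        data.frame(parameter = x@param1, ti = as.numeric(x@values))
    } else {
        data.frame(param1 = rep(x@param1, times = length(x@param2)),
                   param2 = rep(x@param2, each = length(x@param1)),
                   ti = as.numeric(x@values))
    }
}

#' Write a TICurve to CSV
#'
#' @param curve a \linkS4class{TICurve}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTICurve <- function(curve, path) {
    utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
    invisible(path)
}
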