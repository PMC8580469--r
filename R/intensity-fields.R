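#' Construct an IntensityField
#'
#' Wraps a positive matrix as an \linkS4class{IntensityField}. The centre
#' defaults to the geometric centre of the grid,
#' \code{((ncol+1)/2, (nrow+1)/2)} in the pixel-centre convention.
#'
#' @param values numeric matrix, strictly positive.
#' @param pixelSize physical length per pixel.
#' @param centre rotation/reflection origin \code{c(x, y)}; NULL for the
#'   geometric centre.
#' @param provenance provenance tag.
#' @return an \linkS4class{IntensityField}.
#' @export
intensityField <- function(values, pixelSize = 1, centre = NULL,
                           provenance = "fixture") {
    values <- as.matrix(values)
    if (is.null(centre))
        centre <- c((ncol(values) + 1) / 2, (nrow(values) + 1) / 2)
    new("IntensityField", values = values, pixelSize = pixelSize,
        centre = as.numeric(centre), provenance = provenance)
}

#' Clamp a raw intensity grid to a strictly positive field
#'
#' TI takes a logarithm of intensity ratios, so zeros and negative values
#' (which arise e.g. from the signed greenness construction) must be
#' replaced before any TI computation. Every value below \code{floor} is
#' raised to \code{floor}; the operation is idempotent.
#'
#' @param raw numeric matrix (may contain zeros/negatives, not NA/Inf).
#' @param floor positive clamp level. The default 1 is the natural unit on
#'   the 0--255 image intensity scale.
#' @param pixelSize,centre,provenance passed to \code{\link{intensityField}}.
#' @return an \linkS4class{IntensityField}.
#' @export
ensurePositive <- function(raw, floor = 1, pixelSize = 1, centre = NULL,
                           provenance = "fixture") {
    if (is(raw, "IntensityField")) {
        return(intensityField(pmax(raw@values, floor), raw@pixelSize,
                              raw@centre, raw@provenance))
    }
    raw <- as.matrix(raw)
    stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
    if (!all(is.finite(raw)))
        stop("raw intensity grid contains non-finite values")
    intensityField(pmax(raw, floor), pixelSize = pixelSize, centre = centre,
                   provenance = provenance)
}

#' Read a raster image as a positive intensity field
#'
#' Reads an 8-bit greyscale or RGB PNG/JPEG/TIFF and builds the intensity
#' function mu that TI operates on. \code{mode = "grey"} uses the standard
#' luminance weighting 0.299 R + 0.587 G + 0.114 B (a greyscale file is used
#' as is); \code{mode = "greenness"} computes the relative greenness
#' \code{2 g - r - b + 1} in signed arithmetic on the 0--255 scale, which
#' enhances green foreground objects against grey backgrounds. Both modes
#' are clamped by \code{\link{ensurePositive}}. Matrix row 1 is the bottom
#' scanline so that the package's y-axis points upward.
#'
#' @param path image file path.
#' @param mode \code{"grey"} or \code{"greenness"}.
#' @param floor positivity floor on the 0--255 scale.
#' @return an \linkS4class{IntensityField} with provenance \code{mode},
#'   centre at the geometric image centre.
#' @export
loadIntensity <- function(path, mode = c("grey", "greenness"), floor = 1) {
    mode <- match.arg(mode)
    if (!file.exists(path)) stop("cannot read image file: ", path)
    img <- EBImage::imageData(EBImage::readImage(path)) * 255
    raw <- .rasterIntensity(img, mode)
    ensurePositive(raw, floor = floor, provenance = mode)
}

## img: EBImage array, dim [x, y(, channel)], y increasing downward, 0-255
.rasterIntensity <- function(img, mode) {
    nd <- length(dim(img))
    if (nd == 2L) {
        if (mode == "greenness")
            stop("greenness mode requires an RGB image, got greyscale")
        raw <- img
    } else {
        if (dim(img)[3] < 3L)
            stop("expected 1 or >= 3 channels, got ", dim(img)[3])
        r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
        raw <- if (mode == "grey") 0.299 * r + 0.587 * g + 0.114 * b
               else 2 * g - r - b + 1
    }
    ## EBImage [x, y-down] -> package [row = y-up, col = x]
    m <- t(raw)
    m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Downsample an intensity field by block averaging
#'
#' Reduces the grid by a factor using the mean over non-overlapping
#' factor-by-factor blocks, which preserves total intensity mass (the
#' quantity TI weights by) and positivity. Rows/columns beyond the last
#' complete block are dropped. The physical pixel size is multiplied by the
#' factor and the centre coordinate is mapped to the coarse grid.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param factor positive integer reduction factor.
#' @return an \linkS4class{IntensityField} on the coarse grid.
#' @export
downsampleField <- function(field, factor) {
    stopifnot(is(field, "IntensityField"))
    factor <- as.integer(factor)
    if (factor < 1L) stop("factor must be a positive integer")
    if (factor == 1L) return(field)
    v <- field@values
    if (nrow(v) < factor || ncol(v) < factor)
        stop("factor exceeds the grid size")
    nr <- nrow(v) %/% factor
    nc <- ncol(v) %/% factor
    v <- v[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
    ## block mean via two grouped row means
    dim(v) <- c(factor, nr, nc * factor)
    v <- apply(v, c(2, 3), mean)
    dim(v) <- c(nr, factor, nc)
    v <- apply(v, c(1, 3), mean)
    ## old pixel coordinate x maps to coarse coordinate (x - 0.5)/factor + 0.5
    ctr <- (field@centre - 0.5) / factor + 0.5
    intensityField(v, pixelSize = field@pixelSize * factor, centre = ctr,
                   provenance = field@provenance)
}

#' Threshold an intensity field to a binary mask
#'
#' Mask value 1 marks pixels whose intensity exceeds the threshold. For
#' darker-than-background objects invert the field (or threshold the
#' complement) before calling.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param threshold intensity cutoff.
#' @return a \linkS4class{BinaryMask}.
#' @export
thresholdMask <- function(field, threshold) {
    stopifnot(is(field, "IntensityField"))
    new("BinaryMask", values = (field@values > threshold) * 1)
}

#' Write a 16-bit greyscale PNG preview of a field
#'
#' Linearly rescales the field to [0, 1] and writes a 16-bit PNG (row order
#' flipped back to the image convention).
#'
#' @param field an \linkS4class{IntensityField}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeFieldPreview <- function(field, path) {
    v <- field@values
    rng <- range(v)
    v01 <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    img <- t(v01[rev(seq_len(nrow(v01))), , drop = FALSE])
    EBImage::writeImage(EBImage::Image(img), path, bits.per.sample = 16L)
    invisible(path)
}
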