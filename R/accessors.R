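#' @describeIn IntensityField-class accessor for the intensity matrix
#' @param object an S4 object from this package
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))
setMethod("intensityValues", "IntensityField", function(object) object@values)

#' @describeIn IntensityField-class physical pixel size
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
setMethod("pixelSize", "IntensityField", function(object) object@pixelSize)
setMethod("pixelSize", "TICurve", function(object) object@pixelSize)

#' @describeIn IntensityField-class field centre \code{c(x, y)} in pixel units
#' @export
setGeneric("fieldCentre", function(object) standardGeneric("fieldCentre"))
setMethod("fieldCentre", "IntensityField", function(object) object@centre)

#' @describeIn BinaryMask-class accessor for the 0/1 matrix
#' @export
setGeneric("maskValues", function(object) standardGeneric("maskValues"))
setMethod("maskValues", "BinaryMask", function(object) object@values)

#' @describeIn TICurve-class TI values on the parameter grid
#' @export
setGeneric("tiValues", function(object) standardGeneric("tiValues"))
setMethod("tiValues", "TICurve", function(object) object@values)

#' @describeIn TICurve-class parameter grid(s) of a scan
#' @export
setGeneric("tiParams", function(object) standardGeneric("tiParams"))
setMethod("tiParams", "TICurve", function(object) {
    if (length(object@param2) == 0L) object@param1
    else list(param1 = object@param1, param2 = object@param2)
})

#' @describeIn RDState-class sum of the two concentration fields, the
#'   pattern observable used throughout
#' @export
setGeneric("patternField", function(object) standardGeneric("patternField"))
setMethod("patternField", "RDState", function(object) object@u + object@v)

setMethod("show", "IntensityField", function(object) {
    v <- object@values
    cat(sprintf(
        "IntensityField: %d x %d pixels (%s), pixelSize %g\n",
        nrow(v), ncol(v), object@provenance, object@pixelSize))
    cat(sprintf("  intensity range [%.4g, %.4g], centre (%.4g, %.4g)\n",
        min(v), max(v), object@centre[1], object@centre[2]))
})

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask: %d x %d, %d foreground pixels\n",
        nrow(object@values), ncol(object@values), sum(object@values)))
})

setMethod("show", "TransformSpec", function(object) {
    cat(sprintf("TransformSpec: %s", object@family))
    detail <- switch(object@family,
        rotation = sprintf(" angle=%g deg about (%g, %g)",
            object@angle, object@centre[1], object@centre[2]),
        reflection = sprintf(" axis angle=%g deg through (%g, %g)",
            object@angle, object@axisPoint[1], object@axisPoint[2]),
        translation = sprintf(" shift=(%g, %g) [%s]",
            object@shift[1], object@shift[2], object@boundary),
        rotation_scale = sprintf(" angle=%g deg, scale=%g about (%g, %g)",
            object@angle, object@scale, object@centre[1], object@centre[2]),
        "")
    cat(detail, "\n", sep = "")
})

setMethod("show", "TICurve", function(object) {
    if (length(object@param2) == 0L) {
        cat(sprintf("TICurve (%s): %d grid points, TI in [%.4g, %.4g]\n",
            object@family, length(object@param1),
            min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE)))
    } else {
        cat(sprintf("TICurve (%s): %d x %d grid, TI in [%.4g, %.4g]\n",
            object@family, length(object@param1), length(object@param2),
            min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE)))
    }
})

setMethod("show", "RDState", function(object) {
    p <- object@params
    cat(sprintf(
        "RDState: %d x %d periodic grid, L=%g, t=%g (c=%g, seed=%d)\n",
        p@N, p@N, p@L, object@t, p@c, p@seed))
})

setMethod("show", "CenterEstimate", function(object) {
    if (object@found)
        cat(sprintf("CenterEstimate [%s]: (%.3f, %.3f)\n", object@method,
            object@coordinates[1], object@coordinates[2]))
    else
        cat(sprintf("CenterEstimate [%s]: no centre found (flat criterion)\n",
            object@method))
})

setMethod("show", "DispersionResult", function(object) {
    cat(sprintf(
        "DispersionResult: kMax=%.4f (lambda=%.4f), %s\n",
        object@kMax, object@lambdaMax,
        if (object@unstable) "unstable band present" else "no positive growth"))
})
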