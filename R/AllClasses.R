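#' @import methods
NULL

#' IntensityField: a strictly positive scalar field on a pixel grid
#'
#' The container for the intensity function that Transformation Information
#' operates on. Values are stored as a numeric matrix indexed
#' \code{[row, col]}; the coordinate convention throughout the package is
#' pixel centres at integer coordinates, \code{x = col} increasing rightward,
#' \code{y = row} increasing upward (image files are flipped on load so row 1
#' is the bottom scanline), and angles in degrees counterclockwise.
#'
#' @slot values numeric matrix of strictly positive intensities.
#' @slot pixelSize physical length of one pixel edge (default 1).
#' @slot centre numeric length-2 \code{c(x, y)} in pixel units; the default
#'   rotation/reflection origin.
#' @slot provenance one of \code{"grey"}, \code{"greenness"},
#'   \code{"simulation"}, \code{"fixture"}.
#'
#' @exportClass IntensityField
setClass("IntensityField",
    representation(
        values = "matrix",
        pixelSize = "numeric",
        centre = "numeric",
        provenance = "character"
    ),
    prototype(pixelSize = 1, provenance = "fixture")
)

setValidity("IntensityField", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (any(dim(v) < 2L)) return("grid must be at least 2 pixels in each direction")
    if (!all(is.finite(v))) return("'values' must be finite")
    if (any(v <= 0)) return("'values' must be strictly positive (apply ensurePositive)")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        return("'pixelSize' must be a single positive number")
    ctr <- object@centre
    if (length(ctr) != 2L || !all(is.finite(ctr)))
        return("'centre' must be finite coordinates c(x, y)")
    if (ctr[1] < 1 || ctr[1] > ncol(v) || ctr[2] < 1 || ctr[2] > nrow(v))
        return("'centre' must lie inside the grid bounds")
    TRUE
})

#' BinaryMask: a 0/1 image mask
#'
#' @slot values numeric matrix containing only 0 and 1.
#' @exportClass BinaryMask
setClass("BinaryMask", representation(values = "matrix"))

setValidity("BinaryMask", function(object) {
    v <- object@values
    if (!all(v %in% c(0, 1))) return("mask values must be 0 or 1")
    TRUE
})

#' TransformSpec: a parametrized member of a transformation family
#'
#' Families: \code{identity}, \code{rotation} (by \code{angle} about
#' \code{centre}), \code{reflection} (about the axis through
#' \code{axisPoint} at \code{angle} degrees from horizontal),
#' \code{translation} (by \code{shift}, physical units), and
#' \code{rotation_scale} (rotation by \code{angle} composed with isotropic
#' rescaling by \code{scale}, sharing origin \code{centre}).
#'
#' @slot family character; the transformation family.
#' @slot angle rotation or axis angle, degrees counterclockwise.
#' @slot axisPoint point the reflection axis passes through, pixel units.
#' @slot shift length-2 translation vector, physical units.
#' @slot scale positive rescale factor (1 unless rotation_scale).
#' @slot centre rotation/scaling origin, pixel units (NA = field centre).
#' @slot boundary \code{"crop_intersect"} or \code{"periodic"} (periodic is
#'   valid for the translation family only).
#' @exportClass TransformSpec
setClass("TransformSpec",
    representation(
        family = "character",
        angle = "numeric",
        axisPoint = "numeric",
        shift = "numeric",
        scale = "numeric",
        centre = "numeric",
        boundary = "character"
    ),
    prototype(
        family = "identity", angle = 0, axisPoint = c(NA_real_, NA_real_),
        shift = c(0, 0), scale = 1, centre = c(NA_real_, NA_real_),
        boundary = "crop_intersect"
    )
)

.TRANSFORM_FAMILIES <- c("identity", "rotation", "reflection", "translation",
                         "rotation_scale")

setValidity("TransformSpec", function(object) {
    if (!object@family %in% .TRANSFORM_FAMILIES)
        return(sprintf("unknown family '%s'", object@family))
    if (!object@boundary %in% c("crop_intersect", "periodic"))
        return("boundary must be 'crop_intersect' or 'periodic'")
    if (object@boundary == "periodic" && object@family != "translation")
        return("periodic boundary is only valid for the translation family")
    if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
        return("scale must be a single positive number")
    if (object@family != "rotation_scale" && object@scale != 1)
        return("scale must be 1 unless family is rotation_scale")
    if (length(object@shift) != 2L) return("shift must have length 2")
    TRUE
})

#' TICurve: Transformation Information over a grid of transform parameters
#'
#' For 1-D scans (rotation angle, reflection-axis angle or offset)
#' \code{values} is a vector over \code{param1}. For 2-D scans
#' (translation: shift-x by shift-y; rotation_scale: angle by scale)
#' \code{values} is a matrix with rows indexed by \code{param1} and columns
#' by \code{param2}. Entries where the overlap domain is empty are NA.
#'
#' @slot family transformation family scanned.
#' @slot param1 first parameter grid (angle; shift-x; angle).
#' @slot param2 second parameter grid (empty; shift-y; scale).
#' @slot values TI values on the grid (vector or matrix).
#' @slot centre centre used for the scan, pixel units.
#' @slot pixelSize physical pixel size of the scanned field.
#' @exportClass TICurve
setClass("TICurve",
    representation(
        family = "character",
        param1 = "numeric",
        param2 = "numeric",
        values = "ANY",
        centre = "numeric",
        pixelSize = "numeric"
    ),
    prototype(param2 = numeric(0), centre = c(NA_real_, NA_real_), pixelSize = 1)
)

setValidity("TICurve", function(object) {
    v <- object@values
    if (length(object@param2) == 0L) {
        if (length(v) != length(object@param1))
            return("values length must match param1")
    } else {
        if (!is.matrix(v) || nrow(v) != length(object@param1) ||
            ncol(v) != length(object@param2))
            return("values must be a param1 x param2 matrix")
    }
    TRUE
})

#' DifferenceMap: signed difference between a field and its transform
#'
#' @slot values signed matrix of transformed-minus-original intensity,
#'   NA outside the overlap domain.
#' @slot overlap logical matrix marking the overlap domain.
#' @slot area overlap area in physical units.
#' @exportClass DifferenceMap
setClass("DifferenceMap",
    representation(values = "matrix", overlap = "matrix", area = "numeric"))

#' CenterEstimate: an automatically estimated symmetry centre
#'
#' @slot coordinates estimated centre \code{c(x, y)}, pixel units of the
#'   field the estimate was computed on.
#' @slot method one of \code{"rotational_dti"}, \code{"reflection_ti"},
#'   \code{"area_balance"}.
#' @slot scoreSurface criterion over the search window (matrix, rows = y).
#' @slot xGrid,yGrid pixel coordinates of the surface columns/rows.
#' @slot found FALSE when the criterion was degenerate (e.g. constant field).
#' @exportClass CenterEstimate
setClass("CenterEstimate",
    representation(
        coordinates = "numeric",
        method = "character",
        scoreSurface = "matrix",
        xGrid = "numeric",
        yGrid = "numeric",
        found = "logical"
    ),
    prototype(found = TRUE)
)

#' RDParams: parameters of the two-species reaction-diffusion model
#'
#' The model integrated by \code{\link{simulateTuring}}:
#' du/dt = D delta lap(u) + alpha u (1 - r1 v^2) + v (1 - r2 u) + c delta du/dy,
#' dv/dt = delta lap(v) + beta v (1 + (alpha r1 / beta) u v) + u (gamma + r2 v),
#' on an L-by-L periodic square discretized on an N-by-N grid.
#'
#' @slot delta system-size parameter (scales both diffusivities).
#' @slot D diffusion ratio of the activator u relative to v.
#' @slot alpha,beta,gamma linear interaction coefficients.
#' @slot r1,r2 nonlinear interaction coefficients.
#' @slot c advection rate along y applied to the u equation.
#' @slot L domain edge length. @slot N grid points per edge (even).
#' @slot dt time step. @slot T final time. @slot seed RNG seed.
#' @exportClass RDParams
setClass("RDParams",
    representation(
        delta = "numeric", D = "numeric", alpha = "numeric", beta = "numeric",
        gamma = "numeric", r1 = "numeric", r2 = "numeric", c = "numeric",
        L = "numeric", N = "integer", dt = "numeric", T = "numeric",
        seed = "integer"
    ),
    prototype(
        delta = 5e-3, D = 0.5, alpha = 1, beta = -1, gamma = -1,
        r1 = 1, r2 = 0, c = 0, L = 10, N = 128L, dt = 0.05, T = 100,
        seed = 1L
    )
)

setValidity("RDParams", function(object) {
    if (object@delta <= 0) return("delta must be positive")
    if (object@D <= 0) return("D must be positive")
    if (object@N < 32L || object@N %% 2L != 0L)
        return("N must be even and at least 32")
    if (object@dt <= 0) return("dt must be positive")
    if (object@T < 0) return("T must be non-negative")
    if (object@L <= 0) return("L must be positive")
    TRUE
})

#' RDState: concentration fields of the reaction-diffusion model
#'
#' @slot u,v real N-by-N matrices on the periodic domain.
#' @slot t current simulation time.
#' @slot params the \code{RDParams} that produced the state.
#' @exportClass RDState
setClass("RDState",
    representation(u = "matrix", v = "matrix", t = "numeric",
                   params = "RDParams"))

setValidity("RDState", function(object) {
    if (!identical(dim(object@u), dim(object@v)))
        return("u and v must have the same shape")
    if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
        return("state contains non-finite values")
    TRUE
})

#' DispersionResult: linear-stability summary of the model
#'
#' @slot kGrid wavenumber magnitudes scanned (2*pi convention).
#' @slot growth leading real part of the per-mode growth rate.
#' @slot kMax wavenumber of the fastest-growing mode.
#' @slot lambdaMax 2*pi/kMax.
#' @slot unstable TRUE when a band of positive growth exists.
#' @exportClass DispersionResult
setClass("DispersionResult",
    representation(kGrid = "numeric", growth = "numeric", kMax = "numeric",
                   lambdaMax = "numeric", unstable = "logical"))

#' LandmarkSet: labelled 2-D points with a rotation centre
#'
#' @slot points n-by-2 matrix of \code{(x, y)} coordinates.
#' @slot centre rotation centre \code{c(x, y)}.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
    representation(points = "matrix", centre = "numeric"),
    prototype(centre = c(0, 0)))

setValidity("LandmarkSet", function(object) {
    p <- object@points
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
        return("points must be an n-by-2 matrix with n >= 1")
    if (anyDuplicated(p)) return("landmark points must be distinct")
    if (length(object@centre) != 2L) return("centre must have length 2")
    TRUE
})
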