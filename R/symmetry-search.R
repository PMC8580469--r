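## Topographic prominence of a local minimum on a 1-D curve: walk out in
## each direction until a strictly lower value appears; the prominence is
## the lower of the two barrier heights climbed. For periodic grids the
## walk wraps.
.minimumProminence1D <- function(v, i, periodic) {
    n <- length(v)
    barrier <- function(dir) {
        best <- -Inf
        j <- i
        for (s in seq_len(n - 1L)) {
            j <- j + dir
            if (periodic) j <- ((j - 1L) %% n) + 1L
            else if (j < 1L || j > n) return(best)
            if (is.na(v[j])) return(best)
            if (v[j] < v[i]) return(best)
            best <- max(best, v[j])
        }
        best
    }
    b <- min(barrier(1L), barrier(-1L))
    if (!is.finite(b)) return(Inf)
    b - v[i]
}

.localMinima1D <- function(v, periodic) {
    n <- length(v)
    idx <- integer(0)
    for (i in seq_len(n)) {
        if (is.na(v[i])) next
        l <- if (i > 1L) i - 1L else if (periodic) n else NA_integer_
        r <- if (i < n) i + 1L else if (periodic) 1L else NA_integer_
        if (is.na(l) || is.na(r)) next              # non-periodic boundary
        if (is.na(v[l]) || is.na(v[r])) next
        if (v[i] < v[l] && v[i] <= v[r]) idx <- c(idx, i)
    }
    idx
}

#' Extract ranked approximate symmetries from a TI curve
#'
#' Finds all interior local minima of the curve with topographic prominence
#' at least \code{minProminence} times the curve's TI range, excluding the
#' identity transformation. Angular grids spanning the family's period
#' (360 degrees for rotations, 180 for reflection axes) are treated as
#' periodic, so minima at the wrap point are found. Candidates are ranked
#' ascending by TI; ties break by lower TI then smaller parameter
#' magnitude.
#'
#' For 2-D scans (rotation-rescale, translation) minima are grid points
#' below all 8 neighbours; their prominence is approximated by the smaller
#' of the 1-D prominences along the row and column through the minimum.
#'
#' @param curve a \linkS4class{TICurve}.
#' @param minProminence prominence threshold as a fraction of the TI range.
#' @return a data.frame with columns \code{rank, family, param1, param2,
#'   ti, prominence} (param2 is NA for 1-D scans), sorted by rank. Zero
#'   rows when no minimum passes.
#' @export
findSymmetries <- function(curve, minProminence = 0.02) {
    stopifnot(is(curve, "TICurve"))
    v <- curve@values
    if (all(is.na(v))) stop("all-undefined TI curve")
    rng <- diff(range(v, na.rm = TRUE))
    thresh <- minProminence * rng
    fam <- curve@family
    is2d <- length(curve@param2) > 0L

    if (!is2d) {
        period <- switch(fam, rotation = 360, reflection = 180, NA_real_)
        p <- curve@param1
        span <- if (length(p) > 1L) diff(range(p)) + (p[2] - p[1]) else 0
        periodic <- !is.na(period) && isTRUE(abs(span - period) < 1e-9)
        idx <- .localMinima1D(v, periodic)
        if (fam == "rotation") {
            idx <- idx[abs(p[idx] %% 360) > 1e-9 &
                       abs(p[idx] %% 360 - 360) > 1e-9]
        }
        prom <- vapply(idx, function(i) .minimumProminence1D(v, i, periodic),
                       numeric(1))
        keep <- which(prom >= thresh)
        out <- data.frame(family = rep(fam, length(keep)),
                          param1 = p[idx[keep]],
                          param2 = rep(NA_real_, length(keep)),
                          ti = v[idx[keep]], prominence = prom[keep])
    } else {
        n1 <- length(curve@param1); n2 <- length(curve@param2)
        rows <- list()
        for (i in seq_len(n1)) for (j in seq_len(n2)) {
            if (is.na(v[i, j])) next
            nb <- c()
            for (di in -1:1) for (dj in -1:1) {
                if (di == 0 && dj == 0) next
                ii <- i + di; jj <- j + dj
                if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
                nb <- c(nb, v[ii, jj])
            }
            if (length(nb) < 8L || any(is.na(nb))) next   # interior only
            if (!all(v[i, j] < nb)) next
            isIdent <- switch(fam,
                rotation_scale = abs(curve@param1[i] %% 360) < 1e-9 &&
                                 abs(curve@param2[j] - 1) < 1e-9,
                translation = curve@param1[i] == 0 && curve@param2[j] == 0,
                FALSE)
            if (isIdent) next
            pr <- min(.minimumProminence1D(v[i, ], j, FALSE),
                      .minimumProminence1D(v[, j], i, FALSE))
            if (pr < thresh) next
            rows[[length(rows) + 1L]] <- data.frame(
                family = fam, param1 = curve@param1[i],
                param2 = curve@param2[j], ti = v[i, j], prominence = pr)
        }
        out <- if (length(rows)) do.call(rbind, rows)
               else data.frame(family = character(0), param1 = numeric(0),
                               param2 = numeric(0), ti = numeric(0),
                               prominence = numeric(0))
    }
    o <- order(out$ti, abs(out$param1))
    out <- out[o, , drop = FALSE]
    out <- cbind(rank = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
}

.resolveWindow <- function(window, field) {
    v <- field@values
    if (is.null(window)) window <- c(1, ncol(v), 1, nrow(v))
    stopifnot(length(window) == 4L)
    if (window[2] < window[1] || window[4] < window[3])
        stop("degenerate search window")
    if (window[1] < 1 || window[2] > ncol(v) ||
        window[3] < 1 || window[4] > nrow(v))
        stop("search window must lie inside the field")
    window
}

#' Estimate a rotation-symmetry centre by the dTI/dtheta criterion
#'
#' For every candidate centre in the search window, evaluates TI at the
#' \code{nAngles} evenly spaced rotations \code{k*360/nAngles} about it,
#' excluding the identity (k = 0), and scores the centre by the Euclidean
#' norm of the consecutive TI differences along that arc. Near a true
#' rotation centre TI swings between deep symmetry minima and high
#' antiphase values, so the norm peaks there; off-centre the curve
#' flattens. The identity is excluded because TI vanishes there for every
#' centre, so differences against it measure the overall TI level rather
#' than its angular variation and would reward poorly centred, highly
#' asymmetric configurations. The
#' field is block-downsampled first, trading resolution for speed; the
#' returned coordinates are in the original field's pixel units.
#'
#' The search window should sit inside the object's core: for candidate
#' centres off the object, the overall TI level (rather than its angular
#' variation) dominates the differences and can out-score the true centre.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param window search box \code{c(x0, x1, y0, y1)} in original pixel
#'   units; NULL for the whole field.
#' @param nAngles number of rotation angles on the ring (default 12).
#' @param downsampleFactor block-mean reduction factor (default 16).
#' @return a \linkS4class{CenterEstimate}, method
#'   \code{"rotational_dti"}; \code{found = FALSE} when the criterion is
#'   flat (e.g. a constant field).
#' @export
estimateCenterRotational <- function(field, window = NULL, nAngles = 12L,
                                     downsampleFactor = 16L) {
    stopifnot(nAngles >= 3L)
    window <- .resolveWindow(window, field)
    f <- downsampleField(field, downsampleFactor)
    dsf <- as.integer(downsampleFactor)
    toCoarse <- function(p) (p - 0.5) / dsf + 0.5
    toFine <- function(p) (p - 0.5) * dsf + 0.5
    cw <- c(max(1, ceiling(toCoarse(window[1]))),
            min(ncol(f@values), floor(toCoarse(window[2]))),
            max(1, ceiling(toCoarse(window[3]))),
            min(nrow(f@values), floor(toCoarse(window[4]))))
    if (cw[2] < cw[1] || cw[4] < cw[3])
        stop("search window is degenerate after downsampling")
    xs <- cw[1]:cw[2]; ys <- cw[3]:cw[4]
    angles <- (360 / nAngles) * seq_len(nAngles - 1L)   # identity excluded
    surf <- matrix(NA_real_, length(ys), length(xs))
    for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
        ti <- vapply(angles, function(a) {
            tryCatch(transformationInformation(
                f, rotationSpec(a, c(xs[ix], ys[iy]))),
                error = function(e) NA_real_)
        }, numeric(1))
        if (all(is.finite(ti)))
            surf[iy, ix] <- sqrt(sum(diff(ti)^2))
    }
    if (all(is.na(surf)) || diff(range(surf, na.rm = TRUE)) == 0) {
        return(new("CenterEstimate", coordinates = c(NA_real_, NA_real_),
                   method = "rotational_dti", scoreSurface = surf,
                   xGrid = toFine(xs), yGrid = toFine(ys), found = FALSE))
    }
    best <- which(surf == max(surf, na.rm = TRUE), arr.ind = TRUE)[1, ]
    new("CenterEstimate",
        coordinates = c(toFine(xs[best[2]]), toFine(ys[best[1]])),
        method = "rotational_dti", scoreSurface = surf,
        xGrid = toFine(xs), yGrid = toFine(ys), found = TRUE)
}

#' Estimate a symmetry centre from axis-aligned reflection TI
#'
#' The x-coordinate minimizes TI for reflections about vertical axes
#' scanned across the window; the y-coordinate minimizes TI for
#' reflections about horizontal axes. The stored score surface is the sum
#' of the two 1-D criteria, so its minimum sits at the returned
#' coordinates; secondary local minima of either scan can be recovered
#' from the surface margins.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param window search box \code{c(x0, x1, y0, y1)}; NULL for the whole
#'   field.
#' @param step scan step in pixels.
#' @return a \linkS4class{CenterEstimate}, method \code{"reflection_ti"}.
#' @export
estimateCenterReflection <- function(field, window = NULL, step = 1) {
    window <- .resolveWindow(window, field)
    xs <- seq(window[1], window[2], by = step)
    ys <- seq(window[3], window[4], by = step)
    yc <- field@centre[2]; xc <- field@centre[1]
    tiX <- vapply(xs, function(x) {
        tryCatch(transformationInformation(
            field, reflectionSpec(90, c(x, yc))), error = function(e) NA_real_)
    }, numeric(1))
    tiY <- vapply(ys, function(y) {
        tryCatch(transformationInformation(
            field, reflectionSpec(0, c(xc, y))), error = function(e) NA_real_)
    }, numeric(1))
    surf <- outer(tiY, tiX, "+")
    flat <- (all(is.na(tiX)) || diff(range(tiX, na.rm = TRUE)) == 0) &&
            (all(is.na(tiY)) || diff(range(tiY, na.rm = TRUE)) == 0)
    if (flat) {
        return(new("CenterEstimate", coordinates = c(NA_real_, NA_real_),
                   method = "reflection_ti", scoreSurface = surf,
                   xGrid = xs, yGrid = ys, found = FALSE))
    }
    new("CenterEstimate",
        coordinates = c(xs[which.min(tiX)], ys[which.min(tiY)]),
        method = "reflection_ti", scoreSurface = surf,
        xGrid = xs, yGrid = ys, found = TRUE)
}

## best split position along one axis given per-line foreground counts:
## candidate lines run between pixels (half-integer) or through a pixel
## row/column (integer, that line's pixels belonging to neither side);
## ties in the imbalance resolve to the median tied position
.balanceSplit <- function(counts) {
    n <- length(counts)
    pos <- seq(1, n, by = 0.5)
    cum <- c(0, cumsum(counts))
    imb <- vapply(pos, function(p) {
        if (p %% 1 == 0) {            # through pixel line p: exclude it
            left <- cum[p]; right <- cum[n + 1] - cum[p + 1]
        } else {                      # between floor(p) and floor(p)+1
            left <- cum[floor(p) + 1]; right <- cum[n + 1] - left
        }
        abs(left - right)
    }, numeric(1))
    best <- pos[imb == min(imb)]
    list(coord = stats::median(best), imbalance = imb, pos = pos)
}

#' Estimate a centre by balancing foreground areas
#'
#' Chooses the vertical split line making the foreground areas left and
#' right of it as equal as integer-pixel splitting allows, and likewise a
#' horizontal split for above/below. Split lines run either between pixel
#' columns/rows or through one (pixels on a through-pixel line belong to
#' neither side); among equally balanced lines the median position wins.
#'
#' @param mask a \linkS4class{BinaryMask} with at least one foreground
#'   pixel.
#' @return a \linkS4class{CenterEstimate}, method \code{"area_balance"};
#'   the score surface is the |left - right| + |below - above| imbalance.
#' @export
estimateCenterArea <- function(mask) {
    stopifnot(is(mask, "BinaryMask"))
    v <- mask@values
    if (sum(v) == 0) stop("empty mask")
    bx <- .balanceSplit(colSums(v))
    by <- .balanceSplit(rowSums(v))
    new("CenterEstimate", coordinates = c(bx$coord, by$coord),
        method = "area_balance",
        scoreSurface = outer(by$imbalance, bx$imbalance, "+"),
        xGrid = bx$pos, yGrid = by$pos, found = TRUE)
}

#' Search for the best bilateral-symmetry axis angle
#'
#' Scans reflection TI over axis angles through a fixed centre and returns
#' the minimizing angle with the full curve. The grid resolution is the
#' precision contract: no sub-grid refinement is applied.
#'
#' @param field an \linkS4class{IntensityField}.
#' @param centre axis anchor point; NULL for the field centre.
#' @param angleRange interval of axis angles, degrees from horizontal.
#' @param step angle step, degrees.
#' @return a list with \code{bestAngle} and \code{curve} (a
#'   \linkS4class{TICurve}).
#' @export
bilateralAxisSearch <- function(field, centre = NULL,
                                angleRange = c(-30, 30), step = 0.5) {
    stopifnot(step > 0, length(angleRange) == 2L,
              angleRange[2] >= angleRange[1])
    angles <- seq(angleRange[1], angleRange[2], by = step)
    curve <- tiScan(field, "reflection", angles = angles, centre = centre)
    list(bestAngle = angles[which.min(curve@values)], curve = curve)
}
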