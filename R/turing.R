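#' Construct reaction-diffusion model parameters
#'
#' Defaults are the stripe-forming parameter set used throughout the
#' package's translation-symmetry analyses: delta=5e-3, D=0.5, alpha=1,
#' beta=-1, gamma=-1, r1=1, r2=0 on a 10x10 periodic domain. With r2=0 the
#' quadratic terms vanish and stripes are preferred to spots. The advection
#' rate \code{c} adds a term \code{c*delta*du/dy} to the u equation, which
#' breaks isotropy and aligns the stripes along x as c grows.
#'
#' @param delta,D,alpha,beta,gamma,r1,r2,c model coefficients (see
#'   \linkS4class{RDParams}).
#' @param L domain edge length. @param N grid points per edge (even).
#' @param dt time step. @param T final time. @param seed RNG seed for the
#'   initial noise.
#' @return an \linkS4class{RDParams}.
#' @export
rdParams <- function(delta = 5e-3, D = 0.5, alpha = 1, beta = -1,
                     gamma = -1, r1 = 1, r2 = 0, c = 0, L = 10,
                     N = 128L, dt = 0.05, T = 100, seed = 1L) {
    new("RDParams", delta = delta, D = D, alpha = alpha, beta = beta,
        gamma = gamma, r1 = r1, r2 = r2, c = c, L = L, N = as.integer(N),
        dt = dt, T = T, seed = as.integer(seed))
}

## phi-function coefficients for the scalar ETDRK4 scheme, evaluated by
## averaging over a complex contour of radius 1 around each h*L value to
## avoid cancellation at small |h*L| (Kassam-Trefethen).
.etdrk4Coefficients <- function(L, h, M = 32L) {
    r <- exp(1i * pi * (seq_len(M) - 0.5) / M)
    n <- length(L)
    LR <- matrix(h * L, n, M) + matrix(r, n, M, byrow = TRUE)
    eLR <- exp(LR)
    cmean <- function(x) Re(rowMeans(x))
    list(
        E = exp(h * L), E2 = exp(h * L / 2),
        Q = h * cmean((exp(LR / 2) - 1) / LR),
        f1 = h * cmean((-4 - LR + eLR * (4 - 3 * LR + LR^2)) / LR^3),
        f2 = h * cmean((2 + LR + eLR * (-2 + LR)) / LR^3),
        f3 = h * cmean((-4 - 3 * LR - LR^2 + eLR * (4 - LR)) / LR^3)
    )
}

#' Integrate the reaction-diffusion model on a periodic square
#'
#' Pseudospectral integration of the two-species model (see
#' \linkS4class{RDParams}) with a fourth-order exponential time
#' differencing scheme (ETDRK4) in Fourier space. The per-mode linear
#' operator contains diffusion and advection (diagonal per species); all
#' reaction terms, including their linear parts, are treated in the
#' nonlinear stage, evaluated in real space with two-thirds dealiasing.
#' The initial condition is independent uniform noise in
#' \code{[-noiseAmplitude, noiseAmplitude]} for u and v, drawn from the
#' seed in \code{params}; the run is deterministic given the seed.
#'
#' @param params an \linkS4class{RDParams}.
#' @param noiseAmplitude amplitude of the initial uniform noise.
#' @return an \linkS4class{RDState} at time \code{params@T}.
#' @export
simulateTuring <- function(params, noiseAmplitude = 0.05) {
    stopifnot(is(params, "RDParams"))
    validObject(params)
    N <- params@N; L <- params@L
    ## wavenumbers, 2*pi convention
    k1 <- (2 * pi / L) * c(0:(N / 2 - 1), (-N / 2):(-1))
    KX <- matrix(k1, N, N, byrow = TRUE)   # varies along columns (x)
    KY <- matrix(k1, N, N)                 # varies along rows (y)
    K2 <- KX^2 + KY^2
    Lu <- -params@D * params@delta * K2 + 1i * params@c * params@delta * KY
    Lv <- -params@delta * K2
    ## two-thirds dealiasing mask for the nonlinear products
    kcut <- (2 * pi / L) * (N / 3)
    dealias <- (abs(KX) < kcut) & (abs(KY) < kcut)

    nsteps <- max(1L, as.integer(ceiling(params@T / params@dt - 1e-9)))
    h <- params@T / nsteps
    cu <- .etdrk4Coefficients(as.vector(Lu), h)
    cv <- .etdrk4Coefficients(as.vector(Lv), h)
    shape <- function(x) matrix(x, N, N)
    cu <- lapply(cu, shape); cv <- lapply(cv, shape)

    alpha <- params@alpha; beta <- params@beta; gamma <- params@gamma
    r1 <- params@r1; r2 <- params@r2
    npix <- N * N
    nonlin <- function(uh, vh) {
        u <- Re(fft(uh, inverse = TRUE)) / npix
        v <- Re(fft(vh, inverse = TRUE)) / npix
        Nu <- alpha * u * (1 - r1 * v^2) + v * (1 - r2 * u)
        Nv <- beta * v + alpha * r1 * u * v^2 + u * (gamma + r2 * v)
        list(u = fft(Nu) * dealias, v = fft(Nv) * dealias)
    }

    set.seed(params@seed)
    u0 <- matrix(stats::runif(npix, -noiseAmplitude, noiseAmplitude), N, N)
    v0 <- matrix(stats::runif(npix, -noiseAmplitude, noiseAmplitude), N, N)
    if (params@T == 0)
        return(new("RDState", u = u0, v = v0, t = 0, params = params))
    uh <- fft(u0); vh <- fft(v0)

    for (step in seq_len(nsteps)) {
        N0 <- nonlin(uh, vh)
        au <- cu$E2 * uh + cu$Q * N0$u
        av <- cv$E2 * vh + cv$Q * N0$v
        Na <- nonlin(au, av)
        bu <- cu$E2 * uh + cu$Q * Na$u
        bv <- cv$E2 * vh + cv$Q * Na$v
        Nb <- nonlin(bu, bv)
        cuh <- cu$E2 * au + cu$Q * (2 * Nb$u - N0$u)
        cvh <- cv$E2 * av + cv$Q * (2 * Nb$v - N0$v)
        Nc <- nonlin(cuh, cvh)
        uh <- cu$E * uh + cu$f1 * N0$u + 2 * cu$f2 * (Na$u + Nb$u) +
              cu$f3 * Nc$u
        vh <- cv$E * vh + cv$f1 * N0$v + 2 * cv$f2 * (Na$v + Nb$v) +
              cv$f3 * Nc$v
        if (step %% 100L == 0L || step == nsteps) {
            if (!all(is.finite(Re(uh))) || !all(is.finite(Re(vh))))
                stop(sprintf(
                    "integration blew up at step %d (t=%.3f); reduce dt ",
                    step, step * h), "(dt <= 0.05 is stable at the default ",
                    "parameter set)")
        }
    }
    u <- Re(fft(uh, inverse = TRUE)) / npix
    v <- Re(fft(vh, inverse = TRUE)) / npix
    new("RDState", u = u, v = v, t = params@T, params = params)
}

#' Convert a simulation state to an IntensityField
#'
#' Takes the pattern observable u+v, clamps it positive, and attaches the
#' physical pixel size \code{L/N} so translation shifts are reported in
#' domain length units.
#'
#' @param state an \linkS4class{RDState}.
#' @param floor positivity floor applied to u+v after shifting its minimum
#'   to \code{floor} (the raw field is signed). The default rescales to a
#'   mean-1 positive field: \code{w - min(w) + floor}.
#' @return an \linkS4class{IntensityField}, provenance "simulation".
#' @export
stateToField <- function(state, floor = 0.1) {
    w <- patternField(state)
    w <- w - min(w) + floor
    intensityField(w, pixelSize = state@params@L / state@params@N,
                   provenance = "simulation")
}

#' Per-mode linear growth rate of the reaction-diffusion model
#'
#' The leading real part of the eigenvalues of the linearization of the
#' model about the zero homogeneous state at wavenumber magnitude k:
#' \code{[[alpha - D*delta*k^2, 1], [gamma, beta - delta*k^2]]}. Advection
#' contributes only an imaginary shift and does not affect the real part.
#'
#' @param params an \linkS4class{RDParams}.
#' @param k wavenumber magnitude(s), 2*pi convention (vectorized).
#' @return numeric vector of growth rates.
#' @export
dispersionGrowthRate <- function(params, k) {
    a11 <- params@alpha - params@D * params@delta * k^2
    a22 <- params@beta - params@delta * k^2
    tr <- a11 + a22
    det <- a11 * a22 - params@gamma * 1
    disc <- tr^2 - 4 * det
    Re((tr + sqrt(as.complex(disc))) / 2)
}

#' Fastest-growing mode of the linearized model
#'
#' Locates the wavenumber maximizing \code{\link{dispersionGrowthRate}} by
#' a coarse scan followed by golden-section refinement. When no positive
#' growth exists anywhere the argmax of the (negative) growth is still
#' returned, flagged with \code{unstable = FALSE} and a warning.
#'
#' @param params an \linkS4class{RDParams}.
#' @param kUpper upper end of the scanned wavenumber range.
#' @param nScan coarse-scan resolution.
#' @return a \linkS4class{DispersionResult}.
#' @export
fastestMode <- function(params, kUpper = 50, nScan = 2001L) {
    kGrid <- seq(0, kUpper, length.out = nScan)
    growth <- dispersionGrowthRate(params, kGrid)
    i <- which.max(growth)
    lo <- kGrid[max(1L, i - 1L)]; hi <- kGrid[min(nScan, i + 1L)]
    opt <- stats::optimize(function(k) dispersionGrowthRate(params, k),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-10)
    unstable <- any(growth > 0)
    if (!unstable)
        warning("no positive growth band: the homogeneous state is stable; ",
                "returning the argmax of the (negative) growth rate")
    kMax <- opt$maximum
    new("DispersionResult", kGrid = kGrid, growth = growth, kMax = kMax,
        lambdaMax = 2 * pi / kMax, unstable = unstable)
}

#' Radially averaged Fourier spectrum of the pattern deviation
#'
#' The magnitude of the 2-D Fourier transform of \code{u+v} minus its mean,
#' averaged over annular wavenumber-magnitude bins of width \code{2*pi/L}
#' (2*pi convention). The peak bin, excluding the zero mode, estimates the
#' characteristic pattern wavenumber.
#'
#' @param state an \linkS4class{RDState}, or a numeric matrix with
#'   \code{L} supplied.
#' @param L domain edge length (required for a bare matrix).
#' @return a list with \code{k} (bin-centre wavenumbers), \code{power}
#'   (mean spectral magnitude per bin) and \code{kPeak}.
#' @export
radialSpectrum <- function(state, L = NULL) {
    if (is(state, "RDState")) {
        w <- patternField(state)
        L <- state@params@L
    } else {
        w <- state
        if (is.null(L)) stop("supply the domain length L for a bare matrix")
    }
    N1 <- nrow(w); N2 <- ncol(w)
    dev <- w - mean(w)
    if (max(abs(dev)) == 0) {
        warning("constant state: spectrum is identically zero")
        return(list(k = numeric(0), power = numeric(0), kPeak = NA_real_))
    }
    P <- abs(fft(dev))
    kx <- (2 * pi / L) * c(0:(N2 %/% 2), -((N2 - N2 %/% 2 - 1):1))
    ky <- (2 * pi / L) * c(0:(N1 %/% 2), -((N1 - N1 %/% 2 - 1):1))
    K <- sqrt(outer(ky^2, kx^2, "+"))
    dk <- 2 * pi / L
    bin <- as.integer(round(K / dk))
    power <- as.numeric(tapply(as.numeric(P), bin, mean))
    kBin <- sort(unique(bin)) * dk
    keep <- kBin > 0
    kPeak <- kBin[keep][which.max(power[keep])]
    list(k = kBin, power = power, kPeak = kPeak)
}

#' Radial profile of a periodic translation TI map
#'
#' Averages TI over annular bins of shift magnitude (bin width one pixel in
#' physical units) and reports the profile and the radius of its maximum --
#' the ring of least symmetric translations, which for a striped pattern
#' sits at about half the characteristic pattern wavelength.
#'
#' @param tiMap a translation \linkS4class{TICurve} from
#'   \code{\link{translationTI}}.
#' @return a list with \code{r} (bin-centre radii), \code{ti} (mean TI per
#'   bin) and \code{radius} (argmax of the profile).
#' @export
tiRadialProfile <- function(tiMap) {
    stopifnot(is(tiMap, "TICurve"), tiMap@family == "translation")
    R <- sqrt(outer(tiMap@param1^2, tiMap@param2^2, "+"))
    dr <- tiMap@pixelSize
    bin <- as.integer(round(R / dr))
    prof <- as.numeric(tapply(as.numeric(tiMap@values), bin, mean))
    rBin <- sort(unique(bin)) * dr
    if (max(prof) - min(prof) <= 0) {
        warning("flat TI map: no annulus radius")
        return(list(r = rBin, ti = prof, radius = NA_real_))
    }
    list(r = rBin, ti = prof, radius = rBin[which.max(prof)])
}

#' @rdname tiRadialProfile
#' @param ... passed to \code{tiRadialProfile}.
#' @export
tiAnnulusRadius <- function(tiMap, ...) tiRadialProfile(tiMap, ...)$radius

#' Directional anisotropy of a translation TI map
#'
#' Ratio of the mean TI over shifts within a sector around the y-axis to
#' the mean over the matching sector around the x-axis, restricted to a
#' common range of shift magnitudes. Isotropic maps give 1; patterns of
#' stripes aligned along x vary along y, concentrating TI in the y sector
#' and pushing the ratio above 1.
#'
#' Shift magnitudes are capped (by default at the least-symmetric-annulus
#' radius of the map, see \code{\link{tiAnnulusRadius}}) so that the
#' transverse component of a sector shift stays well below the
#' characteristic pattern wavelength; without the cap, long shifts
#' decorrelate the pattern in every direction and dilute the contrast.
#'
#' @param tiMap a translation \linkS4class{TICurve}.
#' @param halfAngle sector half-width, degrees.
#' @param rCap largest shift magnitude included; NULL for the annulus
#'   radius (falling back to the full common range on flat maps).
#' @return a single numeric ratio.
#' @export
anisotropyRatio <- function(tiMap, halfAngle = 15, rCap = NULL) {
    stopifnot(is(tiMap, "TICurve"), tiMap@family == "translation")
    sx <- matrix(tiMap@param1, length(tiMap@param1), length(tiMap@param2))
    sy <- matrix(tiMap@param2, length(tiMap@param1), length(tiMap@param2),
                 byrow = TRUE)
    r <- sqrt(sx^2 + sy^2)
    rMax <- min(max(abs(tiMap@param1)), max(abs(tiMap@param2)))
    if (is.null(rCap)) {
        rCap <- suppressWarnings(tiAnnulusRadius(tiMap))
        if (!is.finite(rCap)) rCap <- rMax
    }
    rCap <- min(rCap, rMax)
    ha <- halfAngle * pi / 180
    angY <- atan2(abs(sx), abs(sy))   # angle from the y-axis
    angX <- atan2(abs(sy), abs(sx))   # angle from the x-axis
    inR <- r > 0 & r <= rCap
    ySec <- inR & angY <= ha
    xSec <- inR & angX <= ha
    mean(tiMap@values[ySec]) / mean(tiMap@values[xSec])
}
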