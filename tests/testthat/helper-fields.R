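# Shared test helpers: small synthetic fields and a cache for the long
# reaction-diffusion runs so several test files can reuse the same states.

# smooth strictly positive test field: sum of a few Gaussian bumps
smoothTestField <- function(size = 64, seed = 1, nBumps = 4) {
    set.seed(seed)
    ctr <- c((size + 1) / 2, (size + 1) / 2)
    x <- matrix(rep(seq_len(size), each = size), size, size) - ctr[1]
    y <- matrix(rep(seq_len(size), times = size), size, size) - ctr[2]
    v <- matrix(0, size, size)
    for (i in seq_len(nBumps)) {
        cx <- runif(1, -size / 4, size / 4)
        cy <- runif(1, -size / 4, size / 4)
        s <- runif(1, size / 12, size / 6)
        v <- v + runif(1, 0.5, 1) * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    }
    intensityField(1 + 100 * v, centre = ctr)
}

# rough (pixel-noise) positive field
roughTestField <- function(size = 16, seed = 1) {
    set.seed(seed)
    intensityField(matrix(runif(size^2, 0.5, 2), size, size))
}

.simCache <- new.env(parent = emptyenv())

# memoized stripe-pattern simulation at the standard parameter set
cachedSim <- function(seed, c = 0, T = 100) {
    key <- sprintf("s%d_c%g_T%g", seed, c, T)
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateTuring(rdParams(seed = seed, c = c, T = T))
    .simCache[[key]]
}

# radial distance of each pixel from a centre, in pixel units
pixelRadius <- function(size, centre = c((size + 1) / 2, (size + 1) / 2)) {
    x <- matrix(rep(seq_len(size), each = size), size, size) - centre[1]
    y <- matrix(rep(seq_len(size), times = size), size, size) - centre[2]
    sqrt(x^2 + y^2)
}
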