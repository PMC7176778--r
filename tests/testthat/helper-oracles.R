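# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-computation (direct sums, brute
# force, fine quadrature) kept separate from the package's implementation
# paths.

# Direct-sum centered DFT pair: O(n^2) textbook definition with the DC bin
# at 0-based index floor(n/2).
naiveCenteredFft <- function(x) {
    n <- length(x)
    ctr <- floor(n / 2)
    k <- seq_len(n) - 1 - ctr       # frequency index
    j <- seq_len(n) - 1 - ctr       # sample index
    W <- exp(-2i * pi * outer(k, j) / n)
    as.vector(W %*% x)
}

naiveCenteredIfft <- function(X) {
    n <- length(X)
    ctr <- floor(n / 2)
    k <- seq_len(n) - 1 - ctr
    j <- seq_len(n) - 1 - ctr
    W <- exp(2i * pi * outer(j, k) / n)
    as.vector(W %*% X) / n
}

# Fine Riemann-sum line integral of a phantom along the ray at angle
# `angleDeg` and signed distance `s` (ray direction is the angle's normal).
naiveLineIntegral <- function(ph, angleDeg, s, tMax = 1.5, nStep = 40000L) {
    th <- angleDeg * pi / 180
    tt <- seq(-tMax, tMax, length.out = nStep)
    dt <- tt[2L] - tt[1L]
    x <- s * cos(th) - tt * sin(th)
    y <- s * sin(th) + tt * cos(th)
    e <- ellipses(ph)
    val <- numeric(nStep)
    for (i in seq_len(nrow(e))) {
        phi <- e$phiDeg[i] * pi / 180
        xr <- (x - e$cx[i]) * cos(phi) + (y - e$cy[i]) * sin(phi)
        yr <- -(x - e$cx[i]) * sin(phi) + (y - e$cy[i]) * cos(phi)
        val <- val + e$rho[i] * ((xr / e$a[i])^2 + (yr / e$b[i])^2 <= 1)
    }
    sum(val) * dt
}

# Brute-force displacement search: for each index, loop over every candidate
# in [-N, N] and evaluate the objective via the exported scalar operations.
naiveBestObjective <- function(p1, p2, N = 12L, lambda = 0.001) {
    vapply(seq_along(p2), function(n)
        min(vapply(-N:N, function(u) objectiveF(p1, p2, n, u, lambda),
                   numeric(1))),
        numeric(1))
}

# compactly supported bump with strictly monotone flanks
monotoneBump <- function(len, at, halfwidth = 4L) {
    x <- numeric(len)
    idx <- (at - halfwidth):(at + halfwidth)
    ok <- idx >= 1 & idx <= len
    x[idx[ok]] <- (halfwidth + 1 - abs(idx[ok] - at))[ok]
    x
}

randomSinogram <- function(nRadial = 16L, nViews = 6L, coverageDeg = 180) {
    Sinogram(matrix(runif(nRadial * nViews), nRadial, nViews),
             coverageDeg = coverageDeg)
}
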