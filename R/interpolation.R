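# View interpolation: linear and periodic-sinc baselines, and the
# displacement-function method (bounded integer estimation by exhaustive
# minimization, then displacement-interpolated view synthesis).
#
# Radial indices are 1-based in R.  Any sample requested outside [1, L] is
# treated as 0: projections vanish outside the object support.

# zero-filled element access
zfAt <- function(v, i) {
    ok <- i >= 1L & i <= length(v)
    out <- numeric(length(i))
    out[ok] <- v[i[ok]]
    out
}

# candidate scan order 0, -1, +1, -2, +2, ..., -N, +N (ties prefer the
# smallest |u|, and -k over +k)
scanOrder <- function(N) {
    ks <- seq_len(N)
    c(0L, as.integer(rbind(-ks, ks)))
}

wrapPartner <- function(values, coverageDeg) {
    # view paired with the last measured one: the first view for a full
    # circle, its radial mirror for a semicircle (conjugate-view symmetry;
    # the radial grid is symmetric about 0, so the mirror is rev())
    if (coverageDeg == 360) values[, 1L] else rev(values[, 1L])
}

checkUniformAngles <- function(s) {
    a <- viewAngles(s)
    if (length(a) > 1L && max(abs(diff(a) - diff(a)[1L])) > 1e-9 * coverageDeg(s))
        stop("view angles must be uniformly spaced for view interpolation")
}

#' Linear angular interpolation of a sinogram
#'
#' Inserts \code{factor - 1} views between each adjacent measured pair by
#' convex combination: the inserted view at fraction \eqn{t = j/\mathrm{factor}}
#' is \eqn{(1-t)\,p(\cdot,m_1) + t\,p(\cdot,m_2)}; for \code{factor = 2} the
#' inserted view is the plain midpoint average.  The last measured view pairs
#' across the angular wrap (the first view for 360° coverage, its radial
#' mirror for 180°).  This is the baseline whose reconstruction splits into
#' the main image plus ghost copies rotated by the half-gap angle.
#'
#' @param s a real [Sinogram-class] with at least 2 uniformly spaced views.
#' @param factor integer >= 2; output has \code{factor * nViews(s)} views and
#'   \code{deltaGammaDeg(s) / factor} spacing.
#' @return The interpolated [Sinogram-class]; measured views pass through
#'   unchanged.
#' @seealso [sincViewInterp()], [upsampleSinogram()].
#' @export
linearViewInterp <- function(s, factor) {
    stopifnot(is(s, "Sinogram"))
    factor <- as.integer(factor)
    if (factor < 2L) stop("factor must be an integer >= 2")
    if (nViews(s) < 2L) stop("need at least 2 views")
    if (is.complex(sinogramValues(s)))
        stop("view interpolation expects a real sinogram; apply magnitude() first")
    checkUniformAngles(s)
    v <- sinogramValues(s)
    M <- ncol(v)
    out <- matrix(0, nrow(v), M * factor)
    for (m in seq_len(M)) {
        p1 <- v[, m]
        p2 <- if (m < M) v[, m + 1L] else wrapPartner(v, coverageDeg(s))
        for (j in seq_len(factor) - 1L) {
            t <- j / factor
            out[, (m - 1L) * factor + j + 1L] <-
                if (j == 0L) p1 else (1 - t) * p1 + t * p2
        }
    }
    refineAngles(s, out, factor)
}

# metadata for a factor-upsampled sinogram (uniform grids only)
refineAngles <- function(s, values, factor) {
    a0 <- viewAngles(s)[1L]
    step <- deltaGammaDeg(s) / factor
    Sinogram(values, anglesDeg = a0 + (seq_len(ncol(values)) - 1L) * step,
             coverageDeg = coverageDeg(s), deltaGammaDeg = step)
}

# Trigonometric (Dirichlet-kernel) upsampling of a periodic sequence by
# spectrum zero-padding.  DC and positive bins (incl. the Nyquist bin of
# even-length inputs) go to the head, pure negative bins to the tail; Re()
# symmetrizes the one-sided Nyquist term, so real input stays real and the
# original samples are reproduced exactly.
dirichletUpsample <- function(x, factor) {
    M <- length(x)
    P <- M * factor
    X <- stats::fft(x)
    Y <- complex(real = numeric(P), imaginary = numeric(P))
    h <- floor(M / 2) + 1L
    Y[seq_len(h)] <- X[seq_len(h)]
    if (M > h)
        Y[P - (M - h) + seq_len(M - h)] <- X[h + seq_len(M - h)]
    Re(stats::fft(Y, inverse = TRUE)) / M
}

#' Periodic-sinc angular interpolation of a sinogram
#'
#' Upsamples the view dimension row-by-row by zero-padding the discrete
#' Fourier spectrum along views (Dirichlet / periodic-sinc interpolation).
#' Measured views are reproduced exactly at their original positions.  For
#' 180° coverage the view axis is first extended to the full circle with the
#' radially mirrored views (conjugate symmetry) so that periodicity holds,
#' then the first half of the upsampled result is returned.
#'
#' @inheritParams linearViewInterp
#' @return The interpolated [Sinogram-class].
#' @export
sincViewInterp <- function(s, factor) {
    stopifnot(is(s, "Sinogram"))
    factor <- as.integer(factor)
    if (factor < 2L) stop("factor must be an integer >= 2")
    if (nViews(s) < 2L) stop("need at least 2 views")
    if (is.complex(sinogramValues(s)))
        stop("view interpolation expects a real sinogram; apply magnitude() first")
    checkUniformAngles(s)
    v <- sinogramValues(s)
    half <- coverageDeg(s) == 180
    if (half) v <- cbind(v, v[rev(seq_len(nrow(v))), , drop = FALSE])
    out <- t(apply(v, 1L, dirichletUpsample, factor = factor))
    if (half) out <- out[, seq_len(ncol(out) / 2L), drop = FALSE]
    refineAngles(s, out, factor)
}

#' Slope-sign regularizer for displacement matching
#'
#' Penalizes a candidate displacement \code{u} at radial index \code{n} when
#' the local slopes of the two views disagree in sign:
#' \deqn{R = [\mathrm{sign}(p_2(n) - p_2(n-1)) -
#'            \mathrm{sign}(p_1(n+u) - p_1(n+u-1))]^2 \in \{0, 1, 4\},}
#' with \code{sign(0) = 0}.  At the first radial index there is no slope
#' information and \code{R = 0}; samples requested outside the support are 0.
#'
#' @param p1,p2 equal-length numeric views (\code{p1} the source view the
#'   displacement indexes into, \code{p2} the target view).
#' @param n radial index (1-based).
#' @param u integer candidate displacement.
#' @return 0, 1 or 4.
#' @seealso [objectiveF()], [estimateDisplacement()].
#' @export
regularizerR <- function(p1, p2, n, u) {
    if (n <= 1L) return(0)
    s2 <- sign(p2[n] - p2[n - 1L])
    s1 <- sign(zfAt(p1, n + u) - zfAt(p1, n + u - 1L))
    (s2 - s1)^2
}

#' Displacement-matching objective
#'
#' The per-index objective minimized over integer displacements:
#' \deqn{F(u) = [p_2(n) - p_1(n+u)]^2 + \lambda R(u),}
#' a squared intensity mismatch plus the slope-sign penalty
#' ([regularizerR()]) weighted by \code{lambdaReg}.
#'
#' @inheritParams regularizerR
#' @param lambdaReg non-negative regularization weight \eqn{\lambda}.
#' @return Non-negative scalar.
#' @export
objectiveF <- function(p1, p2, n, u, lambdaReg = 0.001) {
    (p2[n] - zfAt(p1, n + u))^2 + lambdaReg * regularizerR(p1, p2, n, u)
}

#' Estimate the integer displacement function between two views
#'
#' For each radial index \code{n} independently, finds the integer
#' \eqn{u(n) \in [-N, N]} minimizing [objectiveF()] by exhaustive evaluation
#' of all \eqn{2N + 1} candidates -- a one-step search replacing iterative
#' descent.  The returned field satisfies
#' \eqn{p_2(n) \approx p_1(n + u(n))}: it maps the first view onto the
#' second.  Candidates are scanned in the order 0, -1, +1, -2, +2, ... and
#' the first strict minimum is kept, so ties prefer the smallest
#' displacement magnitude (and \code{-k} over \code{+k}).
#'
#' When \code{cfg@normalize} is on, both views are scaled by their joint
#' maximum modulus before evaluation, making the data/regularizer balance
#' independent of the intensity scale; the displacement field itself is
#' scale-free.
#'
#' @param p1 source view (numeric vector).
#' @param p2 target view, same length.
#' @param cfg an [EstimatorConfig-class]; defaults \eqn{N = 12},
#'   \eqn{\lambda = 0.001}, normalization on.
#' @param pair ordered view indices recorded in the result.
#' @return A [DisplacementField-class] with one entry per radial index,
#'   every \code{|u(n)| <= boundN}.
#' @examples
#' bump <- c(0, 0, 1, 2, 3, 2, 1, 0, 0, 0, 0, 0)
#' shifted <- c(0, 0, 0, 0, 0, 1, 2, 3, 2, 1, 0, 0)  # bump moved right by 3
#' displacement(estimateDisplacement(bump, shifted))  # -3 on the bump support
#' @export
estimateDisplacement <- function(p1, p2, cfg = estimatorConfig(),
                                 pair = c(1L, 2L)) {
    stopifnot(is(cfg, "EstimatorConfig"))
    if (length(p1) != length(p2))
        stop(sprintf("view lengths differ: %d vs %d", length(p1), length(p2)))
    if (cfg@normalize) {
        sc <- max(abs(c(p1, p2)))
        if (sc > 0) { p1 <- p1 / sc; p2 <- p2 / sc }
    }
    L <- length(p1)
    N <- cfg@boundN
    cand <- scanOrder(N)
    pad <- N + 2L
    p1pad <- c(numeric(pad), p1, numeric(pad))
    idx <- seq_len(L) + pad
    sign2 <- c(0, sign(diff(p2)))
    Fmat <- matrix(0, L, length(cand))
    for (j in seq_along(cand)) {
        u <- cand[j]
        s1 <- p1pad[idx + u]
        sl1 <- sign(s1 - p1pad[idx + u - 1L])
        R <- (sign2 - sl1)^2
        R[1L] <- 0
        Fmat[, j] <- (p2 - s1)^2 + cfg@lambdaReg * R
    }
    best <- max.col(-Fmat, ties.method = "first")
    DisplacementField(cand[best], boundN = N, pair = pair,
                      lambdaReg = cfg@lambdaReg)
}

#' Synthesize intermediate views from a displacement field
#'
#' Produces \code{M} views spanning the gap from the source view to its pair:
#' view \code{j} (0-based, fraction \eqn{t = j/M}) samples the source at the
#' fractionally displaced positions \eqn{x = n + t\,u(n)}.  With
#' \eqn{n_1 = \lfloor x \rfloor} and \eqn{\alpha = x - n_1}, the output is
#' the linear interpolation \eqn{(1-\alpha)\,p_1(n_1) + \alpha\,p_1(n_1+1)};
#' positions outside the support contribute 0.  Fraction 0 returns the source
#' view exactly, so measured views are never overwritten.  At the midpoint
#' (\eqn{t = 0.5}) the effective displacement is \eqn{0.5\,u(n)}.
#'
#' @param p1 source view (numeric vector).
#' @param u a [DisplacementField-class] whose length matches \code{p1}.
#' @param M integer >= 1: number of views returned (fractions
#'   \eqn{0, 1/M, \dots, (M-1)/M}).
#' @return List of \code{M} numeric vectors; element 1 is \code{p1} itself.
#' @export
synthesizeViews <- function(p1, u, M) {
    stopifnot(is(u, "DisplacementField"))
    M <- as.integer(M)
    if (M < 1L) stop("M must be an integer >= 1")
    uu <- displacement(u)
    if (length(uu) != length(p1))
        stop("displacement field length does not match the view length")
    L <- length(p1)
    out <- vector("list", M)
    out[[1L]] <- p1
    for (j in seq_len(M - 1L)) {
        t <- j / M
        x <- seq_len(L) + t * uu
        n1 <- floor(x)
        a <- x - n1
        out[[j + 1L]] <- (1 - a) * zfAt(p1, as.integer(n1)) +
            a * zfAt(p1, as.integer(n1) + 1L)
    }
    out
}

#' Fill un-measured views by displacement-function interpolation
#'
#' The full method: for every adjacent measured pair (and the wrap pair --
#' first view for 360° coverage, radially mirrored first view for 180°),
#' estimates the integer displacement field with [estimateDisplacement()]
#' and synthesizes \code{factor - 1} intermediate views with
#' [synthesizeViews()].  Measured views pass through bit-identical.  The
#' whole sinogram is scaled to unit maximum for the estimation step only
#' (synthesis is linear, so output intensities are untouched).
#'
#' @param s a real [Sinogram-class] with >= 2 uniformly spaced views.
#' @param factor integer >= 2: view multiplication factor (e.g. 24 measured
#'   views with \code{factor = 3} yield 72).
#' @param cfg an [EstimatorConfig-class].
#' @return A [Sinogram-class] with \code{factor * nViews(s)} views.
#' @examples
#' s24 <- sinogramFromPhantom(makePhantom("rotating_features"),
#'                            nViews = 24, coverageDeg = 180, nRadial = 128)
#' s72 <- upsampleSinogram(s24, 3)
#' nViews(s72)
#' @export
upsampleSinogram <- function(s, factor, cfg = estimatorConfig()) {
    stopifnot(is(s, "Sinogram"))
    factor <- as.integer(factor)
    if (factor < 2L) stop("factor must be an integer >= 2")
    if (nViews(s) < 2L) stop("need at least 2 views")
    if (is.complex(sinogramValues(s)))
        stop("view interpolation expects a real sinogram; apply magnitude() first")
    checkUniformAngles(s)
    v <- sinogramValues(s)
    M <- ncol(v)
    sc <- max(abs(v))
    vn <- if (cfg@normalize && sc > 0) v / sc else v
    ecfg <- estimatorConfig(boundN = cfg@boundN, lambdaReg = cfg@lambdaReg,
                            normalize = FALSE)
    out <- matrix(0, nrow(v), M * factor)
    for (m in seq_len(M)) {
        p2n <- if (m < M) vn[, m + 1L] else wrapPartner(vn, coverageDeg(s))
        u <- estimateDisplacement(vn[, m], p2n, ecfg, pair = c(m, m %% M + 1L))
        synth <- synthesizeViews(v[, m], u, factor)
        for (j in seq_len(factor))
            out[, (m - 1L) * factor + j] <- synth[[j]]
    }
    refineAngles(s, out, factor)
}
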