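# Parallel-beam filtered backprojection and the rotated-ghost analysis
# harness.

# Ram-Lak (ramp) filtering of one projection: zero-pad to the next power of
# two >= 2L and convolve (via FFT) with the band-limited ramp kernel
# h(0) = 1/(4 ds^2), h(odd n) = -1/(pi n ds)^2, h(even n) = 0.  Using the
# discrete spatial kernel rather than sampling |f| keeps the small positive
# DC term of the finite filter, which removes the intensity bias the
# truncated |f| version introduces.  ds is the radial sample spacing; the
# extra ds factor makes the convolution approximate the continuous filtering
# integral, so backprojection is quantitatively correct.
rampFilterColumn <- function(p, ds) {
    L <- length(p)
    P <- max(64L, 2L^ceiling(log2(2L * L)))
    nn <- c(seq(0L, P / 2L), seq(-P / 2L + 1L, -1L))
    h <- numeric(P)
    h[nn == 0L] <- 1 / (4 * ds^2)
    odd <- nn %% 2L != 0L
    h[odd] <- -1 / (pi * nn[odd] * ds)^2
    padded <- c(p, numeric(P - L))
    q <- Re(stats::fft(stats::fft(padded) * stats::fft(h),
                       inverse = TRUE)) / P * ds
    q[seq_len(L)]
}

# fold a 360-degree sinogram onto 180 degrees by averaging each view with the
# radial mirror of its conjugate partner at angle + 180
foldTo180 <- function(v, angles) {
    M <- ncol(v)
    if (M %% 2L != 0L)
        stop("360-degree sinograms need an even view count for conjugate folding")
    half <- M / 2L
    partner <- angles[half + seq_len(half)] - 180
    if (max(abs(partner - angles[seq_len(half)])) > 1e-6)
        stop("360-degree folding requires the view at angle + 180 for every view")
    flip <- v[rev(seq_len(nrow(v))), half + seq_len(half), drop = FALSE]
    list(values = (v[, seq_len(half), drop = FALSE] + flip) / 2,
         angles = angles[seq_len(half)])
}

#' Filtered backprojection of a real sinogram
#'
#' Parallel-beam FBP: each projection is ramp-filtered (frequency-domain
#' \eqn{|f|} filter, zero-padded to the next power of two) and backprojected
#' with linear interpolation onto a square grid covering \code{[-1, 1]^2};
#' pixels outside the inscribed unit circle -- the region radial data
#' determines -- are set to 0.  360°-coverage sinograms are first folded to
#' 180° by averaging conjugate (radially mirrored) view pairs.  The operator
#' is linear in the input.
#'
#' @param s a real [Sinogram-class] (complex input is an error; apply
#'   [magnitude()] first).
#' @param cfg an [FbpConfig-class]; \code{outputSize} sets the grid.
#' @param pixelSizeMm physical pixel size recorded in the output metadata.
#' @return A [ReconImage-class]; rows index \eqn{x}, columns \eqn{y}, both on
#'   \code{seq(-1, 1, length.out = outputSize)} (the [rasterizePhantom()]
#'   grid).
#' @examples
#' s <- sinogramFromPhantom(makePhantom("disk"), nViews = 90,
#'                          coverageDeg = 180, nRadial = 128)
#' img <- fbp(s, fbpConfig(outputSize = 64))
#' mean(pixels(img)[pixels(img) > 0.5])  # ~1, the disk intensity
#' @export
fbp <- function(s, cfg = fbpConfig(), pixelSizeMm = 1) {
    stopifnot(is(s, "Sinogram"), is(cfg, "FbpConfig"))
    if (is.complex(sinogramValues(s)))
        stop("fbp() expects a real sinogram; apply magnitude() first")
    v <- sinogramValues(s)
    angles <- viewAngles(s)
    if (coverageDeg(s) == 360) {
        folded <- foldTo180(v, angles)
        v <- folded$values
        angles <- folded$angles
    }
    L <- nrow(v)
    M <- ncol(v)
    ds <- 2 / (L - 1)
    sgrid <- radialPositions(L)
    size <- cfg@outputSize
    g <- radialPositions(size)
    X <- matrix(g, size, size)
    Y <- matrix(g, size, size, byrow = TRUE)
    acc <- matrix(0, size, size)
    for (m in seq_len(M)) {
        q <- rampFilterColumn(v[, m], ds)
        th <- angles[m] * pi / 180
        sxy <- X * cos(th) + Y * sin(th)
        acc <- acc + stats::approx(sgrid, q, xout = sxy, yleft = 0,
                                   yright = 0)$y
    }
    acc <- acc * (pi / M)
    acc[X^2 + Y^2 > 1] <- 0
    ReconImage(acc, pixelSizeMm = pixelSizeMm)
}

# bilinear resampling of img (rows = x, cols = y on radialPositions(size))
# at arbitrary coordinates; outside the grid -> 0
bilinearSample <- function(img, xs, ys) {
    size <- nrow(img)
    h <- 2 / (size - 1)
    fx <- (xs + 1) / h + 1
    fy <- (ys + 1) / h + 1
    i0 <- floor(fx); j0 <- floor(fy)
    ax <- fx - i0;  ay <- fy - j0
    out <- numeric(length(xs))
    pick <- function(i, j) {
        ok <- i >= 1 & i <= size & j >= 1 & j <= size
        v <- numeric(length(i))
        v[ok] <- img[cbind(i[ok], j[ok])]
        v
    }
    (1 - ax) * (1 - ay) * pick(i0, j0) +
        ax * (1 - ay) * pick(i0 + 1L, j0) +
        (1 - ax) * ay * pick(i0, j0 + 1L) +
        ax * ay * pick(i0 + 1L, j0 + 1L)
}

#' Rotate a reconstructed image about the grid center
#'
#' Bilinear resampling on the shared \code{[-1, 1]^2} grid; regions rotated
#' in from outside the grid are 0.
#'
#' @param img a [ReconImage-class].
#' @param angleDeg rotation angle in degrees (the image content moves the way
#'   the phantom moves when every view angle is increased by
#'   \code{angleDeg}).
#' @return A [ReconImage-class] of the same size.
#' @export
rotateImage <- function(img, angleDeg) {
    stopifnot(is(img, "ReconImage"))
    p <- pixels(img)
    size <- nrow(p)
    g <- radialPositions(size)
    X <- matrix(g, size, size)
    Y <- matrix(g, size, size, byrow = TRUE)
    th <- angleDeg * pi / 180
    # value at x comes from the source point R(-th) x
    xs <- cos(th) * X + sin(th) * Y
    ys <- -sin(th) * X + cos(th) * Y
    out <- matrix(bilinearSample(p, as.vector(xs), as.vector(ys)),
                  size, size)
    ReconImage(out, pixelSizeMm = pixelSizeMm(img))
}

#' Decompose an interpolated reconstruction into main and rotated ghosts
#'
#' Least-squares fit of \code{interp} against the span of \code{main} and its
#' two rotations by \eqn{\pm\Delta\gamma}:
#' \deqn{\mathrm{interp} \approx w_0\,\mathrm{main} +
#'   w_+\,\mathrm{rot}(\mathrm{main}, +\Delta\gamma) +
#'   w_-\,\mathrm{rot}(\mathrm{main}, -\Delta\gamma).}
#' Linear angular interpolation of an under-sampled sinogram reconstructs to
#' approximately the main image plus half-weight copies rotated by the
#' half-gap angle, so the fitted \eqn{(w_0, w_+, w_-)} quantify the rotated
#' shadow artifact; a method that suppresses it yields small \eqn{w_\pm}.
#'
#' The fit is restricted to pixels inside the unit circle where the two
#' rotated copies actually differ (by more than \code{sensitivity} times the
#' largest such difference).  Pixels the rotation leaves unchanged -- the
#' rotationally symmetric bulk of the object and most of the view-sampling
#' streak texture -- carry no information about the ghost weights but make
#' the three regressors nearly collinear, which lets the fit launder
#' streak-level differences into spurious ghost mass; dropping them makes
#' the weights identifiable.  (With \code{sensitivity = 0} the fit uses the
#' whole disk.)
#'
#' @param main reference [ReconImage-class] (e.g. the under-sampled-view
#'   reconstruction).
#' @param interp same-size [ReconImage-class] to decompose.
#' @param deltaGammaDeg ghost rotation angle \eqn{\Delta\gamma} in degrees.
#' @param sensitivity fraction of the maximal rotation-induced pixel change
#'   below which pixels are excluded from the fit (default 0.1).
#' @return Named numeric vector \code{c(w0, wPlus, wMinus)}.
#' @export
rotatedGhostDecomposition <- function(main, interp, deltaGammaDeg,
                                      sensitivity = 0.1) {
    stopifnot(is(main, "ReconImage"), is(interp, "ReconImage"))
    if (!identical(dim(pixels(main)), dim(pixels(interp))))
        stop("main and interp images must have the same size")
    size <- nrow(pixels(main))
    g <- radialPositions(size)
    mask <- matrix(g, size, size)^2 + matrix(g, size, size, byrow = TRUE)^2 <= 1
    plus <- pixels(rotateImage(main, deltaGammaDeg))
    minus <- pixels(rotateImage(main, -deltaGammaDeg))
    if (sensitivity > 0) {
        dd <- abs(plus - minus)
        keep <- mask & dd > sensitivity * max(dd)
        # degenerate case (rotation-invariant image): keep the full disk
        if (sum(keep) >= 3L * size) mask <- keep
    }
    A <- cbind(pixels(main)[mask], plus[mask], minus[mask])
    w <- stats::lsfit(A, pixels(interp)[mask], intercept = FALSE)$coefficients
    names(w) <- c("w0", "wPlus", "wMinus")
    w
}
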