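# Spoke-wise Fourier transforms, magnitude reduction, view under-sampling,
# and lossless container I/O.

# Radial sample positions shared package-wide: n_radial points spanning
# [-1, 1] in object units, symmetric about 0 so the conjugate (theta + 180)
# view is the exact reversal.
radialPositions <- function(n) seq(-1, 1, length.out = n)

# Centered DFT pair.  Spokes store DC at 0-based index floor(L/2), so a
# center-shift wraps it to index 0 before the FFT and back afterwards.
centeredIfft <- function(col) {
    n <- length(col)
    pracma::fftshift(stats::fft(pracma::ifftshift(col), inverse = TRUE)) / n
}

centeredFft <- function(col) {
    pracma::fftshift(stats::fft(pracma::ifftshift(col)))
}

#' Sinogram from radial k-space by spoke-wise inverse Fourier transform
#'
#' Applies a centered 1D inverse discrete Fourier transform to each spoke
#' (column).  The DC sample of a spoke maps to the central radial index
#' (0-based \code{floor(readoutLen/2)}), so projections line up across views
#' for displacement matching.  By the projection-slice theorem the result is
#' the (complex) spatial-domain sinogram.
#'
#' @param k a [RadialKSpace-class] object with at least one view and
#'   \code{readoutLen >= 2}.
#' @return A complex [Sinogram-class] sharing the input's angular metadata.
#'   Apply [magnitude()] before displacement estimation or [fbp()].
#' @seealso [kspaceFromSinogram()] for the exact inverse.
#' @examples
#' s0 <- sinogramFromPhantom(makePhantom("disk"), nViews = 8, nRadial = 32)
#' k  <- kspaceFromSinogram(s0)
#' s1 <- magnitude(ifftRadial(k))
#' max(abs(sinogramValues(s1) - sinogramValues(s0)))  # ~1e-16
#' @export
ifftRadial <- function(k) {
    stopifnot(is(k, "RadialKSpace"))
    if (nViews(k) == 0L)
        stop("no views: k-space container holds zero spokes")
    if (readoutLen(k) < 2L)
        stop("readout length must be at least 2")
    v <- apply(kspaceSamples(k), 2L, centeredIfft)
    Sinogram(v, anglesDeg = viewAngles(k), coverageDeg = coverageDeg(k),
             deltaGammaDeg = coverageDeg(k) / nViews(k))
}

#' @rdname magnitude
setMethod("magnitude", "Sinogram", function(x) {
    Sinogram(Mod(sinogramValues(x)), anglesDeg = viewAngles(x),
             coverageDeg = coverageDeg(x), deltaGammaDeg = deltaGammaDeg(x))
})

#' Keep every k-th view of a sinogram
#'
#' Emulates sparse angular acquisition by retaining views
#' \code{1, 1 + keepEvery, 1 + 2 keepEvery, ...} and scaling the nominal
#' inter-view spacing accordingly (e.g. 72 views reduced to 24 with
#' \code{keepEvery = 3}).
#'
#' @param s a [Sinogram-class].
#' @param keepEvery positive integer; the view count must be divisible by it.
#' @return The under-sampled [Sinogram-class].
#' @export
undersampleViews <- function(s, keepEvery) {
    stopifnot(is(s, "Sinogram"))
    keepEvery <- as.integer(keepEvery)
    if (keepEvery < 1L) stop("keepEvery must be a positive integer")
    m <- nViews(s)
    if (m %% keepEvery != 0L)
        stop(sprintf("view count %d is not divisible by keepEvery = %d",
                     m, keepEvery))
    idx <- seq(1L, m, by = keepEvery)
    Sinogram(sinogramValues(s)[, idx, drop = FALSE],
             anglesDeg = viewAngles(s)[idx], coverageDeg = coverageDeg(s),
             deltaGammaDeg = deltaGammaDeg(s) * keepEvery)
}

#' Write a k-space or sinogram container to disk
#'
#' Containers are stored as R serialization (\code{.rds}) of a named list:
#' \code{kind} (\code{"kspace"} or \code{"sinogram"}), the data matrix
#' (\code{samples} or \code{values}), \code{anglesDeg}, \code{coverageDeg},
#' and for sinograms \code{deltaGammaDeg}.  The round trip is lossless for
#' both real and complex data and all metadata.
#'
#' @param obj a [RadialKSpace-class] or [Sinogram-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readContainer()], [exportNifti()] for images.
#' @export
writeContainer <- function(obj, path) {
    payload <-
        if (is(obj, "RadialKSpace"))
            list(kind = "kspace", samples = kspaceSamples(obj),
                 anglesDeg = viewAngles(obj), coverageDeg = coverageDeg(obj))
        else if (is(obj, "Sinogram"))
            list(kind = "sinogram", values = sinogramValues(obj),
                 anglesDeg = viewAngles(obj), coverageDeg = coverageDeg(obj),
                 deltaGammaDeg = deltaGammaDeg(obj))
        else stop("writeContainer() handles RadialKSpace and Sinogram objects")
    saveRDS(payload, path)
    invisible(path)
}

#' Read a k-space or sinogram container from disk
#'
#' @param path file written by [writeContainer()].
#' @return A [RadialKSpace-class] or [Sinogram-class], depending on the
#'   stored \code{kind}.
#' @export
readContainer <- function(path) {
    payload <- readRDS(path)
    if (!is.list(payload) || is.null(payload$kind))
        stop("not a radialfill container: missing 'kind' field")
    need <- switch(payload$kind,
        kspace = c("samples", "anglesDeg", "coverageDeg"),
        sinogram = c("values", "anglesDeg", "coverageDeg", "deltaGammaDeg"),
        stop(sprintf("unknown container kind '%s'", payload$kind)))
    missing <- setdiff(need, names(payload))
    if (length(missing))
        stop(sprintf("container is missing required field(s): %s",
                     paste(missing, collapse = ", ")))
    if (payload$kind == "kspace")
        RadialKSpace(payload$samples, payload$anglesDeg, payload$coverageDeg)
    else
        Sinogram(payload$values, payload$anglesDeg, payload$coverageDeg,
                 payload$deltaGammaDeg)
}

#' Export a reconstructed image as NIfTI
#'
#' @param img a [ReconImage-class].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
exportNifti <- function(img, path) {
    stopifnot(is(img, "ReconImage"))
    RNifti::writeNifti(
        RNifti::asNifti(pixels(img),
                        pixdim = rep(pixelSizeMm(img), 2L)),
        path)
    invisible(path)
}
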