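#' @import methods
NULL

#' Radial k-space container
#'
#' Complex samples acquired on uniformly spaced radial lines (spokes) through
#' the k-space origin.  Column \code{m} holds one spoke; row \code{n} holds one
#' readout sample.  Spokes are stored frequency-centered: the DC sample sits at
#' 0-based row index \code{floor(readoutLen/2)}.
#'
#' @slot samples complex (or numeric) matrix, readout sample by view.
#' @slot anglesDeg numeric vector of per-view angles in degrees, strictly
#'   increasing within \code{[0, coverageDeg)}.
#' @slot coverageDeg total angular span of the acquisition, 180 or 360.
#'
#' @seealso [RadialKSpace()] for construction, [ifftRadial()] to obtain the
#'   sinogram, [kspaceFromSinogram()] for the exact inverse.
#' @export
setClass("RadialKSpace",
    representation(samples = "matrix",
                   anglesDeg = "numeric",
                   coverageDeg = "numeric"))

setValidity("RadialKSpace", function(object) {
    msg <- character()
    if (ncol(object@samples) != length(object@anglesDeg))
        msg <- c(msg, sprintf("number of angles (%d) must equal number of sample columns (%d)",
                              length(object@anglesDeg), ncol(object@samples)))
    if (length(object@coverageDeg) != 1L || !(object@coverageDeg %in% c(180, 360)))
        msg <- c(msg, "coverageDeg must be 180 or 360")
    if (length(object@anglesDeg)) {
        if (any(diff(object@anglesDeg) <= 0))
            msg <- c(msg, "anglesDeg must be strictly increasing")
        if (min(object@anglesDeg) < 0 || max(object@anglesDeg) >= object@coverageDeg)
            msg <- c(msg, "anglesDeg must lie within [0, coverageDeg)")
    }
    if (nrow(object@samples) < 1L)
        msg <- c(msg, "readout length must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a RadialKSpace object
#'
#' @param samples complex matrix, readout sample (rows) by view (columns).
#' @param anglesDeg per-view angles in degrees.
#' @param coverageDeg total angular span, 180 (default) or 360.
#' @return A [RadialKSpace-class] object.
#' @examples
#' k <- RadialKSpace(matrix(1 + 0i, 8, 4), anglesDeg = c(0, 45, 90, 135))
#' readoutLen(k)
#' @export
RadialKSpace <- function(samples, anglesDeg, coverageDeg = 180) {
    if (!is.matrix(samples)) samples <- as.matrix(samples)
    new("RadialKSpace", samples = samples, anglesDeg = as.numeric(anglesDeg),
        coverageDeg = as.numeric(coverageDeg))
}

#' Sinogram container
#'
#' A 2D array \eqn{p(n, m)} of projection values indexed by radial position
#' \eqn{n} (rows) and view \eqn{m} (columns), with angular metadata.  Values
#' may be complex (straight out of [ifftRadial()]) or real (after
#' [magnitude()], or analytic phantom projections).  Radial sample positions
#' are taken as \code{seq(-1, 1, length.out = nrow)} in object units.
#'
#' @slot values matrix \eqn{p(n, m)}, real or complex.
#' @slot anglesDeg per-view angles in degrees.
#' @slot coverageDeg 180 or 360.  For 360 the angle axis is periodic; for 180
#'   the view at \eqn{\theta + 180^\circ} is the radial mirror of the view at
#'   \eqn{\theta} (conjugate-view symmetry).
#' @slot deltaGammaDeg nominal inter-view angular spacing in degrees.
#'
#' @seealso [Sinogram()], [sinogramFromPhantom()], [upsampleSinogram()],
#'   [fbp()].
#' @export
setClass("Sinogram",
    representation(values = "matrix",
                   anglesDeg = "numeric",
                   coverageDeg = "numeric",
                   deltaGammaDeg = "numeric"))

setValidity("Sinogram", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@anglesDeg))
        msg <- c(msg, sprintf("number of angles (%d) must equal number of view columns (%d)",
                              length(object@anglesDeg), ncol(object@values)))
    if (length(object@coverageDeg) != 1L || !(object@coverageDeg %in% c(180, 360)))
        msg <- c(msg, "coverageDeg must be 180 or 360")
    if (length(object@deltaGammaDeg) != 1L || object@deltaGammaDeg <= 0)
        msg <- c(msg, "deltaGammaDeg must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a Sinogram object
#'
#' @param values matrix of projection values, radial index by view.
#' @param anglesDeg per-view angles in degrees; defaults to a uniform grid
#'   over \code{[0, coverageDeg)}.
#' @param coverageDeg angular span, 180 (default) or 360.
#' @param deltaGammaDeg nominal inter-view spacing; defaults to
#'   \code{coverageDeg / ncol(values)}.
#' @return A [Sinogram-class] object.
#' @examples
#' s <- Sinogram(matrix(runif(64 * 12), 64, 12), coverageDeg = 180)
#' deltaGammaDeg(s)
#' @export
Sinogram <- function(values, anglesDeg = NULL, coverageDeg = 180,
                     deltaGammaDeg = NULL) {
    if (!is.matrix(values)) values <- as.matrix(values)
    nv <- ncol(values)
    if (is.null(anglesDeg))
        anglesDeg <- seq(0, coverageDeg, length.out = nv + 1L)[seq_len(nv)]
    if (is.null(deltaGammaDeg))
        deltaGammaDeg <- coverageDeg / nv
    new("Sinogram", values = values, anglesDeg = as.numeric(anglesDeg),
        coverageDeg = as.numeric(coverageDeg),
        deltaGammaDeg = as.numeric(deltaGammaDeg))
}

#' Integer displacement field relating two sinogram views
#'
#' The per-radial-index integer shift \eqn{u(n)} connecting an ordered pair of
#' views so that \eqn{p(n, m_2) \approx p(n + u(n), m_1)}.  Every entry is
#' bounded, \eqn{|u(n)| \le N}.
#'
#' @slot u integer vector over the radial index.
#' @slot boundN positive integer search bound \eqn{N}.
#' @slot pair ordered view indices \code{c(m1, m2)} the field connects.
#' @slot lambdaReg regularization weight \eqn{\lambda} used during estimation.
#'
#' @seealso [estimateDisplacement()], [synthesizeViews()].
#' @export
setClass("DisplacementField",
    representation(u = "integer",
                   boundN = "integer",
                   pair = "integer",
                   lambdaReg = "numeric"))

setValidity("DisplacementField", function(object) {
    msg <- character()
    if (object@boundN < 1L)
        msg <- c(msg, "boundN must be a positive integer")
    if (length(object@u) && max(abs(object@u)) > object@boundN)
        msg <- c(msg, "all |u(n)| must be <= boundN")
    if (length(object@pair) != 2L || object@pair[1L] == object@pair[2L])
        msg <- c(msg, "pair must hold two distinct view indices")
    if (length(object@lambdaReg) != 1L || object@lambdaReg < 0)
        msg <- c(msg, "lambdaReg must be a non-negative scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a DisplacementField object
#'
#' Usually produced by [estimateDisplacement()]; direct construction is mainly
#' useful for testing [synthesizeViews()] with known fields.
#'
#' @param u integer displacement per radial index.
#' @param boundN search bound \eqn{N} (every \code{|u|} must be within it).
#' @param pair ordered pair of view indices, default \code{c(1L, 2L)}.
#' @param lambdaReg regularization weight recorded with the field.
#' @return A [DisplacementField-class] object.
#' @export
DisplacementField <- function(u, boundN = max(1L, max(abs(u))),
                              pair = c(1L, 2L), lambdaReg = 0.001) {
    if (any(u != round(u)))
        stop("displacement entries must be integers")
    new("DisplacementField", u = as.integer(round(u)),
        boundN = as.integer(boundN), pair = as.integer(pair),
        lambdaReg = as.numeric(lambdaReg))
}

#' Reconstructed image container
#'
#' Square real-valued pixel grid produced by [fbp()], covering the
#' \code{[-1, 1]^2} field of view inscribed in the radial support.
#'
#' @slot pixels square numeric matrix of finite values.
#' @slot pixelSizeMm physical pixel size, metadata only.
#' @export
setClass("ReconImage",
    representation(pixels = "matrix", pixelSizeMm = "numeric"))

setValidity("ReconImage", function(object) {
    msg <- character()
    if (nrow(object@pixels) != ncol(object@pixels))
        msg <- c(msg, "pixel matrix must be square")
    if (!all(is.finite(object@pixels)))
        msg <- c(msg, "pixel values must be finite")
    if (length(object@pixelSizeMm) != 1L || object@pixelSizeMm <= 0)
        msg <- c(msg, "pixelSizeMm must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' Construct a ReconImage object
#'
#' @param pixels square numeric matrix.
#' @param pixelSizeMm physical pixel size in mm (metadata only; default 1).
#' @return A [ReconImage-class] object.
#' @export
ReconImage <- function(pixels, pixelSizeMm = 1) {
    new("ReconImage", pixels = as.matrix(pixels),
        pixelSizeMm = as.numeric(pixelSizeMm))
}

#' Analytic ellipse phantom
#'
#' A phantom is a list of constant-intensity ellipses; intensities add where
#' ellipses overlap (negative \code{rho} carves holes, as in the classic
#' head phantom).  Projections have a closed form, so sinograms can be
#' generated analytically without rasterization error.
#'
#' @slot ellipses data.frame with columns \code{cx, cy} (center), \code{a, b}
#'   (semi-axes, positive), \code{phiDeg} (rotation) and \code{rho} (additive
#'   intensity), one row per ellipse.  All geometry is in object units where
#'   the field of view is the unit square \code{[-1, 1]^2}.
#' @seealso [makePhantom()], [analyticProjection()], [sinogramFromPhantom()],
#'   [rasterizePhantom()].
#' @export
setClass("Phantom", representation(ellipses = "data.frame"))

setValidity("Phantom", function(object) {
    e <- object@ellipses
    msg <- character()
    need <- c("cx", "cy", "a", "b", "phiDeg", "rho")
    if (!all(need %in% names(e)))
        msg <- c(msg, paste("ellipse table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(e) < 1L) msg <- c(msg, "phantom needs at least one ellipse")
        if (nrow(e) && any(e$a <= 0 | e$b <= 0))
            msg <- c(msg, "semi-axes a, b must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Phantom from an ellipse table
#'
#' @param ellipses data.frame (or coercible) with columns
#'   \code{cx, cy, a, b, phiDeg, rho}.
#' @return A [Phantom-class] object.
#' @examples
#' disk <- Phantom(data.frame(cx = 0, cy = 0, a = 0.6, b = 0.6,
#'                            phiDeg = 0, rho = 1))
#' analyticProjection(disk, 0, 0)  # chord through the center: 2 * rho * r
#' @export
Phantom <- function(ellipses) {
    new("Phantom", ellipses = as.data.frame(ellipses))
}

#' Displacement-estimator settings
#'
#' Bundles the tunables of [estimateDisplacement()] and
#' [upsampleSinogram()]: the integer search bound \eqn{N}, the regularization
#' weight \eqn{\lambda}, and whether the views are rescaled to unit maximum
#' before estimation (the squared-difference data term is intensity-scale
#' dependent while \eqn{\lambda} is fixed, so the balance is made
#' scale-invariant by normalizing).
#'
#' @slot boundN positive integer \eqn{N}; candidate shifts span
#'   \eqn{[-N, N]}.
#' @slot lambdaReg non-negative \eqn{\lambda}.
#' @slot normalize logical; rescale to unit maximum before estimation.
#' @export
setClass("EstimatorConfig",
    representation(boundN = "integer", lambdaReg = "numeric",
                   normalize = "logical"))

setValidity("EstimatorConfig", function(object) {
    msg <- character()
    if (length(object@boundN) != 1L || object@boundN < 1L)
        msg <- c(msg, "boundN must be a positive integer")
    if (length(object@lambdaReg) != 1L || object@lambdaReg < 0)
        msg <- c(msg, "lambdaReg must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct an EstimatorConfig
#'
#' Defaults follow the reference protocol for this class of data:
#' \code{boundN = 12}, \code{lambdaReg = 0.001}, normalization on.
#'
#' @param boundN integer search bound \eqn{N}.
#' @param lambdaReg regularization weight \eqn{\lambda}.
#' @param normalize rescale views to unit maximum before estimation.
#' @return An [EstimatorConfig-class] object.
#' @export
estimatorConfig <- function(boundN = 12L, lambdaReg = 0.001, normalize = TRUE) {
    new("EstimatorConfig", boundN = as.integer(boundN),
        lambdaReg = as.numeric(lambdaReg), normalize = as.logical(normalize))
}

#' Filtered-backprojection settings
#'
#' @slot filterName projection filter; only \code{"ramp"} (Ram-Lak) is
#'   provided.
#' @slot outputSize side length of the square output grid, at least 8.
#' @slot interp backprojection sampling; only \code{"linear"}.
#' @export
setClass("FbpConfig",
    representation(filterName = "character", outputSize = "integer",
                   interp = "character"))

setValidity("FbpConfig", function(object) {
    msg <- character()
    if (!identical(object@filterName, "ramp"))
        msg <- c(msg, "filterName must be \"ramp\"")
    if (length(object@outputSize) != 1L || object@outputSize < 8L)
        msg <- c(msg, "outputSize must be an integer >= 8")
    if (!identical(object@interp, "linear"))
        msg <- c(msg, "interp must be \"linear\"")
    if (length(msg)) msg else TRUE
})

#' Construct an FbpConfig
#'
#' @param outputSize side length of the square output image (default 256).
#' @param filterName projection filter, \code{"ramp"}.
#' @param interp backprojection sampling, \code{"linear"}.
#' @return An [FbpConfig-class] object.
#' @export
fbpConfig <- function(outputSize = 256L, filterName = "ramp",
                      interp = "linear") {
    new("FbpConfig", filterName = filterName,
        outputSize = as.integer(outputSize), interp = interp)
}
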