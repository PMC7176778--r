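# Experiment driver: error metrics, the simulation and patient-style
# protocols, and the k-space-to-image chain.

asArray <- function(x) {
    if (is(x, "Sinogram")) sinogramValues(x)
    else if (is(x, "ReconImage")) pixels(x)
    else if (is(x, "RadialKSpace")) kspaceSamples(x)
    else x
}

checkSameShape <- function(a, b) {
    if (!identical(dim(a), dim(b)) || length(a) != length(b))
        stop("inputs have different shapes")
}

#' Error metrics between two arrays
#'
#' Element-wise comparison of two equal-shape arrays (plain matrices,
#' [Sinogram-class] or [ReconImage-class] objects): the maximal absolute
#' error, the sum of absolute errors, and the root mean square error.  All
#' three are symmetric in their arguments.
#'
#' @param a,b arrays of identical shape.
#' @return A non-negative scalar.
#' @examples
#' maxAbsError(c(3, 0), c(0, 4))  # 4
#' sumAbsError(c(3, 0), c(0, 4))  # 7
#' rmse(c(3, 0), c(0, 4))         # sqrt(12.5)
#' @export
maxAbsError <- function(a, b) {
    a <- asArray(a); b <- asArray(b)
    checkSameShape(a, b)
    max(abs(a - b))
}

#' @rdname maxAbsError
#' @export
sumAbsError <- function(a, b) {
    a <- asArray(a); b <- asArray(b)
    checkSameShape(a, b)
    sum(abs(a - b))
}

#' @rdname maxAbsError
#' @export
rmse <- function(a, b) {
    a <- asArray(a); b <- asArray(b)
    checkSameShape(a, b)
    sqrt(mean((a - b)^2))
}

#' Experiment configuration
#'
#' Bundles everything one protocol run needs: the phantom, the full and
#' measured view counts, the angular coverage, the radial resolution, the
#' sinogram-filling methods to compare, and the estimator/FBP settings.
#'
#' @slot phantomName packaged phantom name (see [makePhantom()]).
#' @slot nViewsFull views in the full (reference) sinogram.
#' @slot nViewsMeasured views actually measured; must divide
#'   \code{nViewsFull}.
#' @slot coverageDeg 180 or 360.
#' @slot nRadial radial samples per view.
#' @slot methods subset of \code{"displacement"}, \code{"linear"},
#'   \code{"sinc"}, \code{"none"} (\code{"none"} reconstructs straight from
#'   the measured views).
#' @slot estimator an [EstimatorConfig-class].
#' @slot fbp an [FbpConfig-class].
#' @slot seed integer seed (only the optional noise generator consumes it).
#' @slot normalizeRmse scale both images by the gold standard's maximum
#'   before image RMSE.
#' @slot outputDir directory for CSV/manifest/NIfTI output, or \code{""} to
#'   skip writing.
#' @export
setClass("ExperimentConfig",
    representation(phantomName = "character", nViewsFull = "integer",
                   nViewsMeasured = "integer", coverageDeg = "numeric",
                   nRadial = "integer", methods = "character",
                   estimator = "EstimatorConfig", fbp = "FbpConfig",
                   seed = "integer", normalizeRmse = "logical",
                   outputDir = "character"))

setValidity("ExperimentConfig", function(object) {
    msg <- character()
    if (object@nViewsFull %% object@nViewsMeasured != 0L)
        msg <- c(msg, sprintf("nViewsFull (%d) must be divisible by nViewsMeasured (%d)",
                              object@nViewsFull, object@nViewsMeasured))
    bad <- setdiff(object@methods,
                   c("displacement", "linear", "sinc", "none"))
    if (length(bad))
        msg <- c(msg, paste("unknown method(s):", paste(bad, collapse = ", ")))
    if (!(object@coverageDeg %in% c(180, 360)))
        msg <- c(msg, "coverageDeg must be 180 or 360")
    if (length(msg)) msg else TRUE
})

#' Construct an ExperimentConfig
#'
#' Defaults encode the first simulation protocol: the packaged
#' "rotating_features" phantom, 180 views over 360° with every third view
#' measured (60), 256 radial samples, all three filling methods plus the
#' plain under-sampled reconstruction.
#'
#' @param phantomName,nViewsFull,nViewsMeasured,coverageDeg,nRadial,methods
#'   see [ExperimentConfig-class].
#' @param estimator,fbp,seed,normalizeRmse,outputDir see
#'   [ExperimentConfig-class].
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(phantomName = "rotating_features",
                             nViewsFull = 180L, nViewsMeasured = 60L,
                             coverageDeg = 360, nRadial = 256L,
                             methods = c("displacement", "linear", "sinc",
                                         "none"),
                             estimator = estimatorConfig(),
                             fbp = fbpConfig(), seed = 1L,
                             normalizeRmse = TRUE, outputDir = "") {
    new("ExperimentConfig", phantomName = phantomName,
        nViewsFull = as.integer(nViewsFull),
        nViewsMeasured = as.integer(nViewsMeasured),
        coverageDeg = as.numeric(coverageDeg), nRadial = as.integer(nRadial),
        methods = methods, estimator = estimator, fbp = fbp,
        seed = as.integer(seed), normalizeRmse = as.logical(normalizeRmse),
        outputDir = outputDir)
}

fillSinogram <- function(s, factor, method, estimator) {
    switch(method,
        displacement = upsampleSinogram(s, factor, estimator),
        linear = linearViewInterp(s, factor),
        sinc = sincViewInterp(s, factor),
        none = s,
        stop(sprintf("unknown filling method '%s'", method)))
}

normalizedRmse <- function(img, gold, normalize = TRUE) {
    a <- asArray(img); g <- asArray(gold)
    checkSameShape(a, g)
    if (normalize) {
        sc <- max(abs(g))
        if (sc > 0) { a <- a / sc; g <- g / sc }
    }
    sqrt(mean((a - g)^2))
}

#' Run one simulation experiment
#'
#' The full protocol on analytic data: generate the noise-free full-view
#' sinogram of the configured phantom, keep every
#' \code{nViewsFull/nViewsMeasured}-th view, fill the gap with each requested
#' method, and score each result twice -- sinogram errors
#' ([maxAbsError()], [sumAbsError()]) against the analytic full sinogram,
#' and image [rmse()] of the FBP reconstruction against the full-view FBP
#' gold standard (normalized to the gold standard's maximum unless
#' \code{normalizeRmse} is off).  Method \code{"none"} skips filling and
#' reconstructs from the measured views alone (its sinogram errors are
#' \code{NA} unless no views are missing).  Runs are deterministic given the
#' configuration.
#'
#' If \code{outputDir} is set, writes \code{metrics.csv} (columns
#' \code{method, max_abs_err, sum_abs_err, rmse}), a \code{manifest.json}
#' logging every parameter, and per-method NIfTI images.
#'
#' @param cfg an [ExperimentConfig-class].
#' @return Invisibly, a list with \code{metrics} (data.frame), \code{gold}
#'   ([ReconImage-class]), \code{images} (named list of [ReconImage-class]),
#'   \code{sinograms} (named list), \code{full} and \code{measured}
#'   sinograms.
#' @examples
#' cfg <- experimentConfig(nViewsFull = 36L, nViewsMeasured = 12L,
#'                         nRadial = 64L, fbp = fbpConfig(64L),
#'                         methods = c("displacement", "linear"))
#' rep <- runSimulationExperiment(cfg)
#' rep$metrics
#' @export
runSimulationExperiment <- function(cfg) {
    stopifnot(is(cfg, "ExperimentConfig"))
    ph <- makePhantom(cfg@phantomName)
    full <- sinogramFromPhantom(ph, cfg@nViewsFull, cfg@coverageDeg,
                                cfg@nRadial)
    factor <- cfg@nViewsFull %/% cfg@nViewsMeasured
    measured <- undersampleViews(full, factor)
    gold <- fbp(full, cfg@fbp)
    metrics <- data.frame(method = character(), max_abs_err = numeric(),
                          sum_abs_err = numeric(), rmse = numeric(),
                          stringsAsFactors = FALSE)
    images <- list()
    sinos <- list()
    for (method in cfg@methods) {
        filled <- if (method == "none") measured
                  else fillSinogram(measured, factor, method, cfg@estimator)
        img <- fbp(filled, cfg@fbp)
        full_match <- nViews(filled) == nViews(full)
        metrics <- rbind(metrics, data.frame(
            method = method,
            max_abs_err = if (full_match) maxAbsError(filled, full) else NA_real_,
            sum_abs_err = if (full_match) sumAbsError(filled, full) else NA_real_,
            rmse = normalizedRmse(img, gold, cfg@normalizeRmse),
            stringsAsFactors = FALSE))
        images[[method]] <- img
        sinos[[method]] <- filled
    }
    if (nzchar(cfg@outputDir)) {
        dir.create(cfg@outputDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(metrics,
                         file.path(cfg@outputDir, "metrics.csv"),
                         row.names = FALSE)
        manifest <- list(
            phantom = cfg@phantomName, n_views_full = cfg@nViewsFull,
            n_views_measured = cfg@nViewsMeasured,
            coverage_deg = cfg@coverageDeg, n_radial = cfg@nRadial,
            methods = cfg@methods, bound_N = cfg@estimator@boundN,
            lambda = cfg@estimator@lambdaReg,
            normalize = cfg@estimator@normalize,
            fbp_filter = cfg@fbp@filterName,
            output_size = cfg@fbp@outputSize, seed = cfg@seed,
            normalize_rmse = cfg@normalizeRmse)
        jsonlite::write_json(manifest,
                             file.path(cfg@outputDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        exportNifti(gold, file.path(cfg@outputDir, "gold.nii.gz"))
        for (method in names(images))
            exportNifti(images[[method]],
                        file.path(cfg@outputDir,
                                  sprintf("recon_%s.nii.gz", method)))
    }
    invisible(list(metrics = metrics, gold = gold, images = images,
                   sinograms = sinos, full = full, measured = measured))
}

#' Reconstruct an image from under-sampled radial k-space
#'
#' The measurement-to-image chain: spoke-wise inverse Fourier transform
#' ([ifftRadial()]), [magnitude()], displacement-interpolated view filling
#' ([upsampleSinogram()]), and [fbp()].  If a reference is supplied (a real
#' [Sinogram-class] compared before reconstruction, or a
#' [ReconImage-class] compared after), the corresponding RMSE is reported.
#'
#' @param k a [RadialKSpace-class], or a path readable by
#'   [readContainer()].
#' @param factor view multiplication factor (e.g. 3 to fill 24 measured
#'   views to 72); 1 skips filling.
#' @param estimator an [EstimatorConfig-class].
#' @param fbpCfg an [FbpConfig-class].
#' @param reference optional [Sinogram-class] or [ReconImage-class].
#' @param normalizeRmse normalize to the reference maximum before RMSE.
#' @return A list with \code{image} ([ReconImage-class]), \code{sinogram}
#'   (the filled real sinogram) and, when a reference is given,
#'   \code{rmse}.
#' @export
runKspacePipeline <- function(k, factor = 3L, estimator = estimatorConfig(),
                              fbpCfg = fbpConfig(), reference = NULL,
                              normalizeRmse = TRUE) {
    if (is.character(k)) k <- readContainer(k)
    if (!is(k, "RadialKSpace"))
        stop("input must be a RadialKSpace or a container path holding one")
    s <- magnitude(ifftRadial(k))
    filled <- if (factor >= 2L) upsampleSinogram(s, factor, estimator) else s
    img <- fbp(filled, fbpCfg)
    out <- list(image = img, sinogram = filled)
    if (!is.null(reference)) {
        out$rmse <- if (is(reference, "Sinogram"))
            normalizedRmse(filled, reference, normalizeRmse)
        else normalizedRmse(img, reference, normalizeRmse)
    }
    out
}
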