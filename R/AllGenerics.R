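# Generics and accessors for the container classes.

#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))
#' @rdname accessors
#' @export
setGeneric("coverageDeg", function(x) standardGeneric("coverageDeg"))
#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))
#' @rdname accessors
#' @export
setGeneric("nRadial", function(x) standardGeneric("nRadial"))
#' @rdname accessors
#' @export
setGeneric("readoutLen", function(x) standardGeneric("readoutLen"))
#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setGeneric("kspaceSamples", function(x) standardGeneric("kspaceSamples"))
#' @rdname accessors
#' @export
setGeneric("deltaGammaDeg", function(x) standardGeneric("deltaGammaDeg"))
#' @rdname accessors
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))
#' @rdname accessors
#' @export
setGeneric("boundN", function(x) standardGeneric("boundN"))
#' @rdname accessors
#' @export
setGeneric("viewPair", function(x) standardGeneric("viewPair"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeMm", function(x) standardGeneric("pixelSizeMm"))
#' @rdname accessors
#' @export
setGeneric("ellipses", function(x) standardGeneric("ellipses"))

#' Element-wise modulus of a complex sinogram
#'
#' Reduces a complex spatial-domain sinogram (as returned by [ifftRadial()])
#' to a real one by taking the element-wise modulus; all angular metadata is
#' preserved.  Displacement estimation and filtered backprojection operate on
#' the magnitude sinogram; the phase is discarded.
#'
#' @param x a [Sinogram-class] (complex or real).
#' @return A real-valued [Sinogram-class].
#' @export
setGeneric("magnitude", function(x) standardGeneric("magnitude"))

#' Accessors for radialfill containers
#'
#' Read-only accessors for the S4 container classes: view angles and angular
#' metadata, matrix dimensions, and the underlying arrays.
#'
#' @param x a container object ([RadialKSpace-class], [Sinogram-class],
#'   [DisplacementField-class], [ReconImage-class] or [Phantom-class]).
#' @return The corresponding slot value (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
setMethod("viewAngles", "RadialKSpace", function(x) x@anglesDeg)
#' @rdname accessors
setMethod("viewAngles", "Sinogram", function(x) x@anglesDeg)
#' @rdname accessors
setMethod("coverageDeg", "RadialKSpace", function(x) x@coverageDeg)
#' @rdname accessors
setMethod("coverageDeg", "Sinogram", function(x) x@coverageDeg)
#' @rdname accessors
setMethod("nViews", "RadialKSpace", function(x) ncol(x@samples))
#' @rdname accessors
setMethod("nViews", "Sinogram", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nRadial", "Sinogram", function(x) nrow(x@values))
#' @rdname accessors
setMethod("readoutLen", "RadialKSpace", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("sinogramValues", "Sinogram", function(x) x@values)
#' @rdname accessors
setMethod("kspaceSamples", "RadialKSpace", function(x) x@samples)
#' @rdname accessors
setMethod("deltaGammaDeg", "Sinogram", function(x) x@deltaGammaDeg)
#' @rdname accessors
setMethod("displacement", "DisplacementField", function(x) x@u)
#' @rdname accessors
setMethod("boundN", "DisplacementField", function(x) x@boundN)
#' @rdname accessors
setMethod("boundN", "EstimatorConfig", function(x) x@boundN)
#' @rdname accessors
setMethod("viewPair", "DisplacementField", function(x) x@pair)
#' @rdname accessors
setMethod("pixels", "ReconImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSizeMm", "ReconImage", function(x) x@pixelSizeMm)
#' @rdname accessors
setMethod("ellipses", "Phantom", function(x) x@ellipses)

setMethod("show", "RadialKSpace", function(object) {
    cat(sprintf("RadialKSpace: %d readout samples x %d spokes over %g deg\n",
                nrow(object@samples), ncol(object@samples), object@coverageDeg))
    cat(sprintf("  storage: %s; angles %g..%g deg\n",
                if (is.complex(object@samples)) "complex" else "real",
                if (length(object@anglesDeg)) min(object@anglesDeg) else NA,
                if (length(object@anglesDeg)) max(object@anglesDeg) else NA))
    invisible(NULL)
})

setMethod("show", "Sinogram", function(object) {
    cat(sprintf("Sinogram: %d radial samples x %d views over %g deg (d-gamma %g deg)\n",
                nrow(object@values), ncol(object@values),
                object@coverageDeg, object@deltaGammaDeg))
    cat(sprintf("  values: %s, range of modulus [%.4g, %.4g]\n",
                if (is.complex(object@values)) "complex" else "real",
                min(Mod(object@values)), max(Mod(object@values))))
    invisible(NULL)
})

setMethod("show", "DisplacementField", function(object) {
    cat(sprintf("DisplacementField: views %d -> %d, %d radial samples, |u| <= %d\n",
                object@pair[1L], object@pair[2L], length(object@u),
                object@boundN))
    cat(sprintf("  u range [%d, %d], lambda = %g\n",
                min(object@u), max(object@u), object@lambdaReg))
    invisible(NULL)
})

setMethod("show", "ReconImage", function(object) {
    cat(sprintf("ReconImage: %d x %d pixels (%.3g mm), value range [%.4g, %.4g]\n",
                nrow(object@pixels), ncol(object@pixels), object@pixelSizeMm,
                min(object@pixels), max(object@pixels)))
    invisible(NULL)
})

setMethod("show", "Phantom", function(object) {
    cat(sprintf("Phantom: %d ellipse(s)\n", nrow(object@ellipses)))
    print(object@ellipses, row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "EstimatorConfig", function(object) {
    cat(sprintf("EstimatorConfig: N = %d, lambda = %g, normalize = %s\n",
                object@boundN, object@lambdaReg, object@normalize))
    invisible(NULL)
})

setMethod("show", "FbpConfig", function(object) {
    cat(sprintf("FbpConfig: %s filter, %d x %d output, %s backprojection\n",
                object@filterName, object@outputSize, object@outputSize,
                object@interp))
    invisible(NULL)
})
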