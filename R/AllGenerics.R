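# Generics and accessors. Slot access from user code goes through these.

#' @rdname Spectrum
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))
#' @rdname Spectrum
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname Spectrum
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))
#' @rdname Spectrum
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname Spectrum
#' @export
setGeneric("molMass", function(x) standardGeneric("molMass"))
#' @rdname Spectrum
#' @export
setGeneric("spectrumSource", function(x) standardGeneric("spectrumSource"))

#' @rdname Spectrum
#' @export
setMethod("spectrumId", "Spectrum", function(x) x@id)
#' @rdname Spectrum
#' @export
setMethod("peaks", "Spectrum", function(x) x@peaks)
#' @rdname Spectrum
#' @export
setMethod("mz", "Spectrum", function(x) unname(x@peaks[, 1L]))
#' @rdname Spectrum
#' @export
setMethod("intensity", "Spectrum", function(x) unname(x@peaks[, 2L]))
#' @rdname Spectrum
#' @export
setMethod("molMass", "Spectrum", function(x) x@molMass)
#' @rdname Spectrum
#' @export
setMethod("spectrumSource", "Spectrum", function(x) x@source)

setMethod("show", "Spectrum", function(object) {
    cat(sprintf(
        "Spectrum '%s' (%s): %d peaks, m/z %.6g-%.6g, base peak %.6g",
        object@id, object@source, nrow(object@peaks),
        min(object@peaks[, 1L]), max(object@peaks[, 1L]),
        object@peaks[which.max(object@peaks[, 2L]), 1L]
    ))
    if (!is.na(object@molMass))
        cat(sprintf(", MW %.6g Da", object@molMass))
    cat("\n")
    invisible(object)
})

setMethod("show", "WeightingScheme", function(object) {
    cat(sprintf(
        "WeightingScheme: intensity^%g * mz^%g, bin width %g Da, max m/z %g\n",
        object@intensityPower, object@mzPower, object@binWidth, object@maxMz
    ))
    invisible(object)
})

setMethod("show", "PeakEmbeddingModel", function(object) {
    cat(sprintf(
        "PeakEmbeddingModel: %d words x %d dims (%s, %d epochs, seed %d)\n",
        nrow(object@vectors), ncol(object@vectors),
        object@params@architecture, object@params@epochs,
        object@params@seed
    ))
    invisible(object)
})

setMethod("show", "MethodVariant", function(object) {
    cat(sprintf("MethodVariant: %s representation, %s search (%s)\n",
                object@representation, object@search, variantLabel(object)))
    invisible(object)
})

setMethod("show", "EvalResult", function(object) {
    cat(sprintf("EvalResult (%s), %d queries", variantLabel(object@variant),
                object@nQueries))
    if (!is.na(object@massFilterDa))
        cat(sprintf(", mass filter %g Da", object@massFilterDa))
    if (object@excluded > 0L)
        cat(sprintf(", %d excluded (truth not in library)", object@excluded))
    cat("\n")
    for (k in names(object@perK))
        cat(sprintf("  recall@%s = %.4f\n", k, object@perK[[k]]))
    invisible(object)
})

setMethod("show", "LibraryArtifacts", function(object) {
    cat(sprintf(
        "LibraryArtifacts: %d spectra (%s)\n", length(object@spectra),
        variantLabel(object@variant)
    ))
    cat(sprintf("  binned: %s; embeddings: %s; index: %s\n",
        if (is.null(object@binned)) "no" else
            paste0(ncol(object@binned), " bins"),
        if (is.null(object@embeddings)) "no" else
            paste0(ncol(object@embeddings), " dims"),
        if (is.null(object@index)) "none" else
            paste0(hnswSize(object@index), " vectors")))
    invisible(object)
})
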