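#' @include AllClasses.R
NULL

#' Managed root of a library
#' @param x A [MediaLibrary-class].
#' @return Absolute path of the managed root.
#' @export
setGeneric("libraryRoot", function(x) standardGeneric("libraryRoot"))

#' @rdname libraryRoot
setMethod("libraryRoot", "MediaLibrary", function(x) x@root)

#' Embedding coordinates
#' @param x An [EmbeddingResult-class].
#' @return `n x k` numeric matrix of coordinates.
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname embeddingCoords
setMethod("embeddingCoords", "EmbeddingResult", function(x) x@coordinates)

#' Explained-variance ratios of a PCA embedding
#' @param x An [EmbeddingResult-class].
#' @return Numeric vector (empty for UMAP results).
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname explainedVariance
setMethod("explainedVariance", "EmbeddingResult", function(x) x@explainedVariance)

#' Method parameters recorded in an embedding result
#' @param x An [EmbeddingResult-class].
#' @return Named list of parameters (includes the seed for UMAP).
#' @export
setGeneric("embeddingParams", function(x) standardGeneric("embeddingParams"))

#' @rdname embeddingParams
setMethod("embeddingParams", "EmbeddingResult", function(x) x@params)

#' Feature values in assets-by-features orientation
#'
#' @param x A [DeckFeatureSet-class].
#' @return Numeric matrix with one row per asset (rownames = asset ids) and
#'   one column per feature, the orientation expected by
#'   [standardizeFeatures()], [runPCA()] and [runUMAP()].
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
setMethod("featureValues", "DeckFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' Per-asset source labels of a feature set
#' @param x A [DeckFeatureSet-class].
#' @return Character vector aligned with the rows of [featureValues()].
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))

#' @rdname sourceLabels
setMethod("sourceLabels", "DeckFeatureSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$source_label)
})

setMethod("show", "MediaLibrary", function(object) {
  n <- tryCatch(dbScalar(object, "SELECT COUNT(*) FROM assets"), error = function(e) NA)
  cat("MediaLibrary at", object@root, "\n")
  cat("  assets:", n, "\n")
  invisible(object)
})

setMethod("show", "DerivativeSpec", function(object) {
  cat(sprintf("DerivativeSpec(thumb<=%d px, preview<=%d px, q=%d, clip=%gs @ %g)\n",
              object@thumbnailMaxEdge, object@previewMaxEdge,
              object@jpegQuality, object@clipDuration, object@clipOffsetFraction))
  invisible(object)
})

setMethod("show", "FeatureConfig", function(object) {
  cat(sprintf("FeatureConfig(P=%d, B=%d, T=%d, raw=%s, entropyBins=%d)\n",
              object@resamplePoints, object@histBins, object@tileGrid,
              object@includeRawProfiles, object@entropyBins))
  cat("  feature length:", featureLength(object),
      " fingerprint:", substr(configFingerprint(object), 1, 12), "...\n")
  invisible(object)
})

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult(%s): %d x %d coordinates\n", object@method,
              nrow(object@coordinates), ncol(object@coordinates)))
  if (length(object@explainedVariance))
    cat("  explained variance:",
        paste(sprintf("%.3f", object@explainedVariance), collapse = " "), "\n")
  invisible(object)
})
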