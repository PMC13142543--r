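#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' MediaLibrary: handle to a managed media library
#'
#' A `MediaLibrary` wraps the managed root directory of a library (holding
#' `library.db` plus the `originals/`, `thumbnails/`, `previews/`,
#' `posters/`, `zips/` and `logs/` subdirectories) and an open connection to
#' the embedded SQLite metadata store. Obtain one with [initLibrary()] or
#' [openLibrary()]; close it with [closeLibrary()].
#'
#' @slot root Absolute path of the managed root directory.
#' @slot dbfile Path of the SQLite database file (`library.db`).
#' @slot state Environment carrying the live DBI connection.
#' @export
setClass("MediaLibrary",
  representation(root = "character", dbfile = "character", state = "environment"))

setValidity("MediaLibrary", function(object) {
  if (length(object@root) != 1L || !nzchar(object@root))
    return("root must be a single non-empty path")
  req <- file.path(object@root, LIBRARY_SUBDIRS)
  miss <- req[!dir.exists(req)]
  if (length(miss)) return(paste0("missing managed subdirectories: ",
                                  paste(basename(miss), collapse = ", ")))
  TRUE
})

LIBRARY_SUBDIRS <- c("originals", "thumbnails", "previews", "posters", "zips", "logs")

#' DerivativeSpec: sizing and encoding parameters for browsing derivatives
#'
#' Controls the generated thumbnail/preview JPEGs and video poster/clip.
#' All sizes are pixel bounds on the longest edge; images are never upscaled.
#'
#' @slot thumbnailMaxEdge Longest edge of thumbnails, pixels (default 256).
#' @slot previewMaxEdge Longest edge of previews, pixels (default 1024).
#' @slot jpegQuality JPEG quality 1--100 (default 82).
#' @slot clipDuration Video preview clip length, seconds (default 3).
#' @slot clipOffsetFraction Poster/clip start as a fraction of the video
#'   duration in `[0, 1]` (default 0.1, avoiding black lead-in frames).
#' @export
setClass("DerivativeSpec",
  representation(thumbnailMaxEdge = "numeric", previewMaxEdge = "numeric",
                 jpegQuality = "numeric", clipDuration = "numeric",
                 clipOffsetFraction = "numeric"))

setValidity("DerivativeSpec", function(object) {
  if (object@thumbnailMaxEdge < 1 || object@previewMaxEdge < 1)
    return("edge bounds must be >= 1 pixel")
  if (object@thumbnailMaxEdge > object@previewMaxEdge)
    return("thumbnailMaxEdge must not exceed previewMaxEdge")
  if (object@jpegQuality < 1 || object@jpegQuality > 100)
    return("jpegQuality must be in 1..100")
  if (object@clipDuration <= 0) return("clipDuration must be positive")
  if (object@clipOffsetFraction < 0 || object@clipOffsetFraction > 1)
    return("clipOffsetFraction must be in [0, 1]")
  TRUE
})

#' Construct a DerivativeSpec
#'
#' @param thumbnailMaxEdge,previewMaxEdge,jpegQuality,clipDuration,clipOffsetFraction
#'   See the class slots.
#' @return A validated [DerivativeSpec-class] object.
#' @examples
#' derivativeSpec(thumbnailMaxEdge = 128)
#' @export
derivativeSpec <- function(thumbnailMaxEdge = 256, previewMaxEdge = 1024,
                           jpegQuality = 82, clipDuration = 3,
                           clipOffsetFraction = 0.1) {
  new("DerivativeSpec", thumbnailMaxEdge = as.numeric(thumbnailMaxEdge),
      previewMaxEdge = as.numeric(previewMaxEdge),
      jpegQuality = as.numeric(jpegQuality),
      clipDuration = as.numeric(clipDuration),
      clipOffsetFraction = as.numeric(clipOffsetFraction))
}

#' FeatureConfig: parameters of the per-image descriptor pipeline
#'
#' The feature vector layout (names, order and length) is a pure function of
#' this configuration; a stable fingerprint of all fields travels with every
#' feature matrix so downstream analyses can verify comparability.
#'
#' @slot resamplePoints Number of points each canonical line is resampled to
#'   (default 100).
#' @slot histBins Equal-width bins per colour channel histogram (default 32).
#' @slot tileGrid Tile grid order `T`, giving `T x T` regional tiles
#'   (default 4).
#' @slot includeRawProfiles Whether raw resampled line-profile RGB values are
#'   included alongside the summaries (default `TRUE`).
#' @slot entropyBins Grayscale histogram bins for intensity entropy
#'   (default 256).
#' @export
setClass("FeatureConfig",
  representation(resamplePoints = "integer", histBins = "integer",
                 tileGrid = "integer", includeRawProfiles = "logical",
                 entropyBins = "integer"))

setValidity("FeatureConfig", function(object) {
  if (object@resamplePoints < 2L) return("resamplePoints must be >= 2")
  if (object@histBins < 2L) return("histBins must be >= 2")
  if (object@tileGrid < 1L) return("tileGrid must be >= 1")
  if (object@entropyBins < 2L) return("entropyBins must be >= 2")
  TRUE
})

#' Construct a FeatureConfig
#'
#' @param resamplePoints,histBins,tileGrid,includeRawProfiles,entropyBins
#'   See the class slots.
#' @return A validated [FeatureConfig-class] object.
#' @examples
#' cfg <- featureConfig()
#' length(featureNames(cfg))
#' @export
featureConfig <- function(resamplePoints = 100, histBins = 32, tileGrid = 4,
                          includeRawProfiles = TRUE, entropyBins = 256) {
  new("FeatureConfig", resamplePoints = as.integer(resamplePoints),
      histBins = as.integer(histBins), tileGrid = as.integer(tileGrid),
      includeRawProfiles = isTRUE(includeRawProfiles),
      entropyBins = as.integer(entropyBins))
}

#' Fingerprint of a FeatureConfig
#'
#' Stable hash over all configuration fields, stored with every feature
#' matrix (and its CSV sidecar) to guard against mixing incompatible runs.
#' @param config A [FeatureConfig-class].
#' @return 64-character hex string.
#' @export
configFingerprint <- function(config) {
  stopifnot(is(config, "FeatureConfig"))
  digest::digest(list(P = config@resamplePoints, B = config@histBins,
                      T = config@tileGrid, raw = config@includeRawProfiles,
                      E = config@entropyBins), algo = "sha256")
}

#' DeckFeatureSet: a feature matrix with aligned asset annotations
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with features as rows
#' and assets as columns (assay `"features"`). `colData` carries `asset_id`
#' and `source_label`; `metadata()` carries the generating [FeatureConfig-class]
#' and its fingerprint. Use [featureValues()] for the conventional
#' assets-by-features orientation consumed by [standardizeFeatures()] and the
#' embedding functions.
#' @export
setClass("DeckFeatureSet", contains = "SummarizedExperiment")

setValidity("DeckFeatureSet", function(object) {
  a <- SummarizedExperiment::assay(object, "features")
  if (any(!is.finite(a))) return("feature values must be finite (no NaN/Inf)")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("asset_id", "source_label") %in% colnames(cd)))
    return("colData must contain asset_id and source_label")
  if (is.null(S4Vectors::metadata(object)$fingerprint))
    return("metadata must record the config fingerprint")
  TRUE
})

#' EmbeddingResult: low-dimensional coordinates with provenance
#'
#' @slot method `"pca"` or `"umap"`.
#' @slot coordinates `n x k` matrix, rows aligned with the input matrix.
#' @slot explainedVariance Length-`k` explained-variance ratios (PCA; empty
#'   for UMAP), non-increasing, each in `[0, 1]`, summing to at most 1.
#' @slot params Method parameters actually used.
#' @slot seed Integer seed (UMAP; `NA` for PCA).
#' @export
setClass("EmbeddingResult",
  representation(method = "character", coordinates = "matrix",
                 explainedVariance = "numeric", params = "list",
                 seed = "integer"))

setValidity("EmbeddingResult", function(object) {
  if (!object@method %in% c("pca", "umap")) return("method must be 'pca' or 'umap'")
  ev <- object@explainedVariance
  if (length(ev)) {
    if (any(ev < -1e-12 | ev > 1 + 1e-12)) return("explained variance ratios must lie in [0,1]")
    if (any(diff(ev) > 1e-9)) return("explained variance ratios must be non-increasing")
    if (sum(ev) > 1 + 1e-9) return("explained variance ratios must sum to <= 1")
  }
  TRUE
})
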