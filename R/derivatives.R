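## Browsing derivatives: thumbnail/preview JPEGs for images; poster frame,
## preview clip and poster-based thumbnail for videos. Derivative filenames
## reuse the asset's sha256 stem so they are auditable against the original.

scaledDims <- function(w, h, maxEdge) {
  s <- maxEdge / max(w, h)
  if (s >= 1) return(c(w, h))                 # never upscale
  pmax(roundHalfUp(c(w, h) * s), 1)
}

resizeImage <- function(img, w, h) {
  if (dim(img)[2] == w && dim(img)[1] == h) return(img)
  ei <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ei, w = w, h = h)
  clip01(aperm(EBImage::imageData(out), c(2, 1, 3)))
}

#' Generate image thumbnail and preview
#'
#' Writes two JPEGs, `thumbnails/<sha256>.jpg` and `previews/<sha256>.jpg`,
#' scaled so the longest edge does not exceed the spec bound, preserving
#' aspect ratio to within one pixel; images already within the bound are
#' re-encoded at their native size (no upscaling). Alpha is flattened onto
#' white at decode time. The original is never modified.
#'
#' @param lib A [MediaLibrary-class].
#' @param originalPath Path to the decodable original image.
#' @param sha256 Content hash used as the derivative file stem.
#' @param spec A [DerivativeSpec-class].
#' @return List with `thumbnail_path` and `preview_path` (relative to the
#'   managed root).
#' @export
makeImageDerivatives <- function(lib, originalPath, sha256,
                                 spec = derivativeSpec()) {
  img <- readImageRGB(originalPath)
  h <- dim(img)[1]; w <- dim(img)[2]
  root <- libraryRoot(lib)
  out <- list()
  for (kind in c("thumbnail", "preview")) {
    bound <- if (kind == "thumbnail") spec@thumbnailMaxEdge else spec@previewMaxEdge
    dd <- scaledDims(w, h, bound)
    rel <- file.path(paste0(kind, "s"), paste0(sha256, ".jpg"))
    writeJPEGImage(resizeImage(img, dd[1], dd[2]), file.path(root, rel),
                   spec@jpegQuality)
    out[[paste0(kind, "_path")]] <- rel
  }
  out
}

#' Generate video poster, preview clip and thumbnail
#'
#' The poster is the frame at `clipOffsetFraction * duration`, written as a
#' JPEG under `posters/`; the preview clip is `min(clipDuration, duration)`
#' seconds starting at that time, re-encoded to a web-playable MP4 under
#' `previews/`; the thumbnail is derived from the poster with the image
#' thumbnail rules. Requires an `ffmpeg`-compatible executable on the PATH.
#'
#' @param lib A [MediaLibrary-class].
#' @param originalPath Path to the original video.
#' @param duration Video duration in seconds (from [extractVideoMetadata()]).
#' @param sha256 Content hash used as the derivative file stem.
#' @param spec A [DerivativeSpec-class].
#' @return List with `poster_path`, `clip_path`, `thumbnail_path`.
#' @export
makeVideoDerivatives <- function(lib, originalPath, duration, sha256,
                                 spec = derivativeSpec()) {
  ffmpeg <- toolkitPath("ffmpeg")
  if (!nzchar(ffmpeg))
    deckEnvironmentError("video derivatives require 'ffmpeg' on the PATH")
  root <- libraryRoot(lib)
  t0 <- spec@clipOffsetFraction * duration
  clipLen <- min(spec@clipDuration, duration)
  posterRel <- file.path("posters", paste0(sha256, ".jpg"))
  clipRel <- file.path("previews", paste0(sha256, ".mp4"))
  run <- function(args, what) {
    out <- suppressWarnings(system2(ffmpeg, args, stdout = TRUE, stderr = TRUE))
    if ((attr(out, "status") %||% 0L) != 0L)
      deckStop("mediadeck_decode_error",
               paste0(what, " extraction failed for ", originalPath))
  }
  run(c("-y", "-ss", format(t0), "-i", shQuote(originalPath), "-frames:v", "1",
        "-q:v", "3", shQuote(file.path(root, posterRel))), "poster")
  run(c("-y", "-ss", format(t0), "-t", format(clipLen), "-i",
        shQuote(originalPath), "-an", "-c:v", "libx264", "-pix_fmt", "yuv420p",
        "-movflags", "+faststart", shQuote(file.path(root, clipRel))), "clip")
  thumb <- makeImageDerivatives(lib, file.path(root, posterRel), sha256, spec)
  list(poster_path = posterRel, clip_path = clipRel,
       thumbnail_path = thumb$thumbnail_path)
}

#' Regenerate derivatives for existing assets
#'
#' Derivatives are disposable: this pass rebuilds thumbnails/previews (and
#' video posters/clips) from the immutable originals, restoring files with
#' identical dimensions after deletion.
#'
#' @param lib A [MediaLibrary-class].
#' @param assetIds Optional subset of asset ids (default: all).
#' @param spec A [DerivativeSpec-class].
#' @return Invisibly, the number of assets regenerated.
#' @export
regenerateDerivatives <- function(lib, assetIds = NULL, spec = derivativeSpec()) {
  assets <- listAssets(lib)
  if (!is.null(assetIds)) assets <- assets[assets$id %in% assetIds, ]
  root <- libraryRoot(lib)
  n <- 0L
  for (i in seq_len(nrow(assets))) {
    a <- assets[i, ]
    orig <- file.path(root, a$original_path)
    if (a$media_type == "image") {
      makeImageDerivatives(lib, orig, a$sha256, spec)
    } else {
      makeVideoDerivatives(lib, orig, a$duration, a$sha256, spec)
    }
    n <- n + 1L
  }
  invisible(n)
}
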