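#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats quantile rnorm runif sd kmeans dist
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions -------------------------------------------------------
## Every user-facing failure carries a condition class so callers (and the
## CLI exit-code mapping) can react without parsing messages.

deckStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mediadeck_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

deckValidationError <- function(msg, ...) deckStop("mediadeck_validation_error", msg, ...)
deckNotFoundError   <- function(msg, ...) deckStop("mediadeck_notfound_error", msg, ...)
deckIntegrityError  <- function(msg, ...) deckStop("mediadeck_integrity_error", msg, ...)
deckQueryError      <- function(msg, ...) deckStop("mediadeck_query_error", msg, ...)
deckEnvironmentError<- function(msg, ...) deckStop("mediadeck_environment_error", msg, ...)
deckPermissionError <- function(msg, ...) deckStop("mediadeck_permission_error", msg, ...)

## Time ---------------------------------------------------------------------

#' Current UTC time as sortable ISO-8601 text
#'
#' Timestamps are stored as `YYYY-MM-DDTHH:MM:SSZ` so that lexicographic and
#' chronological order coincide.
#' @return A length-one character string.
#' @keywords internal
utcNow <- function() formatUTC(Sys.time())

formatUTC <- function(t) format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parseUTC <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

## Arithmetic helpers -------------------------------------------------------

## Half-up rounding: round(0.5) in R is banker's rounding; tile boundaries
## and derivative sizes need the conventional floor(x + 0.5).
roundHalfUp <- function(x) floor(x + 0.5)

popSD <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Image I/O ----------------------------------------------------------------

IMAGE_EXTENSIONS <- c("jpg", "jpeg", "png", "tif", "tiff")
VIDEO_EXTENSIONS <- c("mp4", "mov", "avi", "webm", "mkv")

fileExtLower <- function(path) tolower(tools::file_ext(path))

#' Read an image file as an RGB array
#'
#' Decodes a PNG, JPEG or TIFF file into a numeric `H x W x 3` array with
#' values in `[0, 1]`. Grayscale images are promoted to RGB by channel
#' replication; an alpha channel is flattened onto a white background
#' (`rgb * a + 1 * (1 - a)`), matching how the images are meant to be viewed.
#'
#' @param path Path to the image file.
#' @return Numeric array of dimension `height x width x 3`, values in `[0, 1]`.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) deckNotFoundError(paste0("image file not found: ", path))
  ext <- fileExtLower(path)
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      deckValidationError(paste0("unsupported image format: .", ext))
    ),
    error = function(e) {
      if (inherits(e, "mediadeck_error")) stop(e)
      deckStop("mediadeck_decode_error", paste0("cannot decode image ", path, ": ", conditionMessage(e)))
    }
  )
  asRGBArray(raw)
}

## Normalise decoder output (matrix or H x W x {1,2,3,4} array) to H x W x 3.
asRGBArray <- function(raw) {
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nc <- dim(raw)[3]
  h <- dim(raw)[1]; w <- dim(raw)[2]
  if (nc == 1L) {
    img <- array(raw[, , 1L], dim = c(h, w, 3L))
  } else if (nc == 2L) {                       # gray + alpha
    g <- raw[, , 1L]; a <- raw[, , 2L]
    g <- g * a + (1 - a)
    img <- array(g, dim = c(h, w, 3L))
  } else if (nc == 3L) {
    img <- raw[, , 1:3, drop = FALSE]
  } else {                                     # rgb + alpha onto white
    a <- raw[, , 4L]
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- raw[, , ch] * a + (1 - a)
  }
  clip01(img)
}

writeJPEGImage <- function(img, path, quality) {
  jpeg::writeJPEG(img, target = path, quality = quality / 100)
  path
}

## Minimal EXIF orientation scan (JPEG APP1). Returns 1 when absent or on any
## parse failure; values 5-8 mean the display dimensions are transposed.
jpegExifOrientation <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  soi <- readBin(con, "raw", 2L)
  if (length(soi) < 2L || soi[1] != as.raw(0xFF) || soi[2] != as.raw(0xD8)) return(1L)
  repeat {
    marker <- readBin(con, "raw", 2L)
    if (length(marker) < 2L || marker[1] != as.raw(0xFF)) return(1L)
    m <- as.integer(marker[2])
    if (m == 0xDA || m == 0xD9) return(1L)       # start of scan / EOI
    len <- readBin(con, "integer", 1L, size = 2L, endian = "big", signed = FALSE)
    if (is.na(len) || len < 2L) return(1L)
    body <- readBin(con, "raw", len - 2L)
    if (m == 0xE1 && length(body) >= 14L &&
        identical(body[1:6], as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00)))) {
      tiff <- body[-(1:6)]
      big <- identical(tiff[1:2], as.raw(c(0x4D, 0x4D)))
      rd16 <- function(i) {
        b <- as.integer(tiff[i:(i + 1)])
        if (big) b[1] * 256L + b[2] else b[2] * 256L + b[1]
      }
      rd32 <- function(i) {
        b <- as.integer(tiff[i:(i + 3)])
        if (big) ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]
        else ((b[4] * 256 + b[3]) * 256 + b[2]) * 256 + b[1]
      }
      off <- rd32(5L) + 1L
      if (off + 1L > length(tiff)) return(1L)
      n <- rd16(off)
      for (k in seq_len(n)) {
        e <- off + 2L + (k - 1L) * 12L
        if (e + 11L > length(tiff)) return(1L)
        if (rd16(e) == 0x0112) return(rd16(e + 8L))
      }
      return(1L)
    }
  }
}

## External toolkit detection -----------------------------------------------

toolkitPath <- function(tool) Sys.which(tool)

#' Is the external video toolkit available?
#'
#' Video probing and derivative generation require `ffprobe`/`ffmpeg` on the
#' PATH. When absent, video candidates are counted as failed with an
#' environment message rather than aborting an import.
#' @return Logical scalar.
#' @export
videoToolkitAvailable <- function() {
  nzchar(toolkitPath("ffprobe")) && nzchar(toolkitPath("ffmpeg"))
}
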