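## Deterministic per-image descriptors: four canonical RGB line profiles with
## channel-wise summaries, whole-image RGB/HSV/CIE Lab histograms, global
## colour statistics, tile-grid regional mean colours, and simple texture
## descriptors. The feature vector layout is a pure function of the
## FeatureConfig and is documented by featureNames().

LINE_KINDS <- c("main_diagonal", "anti_diagonal", "mid_horizontal", "mid_vertical")
RGB_CHANNELS <- c("R", "G", "B")
SUMMARY_STATS <- c("mean", "std", "min", "q1", "median", "q3", "max", "range")
COLOR_SPACES <- list(rgb = c("R", "G", "B"), hsv = c("H", "S", "V"),
                     lab = c("L", "a", "b"))
TEXTURE_NAMES <- c("tex_gradient_mean", "tex_gradient_dispersion",
                   "tex_edge_density", "tex_intensity_entropy",
                   "tex_global_contrast")

## Colour conversions -------------------------------------------------------

pixelMatrix <- function(img) {
  ## n x 3 matrix of pixels, rows in column-major image order (fixed order so
  ## exports are deterministic; all consumers are order-invariant statistics)
  matrix(img, ncol = 3L)
}

## HSV with hue in degrees [0, 360); sRGB input in [0, 1]
rgbToHSVDeg <- function(px) {
  hsv <- t(grDevices::rgb2hsv(t(px), maxColorValue = 1))
  cbind(H = hsv[, 1] * 360, S = hsv[, 2], V = hsv[, 3])
}

## CIE Lab from sRGB, D65 white point, standard IEC 61966-2-1 constants;
## a/b clamped to the canonical [-128, 127] histogram range.
SRGB_TO_XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                        0.2126729, 0.7151522, 0.0721750,
                        0.0193339, 0.1191920, 0.9503041),
                      nrow = 3, byrow = TRUE)
D65_WHITE <- c(0.95047, 1, 1.08883)

rgbToLab <- function(px) {
  lin <- ifelse(px <= 0.04045, px / 12.92, ((px + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(SRGB_TO_XYZ)
  tt <- sweep(xyz, 2, D65_WHITE, "/")
  delta <- 6 / 29
  f <- ifelse(tt > delta^3, tt^(1 / 3), tt / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  cbind(L = pmin(pmax(L, 0), 100),
        a = pmin(pmax(500 * (f[, 1] - f[, 2]), -128), 127),
        b = pmin(pmax(200 * (f[, 2] - f[, 3]), -128), 127))
}

channelRange <- function(space, channel) {
  switch(space,
    rgb = c(0, 1),
    hsv = if (channel == "H") c(0, 360) else c(0, 1),
    lab = if (channel == "L") c(0, 100) else c(-128, 127))
}

luma <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]

## Line profiles ------------------------------------------------------------

lineEndpoints <- function(kind, W, H) {
  ## 0-based pixel-centre coordinates (x = column, y = row)
  switch(kind,
    main_diagonal  = c(0, 0, W - 1, H - 1),
    anti_diagonal  = c(W - 1, 0, 0, H - 1),
    mid_horizontal = c(0, (H - 1) / 2, W - 1, (H - 1) / 2),
    mid_vertical   = c((W - 1) / 2, 0, (W - 1) / 2, H - 1),
    deckValidationError(paste0("unknown line kind: ", kind)))
}

bilinearSample <- function(img, x, y) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- pmin(pmax(floor(x), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  y0 <- pmin(pmax(floor(y), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  out <- matrix(0, length(x), 3L, dimnames = list(NULL, RGB_CHANNELS))
  for (ch in 1:3) {
    out[, ch] <-
      img[cbind(y0 + 1, x0 + 1, ch)] * (1 - fx) * (1 - fy) +
      img[cbind(y0 + 1, x1 + 1, ch)] * fx * (1 - fy) +
      img[cbind(y1 + 1, x0 + 1, ch)] * (1 - fx) * fy +
      img[cbind(y1 + 1, x1 + 1, ch)] * fx * fy
  }
  out
}

#' Sample RGB values along a canonical image line
#'
#' Samples `P` points evenly spaced in the parameter `t` along one of the
#' four canonical segments -- main diagonal, anti-diagonal, middle
#' horizontal, middle vertical -- using 0-based pixel-centre coordinates and
#' bilinear interpolation per channel.
#'
#' @param img `H x W x 3` array in `[0, 1]` (see [readImageRGB()]).
#' @param lineKind One of `"main_diagonal"`, `"anti_diagonal"`,
#'   `"mid_horizontal"`, `"mid_vertical"`.
#' @param P Number of resample points (>= 2).
#' @return List with `line_kind` and `samples`, a `P x 3` matrix in `[0, 1]`.
#' @export
sampleLine <- function(img, lineKind, P = 100) {
  if (length(dim(img)) != 3L || any(dim(img)[1:2] < 1L))
    deckValidationError("img must be a non-empty H x W x 3 array")
  P <- as.integer(P)
  if (P < 2L) deckValidationError("P must be >= 2")
  ep <- lineEndpoints(lineKind, dim(img)[2], dim(img)[1])
  t <- seq(0, 1, length.out = P)
  x <- ep[1] + t * (ep[3] - ep[1])
  y <- ep[2] + t * (ep[4] - ep[2])
  list(line_kind = lineKind, samples = bilinearSample(img, x, y))
}

#' Channel-wise summary of a line profile
#'
#' Per channel over the `P` resampled values: mean, population standard
#' deviation, min, first quartile, median, third quartile, max and range
#' (max - min), with quartiles by linear interpolation between order
#' statistics; plus two gradient measures over the `P - 1` first
#' differences: mean and max absolute first difference.
#'
#' @param profile A line profile from [sampleLine()].
#' @return Named numeric vector of length 30 (`<channel>_<stat>` then
#'   `<channel>_grad_mean` / `<channel>_grad_max`).
#' @export
summarizeLine <- function(profile) {
  s <- profile$samples
  out <- numeric(0)
  for (ch in seq_along(RGB_CHANNELS)) {
    v <- s[, ch]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    st <- c(mean = mean(v), std = popSD(v), min = min(v), q1 = q[1],
            median = q[2], q3 = q[3], max = max(v), range = max(v) - min(v))
    names(st) <- paste0(RGB_CHANNELS[ch], "_", SUMMARY_STATS)
    out <- c(out, st)
  }
  for (ch in seq_along(RGB_CHANNELS)) {
    d <- abs(diff(s[, ch]))
    g <- c(mean(d), max(d))
    names(g) <- paste0(RGB_CHANNELS[ch], c("_grad_mean", "_grad_max"))
    out <- c(out, g)
  }
  out
}

## Histograms and colour statistics -----------------------------------------

binIndices <- function(v, lo, hi, B) {
  ## equal-width bins over [lo, hi], upper edge inclusive in the last bin
  idx <- floor((v - lo) / (hi - lo) * B) + 1
  pmin(pmax(idx, 1L), B)
}

histOneChannel <- function(v, lo, hi, B) {
  counts <- tabulate(binIndices(v, lo, hi, B), nbins = B)
  counts / sum(counts)
}

#' Whole-image colour histograms in RGB, HSV and CIE Lab
#'
#' Per channel, `B` equal-width bins over the channel's canonical range
#' (RGB `[0,1]`; H `[0,360)`, S,V `[0,1]`; L `[0,100]`, a,b clamped to
#' `[-128,127]`), each histogram normalised to sum 1, upper edge inclusive
#' in the last bin.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param B Bins per channel (>= 2).
#' @return Named list of nine numeric vectors (`rgb_R`, ..., `lab_b`), each
#'   of length `B` and summing to 1.
#' @export
colorHistograms <- function(img, B = 32) {
  B <- as.integer(B)
  px <- list(rgb = pixelMatrix(img))
  px$hsv <- rgbToHSVDeg(px$rgb)
  px$lab <- rgbToLab(px$rgb)
  out <- list()
  for (space in names(COLOR_SPACES)) {
    for (ci in seq_along(COLOR_SPACES[[space]])) {
      ch <- COLOR_SPACES[[space]][ci]
      r <- channelRange(space, ch)
      out[[paste0(space, "_", ch)]] <- histOneChannel(px[[space]][, ci], r[1], r[2], B)
    }
  }
  out
}

circularMeanDeg <- function(deg) {
  r <- deg * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  m <- atan2(s, c) * 180 / pi
  ((m %% 360) + 360) %% 360
}

circularSDDeg <- function(deg) {
  r <- deg * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  sqrt(-2 * log(max(min(R, 1), 1e-300))) * 180 / pi
}

#' Global colour statistics per colour space
#'
#' Per-channel mean and population standard deviation in RGB, HSV and Lab.
#' Hue is treated circularly: its mean is the circular mean in degrees and
#' its dispersion the resultant-length-based circular standard deviation, so
#' hues of 350 and 10 degrees average to 0, not 180.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @return Named numeric vector of length 18
#'   (`stat_<space>_<channel>_{mean,std}`).
#' @export
globalColorStats <- function(img) {
  px <- list(rgb = pixelMatrix(img))
  px$hsv <- rgbToHSVDeg(px$rgb)
  px$lab <- rgbToLab(px$rgb)
  out <- numeric(0)
  for (space in names(COLOR_SPACES)) {
    for (ci in seq_along(COLOR_SPACES[[space]])) {
      ch <- COLOR_SPACES[[space]][ci]
      v <- px[[space]][, ci]
      st <- if (space == "hsv" && ch == "H")
        c(circularMeanDeg(v), circularSDDeg(v))
      else c(mean(v), popSD(v))
      names(st) <- paste0("stat_", space, "_", ch, c("_mean", "_std"))
      out <- c(out, st)
    }
  }
  out
}

## Tile means ---------------------------------------------------------------

tileBoundaries <- function(n, T) roundHalfUp(seq(0, T) * n / T)

#' Regional mean colours on a regular tile grid
#'
#' Partitions the image into `T x T` rectangles with boundaries at
#' `round(i * W / T)` / `round(j * H / T)` (half-open intervals: full
#' coverage, no overlap) and reports each tile's per-channel mean, row-major
#' from the top-left tile.
#'
#' @param img `H x W x 3` array in `[0, 1]`, with `W >= T` and `H >= T`.
#' @param T Grid order (default 4 for a 4 x 4 grid).
#' @return Named numeric vector of length `T * T * 3`
#'   (`tile_r<i>_c<j>_<channel>`).
#' @export
tileMeans <- function(img, T = 4) {
  T <- as.integer(T)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (W < T || H < T)
    deckValidationError(sprintf(
      "image %dx%d is smaller than the %dx%d tile grid; use a smaller T", W, H, T, T))
  cb <- tileBoundaries(W, T); rb <- tileBoundaries(H, T)
  out <- numeric(0)
  for (i in seq_len(T)) {
    rows <- (rb[i] + 1):rb[i + 1]
    for (j in seq_len(T)) {
      cols <- (cb[j] + 1):cb[j + 1]
      m <- vapply(1:3, function(ch) mean(img[rows, cols, ch]), numeric(1))
      names(m) <- paste0("tile_r", i, "_c", j, "_", RGB_CHANNELS)
      out <- c(out, m)
    }
  }
  out
}

## Texture ------------------------------------------------------------------

## Central differences with replicated borders, per axis
centralDiff <- function(g) {
  H <- nrow(g); W <- ncol(g)
  xr <- g[, pmin(seq_len(W) + 1, W), drop = FALSE]
  xl <- g[, pmax(seq_len(W) - 1, 1), drop = FALSE]
  yd <- g[pmin(seq_len(H) + 1, H), , drop = FALSE]
  yu <- g[pmax(seq_len(H) - 1, 1), , drop = FALSE]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

## Otsu threshold on a K-bin histogram of v; NA when all values are equal.
otsuThreshold <- function(v, K = 256L) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  p <- tabulate(binIndices(v, lo, hi, K), nbins = K) / length(v)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(K))
  muT <- mu[K]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)                          # ties: smallest split
  lo + k * (hi - lo) / K
}

shannonEntropyBits <- function(v, bins, lo = 0, hi = 1) {
  p <- tabulate(binIndices(v, lo, hi, bins), nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Simple texture descriptors
#'
#' The image is converted to grayscale by luma (0.299 R + 0.587 G +
#' 0.114 B); the gradient magnitude field uses central differences with
#' replicated borders. Descriptors:
#'
#' * `tex_gradient_mean` -- mean gradient magnitude;
#' * `tex_gradient_dispersion` -- population SD of the magnitudes;
#' * `tex_edge_density` -- fraction of pixels whose magnitude exceeds an
#'   Otsu threshold on the magnitude histogram (0 when all magnitudes are
#'   equal);
#' * `tex_intensity_entropy` -- Shannon entropy (bits) of the
#'   `entropyBins`-bin grayscale histogram;
#' * `tex_global_contrast` -- population SD of the grayscale image (RMS
#'   contrast).
#'
#' A constant image scores 0 on all five.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param entropyBins Grayscale histogram bins (default 256).
#' @return Named numeric vector of length 5.
#' @export
textureDescriptors <- function(img, entropyBins = 256) {
  g <- luma(img)
  d <- centralDiff(g)
  mag <- sqrt(d$gx^2 + d$gy^2)
  thr <- otsuThreshold(as.vector(mag))
  edge <- if (is.na(thr)) 0 else mean(mag > thr)
  out <- c(mean(mag), popSD(mag), edge,
           shannonEntropyBits(as.vector(g), as.integer(entropyBins)),
           popSD(as.vector(g)))
  names(out) <- TEXTURE_NAMES
  out
}

## Assembly -----------------------------------------------------------------

#' Names (and implicitly the layout) of the feature vector
#'
#' The fixed column order is: per line (main diagonal, anti-diagonal, middle
#' horizontal, middle vertical) the 30 summary values; then, if
#' `includeRawProfiles`, the raw `P x 3` resampled RGB values per line
#' (point-major, channels innermost); then the nine `B`-bin histograms
#' (RGB, HSV, Lab; channels in space order); then the 18 global colour
#' statistics; then the `T x T x 3` tile means (row-major, channels
#' innermost); then the five texture descriptors.
#'
#' @param config A [FeatureConfig-class].
#' @return Character vector of feature names; its length is the feature
#'   dimension implied by `config`.
#' @export
featureNames <- function(config) {
  P <- config@resamplePoints; B <- config@histBins; T <- config@tileGrid
  nm <- character(0)
  for (kind in LINE_KINDS)
    nm <- c(nm,
      paste0(kind, "_", rep(RGB_CHANNELS, each = length(SUMMARY_STATS)), "_",
             rep(SUMMARY_STATS, times = 3)),
      paste0(kind, "_", rep(RGB_CHANNELS, each = 2), rep(c("_grad_mean", "_grad_max"), 3)))
  if (config@includeRawProfiles)
    for (kind in LINE_KINDS)
      nm <- c(nm, sprintf("raw_%s_p%03d_%s", kind,
                          rep(seq_len(P), each = 3), rep(RGB_CHANNELS, P)))
  for (space in names(COLOR_SPACES))
    for (ch in COLOR_SPACES[[space]])
      nm <- c(nm, sprintf("hist_%s_%s_bin%02d", space, ch, seq_len(B)))
  for (space in names(COLOR_SPACES))
    for (ch in COLOR_SPACES[[space]])
      nm <- c(nm, paste0("stat_", space, "_", ch, c("_mean", "_std")))
  for (i in seq_len(T))
    for (j in seq_len(T))
      nm <- c(nm, paste0("tile_r", i, "_c", j, "_", RGB_CHANNELS))
  c(nm, TEXTURE_NAMES)
}

#' @rdname featureNames
#' @export
featureLength <- function(config) {
  P <- config@resamplePoints; B <- config@histBins; T <- config@tileGrid
  4L * 30L + (if (config@includeRawProfiles) 4L * P * 3L else 0L) +
    9L * B + 18L + T * T * 3L + 5L
}

#' Extract the full feature vector of one image
#'
#' Concatenates every descriptor block in the fixed order documented by
#' [featureNames()]. The result never contains NaN: degenerate inputs
#' (constant images, zero gradients) produce 0 by the stated conventions.
#'
#' @param img An `H x W x 3` array in `[0, 1]`, or a path to a decodable
#'   image (grayscale is promoted to RGB, alpha flattened onto white).
#' @param config A [FeatureConfig-class].
#' @return Named numeric vector of length `featureLength(config)`.
#' @examples
#' img <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
#' v <- extractFeatures(img, featureConfig(resamplePoints = 10, histBins = 8))
#' length(v)
#' @export
extractFeatures <- function(img, config = featureConfig()) {
  if (is.character(img)) img <- readImageRGB(img)
  P <- config@resamplePoints
  profiles <- lapply(LINE_KINDS, function(k) sampleLine(img, k, P))
  names(profiles) <- LINE_KINDS

  v <- numeric(0)
  for (k in LINE_KINDS) {
    s <- summarizeLine(profiles[[k]])
    names(s) <- paste0(k, "_", names(s))
    v <- c(v, s)
  }
  if (config@includeRawProfiles)
    for (k in LINE_KINDS) {
      raw <- as.vector(t(profiles[[k]]$samples))  # point-major, channels inner
      names(raw) <- sprintf("raw_%s_p%03d_%s", k,
                            rep(seq_len(P), each = 3), rep(RGB_CHANNELS, P))
      v <- c(v, raw)
    }
  hists <- colorHistograms(img, config@histBins)
  for (nm in names(hists)) {
    h <- hists[[nm]]
    names(h) <- sprintf("hist_%s_bin%02d", nm, seq_along(h))
    v <- c(v, h)
  }
  v <- c(v, globalColorStats(img), tileMeans(img, config@tileGrid),
         textureDescriptors(img, config@entropyBins))
  stopifnot(identical(names(v), featureNames(config)))
  v
}

## Overlays -----------------------------------------------------------------

drawSegment <- function(img, x0, y0, x1, y1, rgb, n = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (is.null(n)) n <- 2L * max(W, H)
  t <- seq(0, 1, length.out = n)
  xs <- roundHalfUp(x0 + t * (x1 - x0)) + 1
  ys <- roundHalfUp(y0 + t * (y1 - y0)) + 1
  xs <- pmin(pmax(xs, 1), W); ys <- pmin(pmax(ys, 1), H)
  for (ch in 1:3) img[cbind(ys, xs, ch)] <- rgb[ch]
  img
}

#' Render a quality-control overlay of the sampled lines
#'
#' Writes a JPEG copy of the (preview-scaled) image with the four canonical
#' segments drawn in distinct colours and the `P` sample points ticked. The
#' original file is never modified.
#'
#' @param imagePath Path to a decodable image.
#' @param P Number of sample ticks per line.
#' @param outPath Output JPEG path (default: `<input>-overlay.jpg` next to
#'   the input).
#' @param previewMaxEdge Longest-edge bound applied before drawing.
#' @return The overlay path, invisibly.
#' @export
renderLineOverlay <- function(imagePath, P = 100, outPath = NULL,
                              previewMaxEdge = 1024) {
  img <- readImageRGB(imagePath)
  dd <- scaledDims(dim(img)[2], dim(img)[1], previewMaxEdge)
  img <- resizeImage(img, dd[1], dd[2])
  H <- dim(img)[1]; W <- dim(img)[2]
  cols <- list(main_diagonal = c(0.9, 0.1, 0.1), anti_diagonal = c(0.1, 0.7, 0.1),
               mid_horizontal = c(0.1, 0.2, 0.9), mid_vertical = c(0.8, 0.1, 0.8))
  for (k in LINE_KINDS) {
    ep <- lineEndpoints(k, W, H)
    img <- drawSegment(img, ep[1], ep[2], ep[3], ep[4], cols[[k]])
    t <- seq(0, 1, length.out = P)
    tx <- pmin(pmax(roundHalfUp(ep[1] + t * (ep[3] - ep[1])) + 1, 2), W - 1)
    ty <- pmin(pmax(roundHalfUp(ep[2] + t * (ep[4] - ep[2])) + 1, 2), H - 1)
    for (d in c(-1L, 1L)) {                    # small tick crosses
      for (ch in 1:3) {
        img[cbind(ty + d, tx, ch)] <- cols[[k]][ch]
        img[cbind(ty, tx + d, ch)] <- cols[[k]][ch]
      }
    }
  }
  if (is.null(outPath))
    outPath <- paste0(tools::file_path_sans_ext(imagePath), "-overlay.jpg")
  writeJPEGImage(img, outPath, 90)
  invisible(outPath)
}

## Feature matrices ---------------------------------------------------------

#' Build a feature matrix for a set of image assets
#'
#' Extracts [extractFeatures()] for each selected image asset and assembles a
#' [DeckFeatureSet-class] (a SummarizedExperiment: features as rows, assets
#' as columns) annotated with asset ids, source labels and the config
#' fingerprint. Row order is deterministic (ascending asset id).
#'
#' @param lib A [MediaLibrary-class].
#' @param assetIds Asset ids; must all be images (default: every image asset).
#' @param config A [FeatureConfig-class].
#' @return A [DeckFeatureSet-class].
#' @export
featureMatrix <- function(lib, assetIds = NULL, config = featureConfig()) {
  assets <- listAssets(lib)
  if (is.null(assetIds)) assetIds <- assets$id[assets$media_type == "image"]
  if (!length(assetIds)) deckValidationError("asset selection is empty")
  sel <- assets[assets$id %in% assetIds, ]
  if (nrow(sel) != length(unique(assetIds)))
    deckNotFoundError("selection contains unknown asset ids")
  vids <- sel$id[sel$media_type != "image"]
  if (length(vids))
    deckValidationError(paste0("feature extraction needs image assets; videos: ",
                               paste(vids, collapse = ", ")))
  sel <- sel[order(sel$id), ]
  root <- libraryRoot(lib)
  vals <- vapply(seq_len(nrow(sel)), function(i)
    extractFeatures(file.path(root, sel$original_path[i]), config),
    numeric(featureLength(config)))
  ## vals is features x assets already
  newDeckFeatureSet(vals, sel$id, sel$source_label, config)
}

newDeckFeatureSet <- function(featByAsset, assetIds, sourceLabels, config,
                              fingerprint = NULL) {
  colnames(featByAsset) <- as.character(assetIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = featByAsset),
    colData = S4Vectors::DataFrame(asset_id = assetIds,
                                   source_label = sourceLabels,
                                   row.names = as.character(assetIds)))
  S4Vectors::metadata(se)$config <- config
  S4Vectors::metadata(se)$fingerprint <- fingerprint %||%
    (if (is.null(config)) "unspecified" else configFingerprint(config))
  new("DeckFeatureSet", se)
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' One row per asset (leading columns `asset_id`, `source_label`), header
#' row with the exact feature names, deterministic row order (ascending
#' asset id); the sidecar `<out>.json` records the configuration and its
#' fingerprint. Re-export with the same config is byte-identical.
#'
#' @param lib A [MediaLibrary-class].
#' @param assetIds Image asset ids (default: all image assets).
#' @param config A [FeatureConfig-class].
#' @param outPath Output CSV path.
#' @return `outPath`, invisibly.
#' @export
exportFeatureMatrix <- function(lib, assetIds = NULL, config = featureConfig(),
                                outPath) {
  fs <- featureMatrix(lib, assetIds, config)
  writeFeatureCSV(fs, outPath)
}

writeFeatureCSV <- function(fs, outPath) {
  vals <- featureValues(fs)
  cd <- SummarizedExperiment::colData(fs)
  df <- data.frame(asset_id = cd$asset_id, source_label = cd$source_label,
                   vals, check.names = FALSE)
  utils::write.csv(df, outPath, row.names = FALSE)
  cfg <- S4Vectors::metadata(fs)$config
  sidecar <- list(fingerprint = S4Vectors::metadata(fs)$fingerprint)
  if (!is.null(cfg))
    sidecar$config <- list(resamplePoints = cfg@resamplePoints,
                           histBins = cfg@histBins, tileGrid = cfg@tileGrid,
                           includeRawProfiles = cfg@includeRawProfiles,
                           entropyBins = cfg@entropyBins)
  jsonlite::write_json(sidecar, paste0(outPath, ".json"), auto_unbox = TRUE)
  invisible(outPath)
}

#' Read a feature-matrix CSV back into a DeckFeatureSet
#'
#' @param csvPath CSV written by [exportFeatureMatrix()].
#' @return A [DeckFeatureSet-class]; the fingerprint is taken from the JSON
#'   sidecar when present.
#' @export
loadFeatureMatrix <- function(csvPath) {
  df <- utils::read.csv(csvPath, check.names = FALSE)
  if (!all(c("asset_id", "source_label") %in% names(df)))
    deckValidationError("feature CSV must have asset_id and source_label columns")
  vals <- t(as.matrix(df[, setdiff(names(df), c("asset_id", "source_label")),
                         drop = FALSE]))
  side <- paste0(csvPath, ".json")
  fp <- if (file.exists(side)) jsonlite::read_json(side)$fingerprint else "unspecified"
  newDeckFeatureSet(vals, df$asset_id, df$source_label, config = NULL,
                    fingerprint = fp %||% "unspecified")
}
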