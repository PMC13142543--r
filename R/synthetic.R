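## Programmatic test media: clustered image populations with controllable
## colour/texture structure, duplicate-laden directory trees, and (when a
## video toolkit is present) small test videos. PNG output is used for the
## populations because its encoding is lossless and byte-deterministic.

#' Specification of a synthetic image population
#'
#' Describes one cluster of images sharing a base colour with per-image mean
#' jitter, per-pixel Gaussian noise and an optional texture pattern. Each
#' image is seeded counter-style as `seed + index`, so a population can be
#' extended without shifting existing images.
#'
#' @param name Population name (used in file names and as a label).
#' @param n Number of images (>= 1).
#' @param size `c(W, H)` in pixels.
#' @param baseRGB Mean colour, three values in `[0, 1]`.
#' @param rgbJitter SD of the per-image mean-colour perturbation.
#' @param noiseSigma SD of the per-pixel Gaussian noise.
#' @param texture `"flat"`, `"stripes"` or `"blobs"`.
#' @param stripePeriod Stripe period in pixels (stripes only).
#' @param seed Integer base seed.
#' @return A validated `PopulationSpec` (named list).
#' @export
populationSpec <- function(name, n, size = c(64, 64), baseRGB = c(0.5, 0.5, 0.5),
                           rgbJitter = 0.02, noiseSigma = 0.05,
                           texture = c("flat", "stripes", "blobs"),
                           stripePeriod = 8, seed = 1) {
  texture <- match.arg(texture)
  if (n < 1) deckValidationError("population size n must be >= 1")
  if (rgbJitter < 0 || noiseSigma < 0) deckValidationError("sigmas must be >= 0")
  if (length(baseRGB) != 3 || any(baseRGB < 0 | baseRGB > 1))
    deckValidationError("baseRGB must be three values in [0, 1]")
  structure(list(name = name, n = as.integer(n), size = as.integer(size),
                 baseRGB = as.numeric(baseRGB), rgbJitter = rgbJitter,
                 noiseSigma = noiseSigma, texture = texture,
                 stripePeriod = stripePeriod, seed = as.integer(seed)),
            class = "PopulationSpec")
}

syntheticImage <- function(spec, index) {
  set.seed(spec$seed + index)
  W <- spec$size[1]; H <- spec$size[2]
  base <- clip01(spec$baseRGB + rnorm(3) * spec$rgbJitter)
  img <- array(rep(base, each = H * W), dim = c(H, W, 3))
  if (spec$texture == "stripes") {
    stripe <- 0.12 * ((floor(col(matrix(0, H, W)) / spec$stripePeriod) %% 2) * 2 - 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + stripe
  } else if (spec$texture == "blobs") {
    nb <- 5L
    cx <- runif(nb, 1, W); cy <- runif(nb, 1, H); amp <- runif(nb, 0.08, 0.18)
    sg <- max(W, H) / 8
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    bump <- Reduce(`+`, lapply(seq_len(nb), function(b)
      amp[b] * exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * sg^2))))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + bump
  }
  if (spec$noiseSigma > 0)
    img <- img + array(rnorm(H * W * 3, sd = spec$noiseSigma), dim = dim(img))
  clip01(img)
}

#' Generate a population of synthetic PNG images
#'
#' Deterministic for a fixed seed: re-running produces byte-identical files.
#'
#' @param spec A [populationSpec()].
#' @param outDir Writable output directory (created if absent).
#' @return Character vector of written PNG paths, in index order.
#' @examples
#' d <- file.path(tempdir(), "pop")
#' paths <- makePopulation(populationSpec("demo", 3, seed = 7), d)
#' basename(paths)
#' @export
makePopulation <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_len(spec$n), function(i) {
    p <- file.path(outDir, sprintf("%s_%04d.png", spec$name, i))
    png::writePNG(syntheticImage(spec, i), p)
    p
  }, character(1))
}

#' The canonical three-population fixture
#'
#' Three populations of `n` images each whose base colours are pairwise at
#' least 0.3 apart in RGB L2 distance, with per-pixel noise `sigma = 0.05`
#' -- colour/texture structure strong enough that a faithful feature +
#' embedding pipeline must separate them, while single pixels remain noisy.
#'
#' @param outDir Output directory; one subdirectory per population.
#' @param n Images per population (default 100).
#' @param seed Base seed; population `i` uses `seed + 1000 * i`.
#' @param size Image size `c(W, H)` (default 64 x 64).
#' @return data.frame with `path` and `population` for every written image.
#' @export
makeThreePopulations <- function(outDir, n = 100, seed = 1, size = c(64, 64)) {
  specs <- list(
    populationSpec("pop_pink",  n, size, baseRGB = c(0.80, 0.55, 0.65),
                   texture = "flat",    seed = seed + 1000L),
    populationSpec("pop_blue",  n, size, baseRGB = c(0.35, 0.45, 0.80),
                   texture = "stripes", seed = seed + 2000L),
    populationSpec("pop_green", n, size, baseRGB = c(0.45, 0.75, 0.40),
                   texture = "blobs",   seed = seed + 3000L))
  do.call(rbind, lapply(specs, function(s) {
    paths <- makePopulation(s, file.path(outDir, s$name))
    data.frame(path = paths, population = s$name)
  }))
}

#' Generate a duplicate-laden directory tree with ground truth
#'
#' Builds a nested tree of unique images plus byte-identical copies under
#' different names and folders, and optionally unsupported files and
#' corrupted (truncated) images. A `manifest.csv` with the ground truth is
#' written next to (not inside) the tree, so importing the tree sees only
#' the planted files.
#'
#' @param baseDir Writable directory; the tree goes in `<baseDir>/tree`.
#' @param nUnique Number of distinct images.
#' @param nDup Number of byte-identical copies of randomly chosen uniques.
#' @param depth Maximum folder nesting (default 3).
#' @param seed Integer seed (full determinism).
#' @param nUnsupported Number of non-media (`.txt`) files to plant.
#' @param nCorrupt Number of truncated `.png` files to plant.
#' @return List with `root` (the tree to import) and `manifest` (data.frame:
#'   `kind` in unique/duplicate/unsupported/corrupt, `path`, `source_path`).
#' @export
makeDuplicateTree <- function(baseDir, nUnique, nDup, depth = 3, seed = 1,
                              nUnsupported = 0, nCorrupt = 0) {
  dir.create(baseDir, recursive = TRUE, showWarnings = FALSE)
  root <- file.path(baseDir, "tree")
  dir.create(root, showWarnings = FALSE)
  set.seed(seed)
  folders <- c("", unlist(lapply(seq_len(depth), function(d)
    replicate(2, paste(sprintf("lvl%d_%s", seq_len(d),
      sample(letters, d, replace = TRUE)), collapse = "/")))))
  pickFolder <- function() {
    f <- sample(folders, 1)
    if (nzchar(f)) dir.create(file.path(root, f), recursive = TRUE,
                              showWarnings = FALSE)
    f
  }
  rows <- list()
  addRow <- function(kind, path, src = NA_character_)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, path = path,
                                             source_path = src)
  uniques <- character(nUnique)
  for (i in seq_len(nUnique)) {
    set.seed(seed * 10000L + i)
    w <- sample(16:40, 1); h <- sample(16:40, 1)
    img <- clip01(array(runif(h * w * 3), dim = c(h, w, 3)))
    f <- pickFolder()
    p <- file.path(root, if (nzchar(f)) f else ".", sprintf("unique_%03d.png", i))
    p <- normalizePath(p, mustWork = FALSE)
    png::writePNG(img, p)
    uniques[i] <- p
    addRow("unique", p)
  }
  set.seed(seed + 1L)
  for (i in seq_len(nDup)) {
    src <- sample(uniques, 1)
    f <- pickFolder()
    p <- file.path(root, if (nzchar(f)) f else ".", sprintf("copy_%03d.png", i))
    p <- normalizePath(p, mustWork = FALSE)
    file.copy(src, p)
    addRow("duplicate", p, src)
  }
  for (i in seq_len(nUnsupported)) {
    p <- file.path(root, sprintf("notes_%02d.txt", i))
    writeLines(sprintf("sidecar notes %d", i), p)
    addRow("unsupported", p)
  }
  for (i in seq_len(nCorrupt)) {
    src <- uniques[1 + (i - 1) %% length(uniques)]
    bytes <- readBin(src, "raw", n = 100)
    p <- file.path(root, sprintf("corrupt_%02d.png", i))
    writeBin(bytes, p)
    addRow("corrupt", p)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(baseDir, "manifest.csv"), row.names = FALSE)
  list(root = root, manifest = manifest)
}

#' Generate a small solid-colour test video
#'
#' Requires an `ffmpeg`-compatible executable; when the toolkit is missing
#' this raises an explicit environment error so callers (and tests) can
#' branch on [videoToolkitAvailable()].
#'
#' @param outPath Output video path (container from the extension).
#' @param seconds Duration in seconds.
#' @param size `c(W, H)` in pixels.
#' @param fps Frames per second.
#' @return `outPath`, invisibly.
#' @export
makeTestVideo <- function(outPath, seconds = 2, size = c(128, 96), fps = 10) {
  ffmpeg <- toolkitPath("ffmpeg")
  if (!nzchar(ffmpeg))
    deckEnvironmentError("test video generation requires 'ffmpeg' on the PATH")
  args <- c("-y", "-f", "lavfi", "-i",
            sprintf("color=c=steelblue:s=%dx%d:r=%g:d=%g",
                    size[1], size[2], fps, seconds),
            "-pix_fmt", "yuv420p", shQuote(outPath))
  out <- suppressWarnings(system2(ffmpeg, args, stdout = TRUE, stderr = TRUE))
  if ((attr(out, "status") %||% 0L) != 0L)
    deckStop("mediadeck_decode_error", "test video generation failed")
  invisible(outPath)
}
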