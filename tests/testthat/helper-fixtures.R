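# Shared fixture builders. Everything is generated in code under tempdir();
# nothing binary ships with the package.

tmpLibrary <- function() {
  root <- tempfile("lib-")
  lib <- initLibrary(root)
  withr::defer(closeLibrary(lib), envir = parent.frame())
  lib
}

randomImage <- function(seed, w = 16, h = 16) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

constantImage <- function(rgb, w = 16, h = 16) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

writePng <- function(img, path = tempfile(fileext = ".png")) {
  png::writePNG(img, path)
  path
}

# Small tree of supported/unsupported files for enumeration tests
writeTree <- function(files) {
  root <- tempfile("tree-")
  dir.create(root)
  for (f in names(files)) {
    p <- file.path(root, f)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    if (is.character(files[[f]])) writeLines(files[[f]], p)
    else png::writePNG(files[[f]], p)
  }
  root
}

# A registered image asset without touching the ingest pipeline (store tests)
fakeAsset <- function(lib, filename, source = "src", seed = 1, folder = "") {
  img <- randomImage(seed, 8, 8)
  rel <- file.path("originals", paste0("tmp-", seed, "-", filename))
  p <- file.path(libraryRoot(lib), rel)
  png::writePNG(img, p)
  dg <- sha256File(p)
  final <- file.path("originals", paste0(dg, ".png"))
  file.rename(p, file.path(libraryRoot(lib), final))
  putAsset(lib, list(
    original_filename = filename,
    display_name = tools::file_path_sans_ext(filename),
    folder_context = folder, source_label = source,
    media_type = "image", width = 8, height = 8,
    file_size = file.info(file.path(libraryRoot(lib), final))$size,
    sha256 = dg, original_path = final))
}
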