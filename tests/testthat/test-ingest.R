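test_that("sha256File matches the published digest test vectors", {
  f1 <- tempfile(); file.create(f1)
  expect_identical(sha256File(f1),
    "e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855")
  f2 <- tempfile(); writeBin(charToRaw("abc"), f2)
  expect_identical(sha256File(f2),
    "ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad")
})

test_that("the digest is a pure function of content, not name or chunking", {
  set.seed(9)
  bytes <- as.raw(sample(0:255, 3 * 1024 * 1024, replace = TRUE))  # > 1 chunk
  f1 <- tempfile("alpha-"); writeBin(bytes, f1)
  f2 <- tempfile("beta-");  writeBin(bytes, f2)
  expect_identical(sha256File(f1), sha256File(f2))
  # one-shot write vs many small appends: same digest
  f3 <- tempfile()
  con <- file(f3, "wb")
  for (i in seq(1, length(bytes), by = 1111))
    writeBin(bytes[i:min(i + 1110, length(bytes))], con)
  close(con)
  expect_identical(sha256File(f3), sha256File(f1))
})

test_that("enumeration is deterministic, classifies every file once and skips hidden", {
  expect_identical(nrow(enumerateMedia(withr::local_tempdir())$candidates), 0L)

  img <- constantImage(c(0.5, 0.5, 0.5), 4, 4)
  root <- writeTree(list("b.png" = img, "sub/a.png" = img, "sub/z.png" = img,
                         "notes.txt" = "x", ".hidden.png" = img,
                         "sub/.DS_Store" = "junk"))
  e <- enumerateMedia(root)
  expect_identical(nrow(e$candidates), 3L)
  expect_identical(e$skipped, 3L)                  # .txt + two hidden files
  expect_identical(basename(e$candidates$path), c("b.png", "a.png", "z.png"))
  expect_identical(e$candidates$relative_folder, c("", "sub", "sub"))
  expect_identical(e$candidates$media_type, rep("image", 3))
  # rerun: identical order
  expect_identical(enumerateMedia(root)$candidates$path, e$candidates$path)
})

test_that("symlinked directory cycles terminate with each real file seen once", {
  skip_if_not(.Platform$OS.type == "unix")
  root <- writeTree(list("a.png" = constantImage(c(0.1, 0.2, 0.3), 4, 4)))
  dir.create(file.path(root, "sub"))
  png::writePNG(constantImage(c(0.9, 0.1, 0.1), 4, 4), file.path(root, "sub", "b.png"))
  file.symlink(root, file.path(root, "sub", "loop"))   # cycle back to root
  e <- enumerateMedia(root)
  expect_identical(sort(basename(e$candidates$path)), c("a.png", "b.png"))
})

test_that("image metadata reports true decoded dimensions and format", {
  p1 <- writePng(constantImage(c(0.2, 0.4, 0.6), w = 64, h = 48))
  m <- extractImageMetadata(p1)
  expect_identical(c(m$width, m$height), c(64L, 48L))
  expect_identical(m$format, "PNG")

  p2 <- tempfile(fileext = ".jpeg")
  jpeg::writeJPEG(constantImage(c(0.5, 0.5, 0.5), 1, 1), p2)
  m2 <- extractImageMetadata(p2)
  expect_identical(c(m2$width, m2$height), c(1L, 1L))
  expect_identical(m2$format, "JPEG")

  trunc <- tempfile(fileext = ".png")
  writeBin(readBin(p1, "raw", 100), trunc)
  expect_error(extractImageMetadata(trunc), class = "mediadeck_decode_error")
})

test_that("video probing degrades to clear errors without the toolkit", {
  if (!videoToolkitAvailable()) {
    expect_error(extractVideoMetadata(tempfile(fileext = ".mp4")),
                 class = "mediadeck_environment_error")
    expect_match(tryCatch(extractVideoMetadata("x.mp4"), error = conditionMessage),
                 "ffprobe")
  } else {
    v <- makeTestVideo(tempfile(fileext = ".mp4"), seconds = 2, size = c(128, 96))
    m <- extractVideoMetadata(v)
    expect_identical(c(m$width, m$height), c(128L, 96L))
    expect_lt(abs(m$duration - 2), 0.1)
    p <- writePng(constantImage(c(0.5, 0.5, 0.5), 8, 8))
    img_as_video <- sub("png$", "mp4", p); file.copy(p, img_as_video)
    expect_error(extractVideoMetadata(img_as_video))
    empty <- tempfile(fileext = ".mp4"); file.create(empty)
    expect_error(extractVideoMetadata(empty))
  }
})

test_that("detectDuplicate resolves by digest across the whole library", {
  lib <- tmpLibrary()
  expect_true(is.na(detectDuplicate(lib, strrep("0", 64))))
  id <- fakeAsset(lib, "x.png", seed = 61)
  expect_identical(detectDuplicate(lib, getAsset(lib, id)$sha256), id)
})

test_that("an import job accounts for every discovered file exactly once", {
  lib <- tmpLibrary()
  base <- tempfile("dt-")
  dt <- makeDuplicateTree(base, nUnique = 5, nDup = 0, seed = 3)
  job <- importDirectory(lib, dt$root, "fresh")
  expect_identical(job$status, "completed")
  expect_identical(job$discovered_count, 5L)
  expect_identical(job$processed_count, 5L)
  expect_identical(job$duplicate_count + job$skipped_count + job$failed_count, 0L)
  expect_true(file.exists(file.path(libraryRoot(lib), job$log_path)))

  # immediate re-import: everything is a duplicate, nothing new registered
  job2 <- importDirectory(lib, dt$root, "again")
  expect_identical(job2$processed_count, 0L)
  expect_identical(job2$duplicate_count, job$processed_count)
  expect_identical(nrow(listAssets(lib)), 5L)
  ev <- duplicateEvents(lib, job2$id)
  expect_identical(nrow(ev), 5L)
  expect_true(all(ev$existing_asset_id %in% listAssets(lib)$id))
})

test_that("corrupted and unsupported files hit the failed/skipped counters", {
  lib <- tmpLibrary()
  dt <- makeDuplicateTree(tempfile("dt-"), nUnique = 4, nDup = 0, seed = 5,
                          nUnsupported = 2, nCorrupt = 1)
  job <- importDirectory(lib, dt$root, "mixed")
  expect_identical(job$processed_count, 4L)
  expect_identical(job$failed_count, 1L)
  expect_identical(job$skipped_count, 2L)
  expect_identical(job$discovered_count,
    job$processed_count + job$duplicate_count + job$skipped_count + job$failed_count)
  log <- readLines(file.path(libraryRoot(lib), job$log_path))
  expect_true(any(grepl("FAILED .*corrupt_01", log)))
  expect_true(any(grepl("SKIPPED .*notes_01", log)))
})

test_that("within-job duplicates resolve deterministically: first wins", {
  lib <- tmpLibrary()
  img <- randomImage(77, 10, 10)
  root <- writeTree(list("a_first.png" = img, "z_second.png" = img))
  job <- importDirectory(lib, root, "dup")
  expect_identical(job$processed_count, 1L)
  expect_identical(job$duplicate_count, 1L)
  a <- listAssets(lib)
  expect_identical(a$original_filename, "a_first.png")   # lexicographic order
  ev <- duplicateEvents(lib, job$id)
  expect_match(ev$candidate_path, "z_second")
  expect_identical(ev$existing_asset_id, a$id)
  expect_identical(ev$sha256, a$sha256)
})

test_that("a missing source root fails the job with a reason", {
  lib <- tmpLibrary()
  id <- submitImportJob(lib, file.path(tempfile(), "nowhere"), "gone")
  job <- runImportJob(lib, id)
  expect_identical(job$status, "failed")
  expect_match(job$failure_reason, "does not exist")
  expect_error(runImportJob(lib, id), class = "mediadeck_validation_error")
})

test_that("the final asset set is order-independent across import order", {
  mk <- function(seedA) {
    dtA <- makeDuplicateTree(tempfile(), nUnique = 3, nDup = 1, seed = 8)
    dtB <- makeDuplicateTree(tempfile(), nUnique = 3, nDup = 0, seed = 9)
    list(a = dtA$root, b = dtB$root)
  }
  t1 <- mk(); t2 <- mk()
  lib1 <- tmpLibrary()
  importDirectory(lib1, t1$a, "A"); importDirectory(lib1, t1$b, "B")
  lib2 <- tmpLibrary()
  importDirectory(lib2, t2$b, "B"); importDirectory(lib2, t2$a, "A")
  expect_identical(sort(listAssets(lib1)$sha256), sort(listAssets(lib2)$sha256))
})

test_that("imported originals stay byte-identical to their hash (audit)", {
  lib <- tmpLibrary()
  dt <- makeDuplicateTree(tempfile("dt-"), nUnique = 6, nDup = 2, seed = 12)
  importDirectory(lib, dt$root, "audited")
  regenerateDerivatives(lib)
  rep <- auditLibrary(lib)
  expect_true(rep$ok)
  expect_identical(rep$hash_verified, 6L)
  expect_identical(nrow(rep$problems), 0L)
})

test_that("the worker drains queued jobs in submission order, each exactly once", {
  lib <- tmpLibrary()
  dt1 <- makeDuplicateTree(tempfile(), nUnique = 2, nDup = 0, seed = 21)
  dt2 <- makeDuplicateTree(tempfile(), nUnique = 2, nDup = 0, seed = 22)
  j1 <- submitImportJob(lib, dt1$root, "one")
  j2 <- submitImportJob(lib, dt2$root, "two")
  expect_identical(pollJobs(lib, drain = TRUE), 2L)
  jobs <- listImportJobs(lib)
  expect_identical(jobs$status, c("completed", "completed"))
  expect_true(jobs$finished_at[1] <= jobs$finished_at[2])
  expect_identical(pollJobs(lib, drain = TRUE), 0L)   # empty queue returns at once

  # claim is atomic: a second handle can never claim an already-claimed job
  j3 <- submitImportJob(lib, dt1$root, "three")
  lib2 <- openLibrary(libraryRoot(lib))
  c1 <- MediaDeck:::claimNextImportJob(lib)
  c2 <- MediaDeck:::claimNextImportJob(lib2)
  expect_identical(c1, j3)
  expect_true(is.na(c2))
  closeLibrary(lib2)
})
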