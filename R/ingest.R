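## Asynchronous import pipeline: enumerate -> hash -> dedup -> copy into
## immutable storage -> extract metadata -> generate derivatives -> register.

#' SHA-256 digest of a file's bytes
#'
#' Streams the file in fixed-size chunks, so memory use is constant in the
#' file size; the digest depends only on content, never on the file name.
#'
#' @param path Readable file.
#' @return 64-character lowercase hex digest.
#' @examples
#' f <- tempfile(); writeBin(charToRaw("abc"), f)
#' sha256File(f)  # ba7816bf8f01cfea...
#' @export
sha256File <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    deckStop("mediadeck_io_error", paste0("cannot hash, not a readable file: ", path))
  digest::digest(path, algo = "sha256", file = TRUE, serialize = FALSE)
}

#' Look up an asset by content hash
#'
#' Duplicate detection is library-wide: a candidate whose digest matches any
#' previously imported asset, from any source, is a duplicate.
#'
#' @param lib A [MediaLibrary-class].
#' @param digest 64-character hex sha256.
#' @return Existing asset id (integer) or `NA` if the digest is new.
#' @export
detectDuplicate <- function(lib, digest) {
  id <- DBI::dbGetQuery(dbcon(lib), "SELECT id FROM assets WHERE sha256 = ?",
                        params = list(digest))$id
  if (length(id)) as.integer(id) else NA_integer_
}

## Enumeration --------------------------------------------------------------

classifyExtension <- function(path) {
  ext <- fileExtLower(path)
  if (ext %in% IMAGE_EXTENSIONS) "image"
  else if (ext %in% VIDEO_EXTENSIONS) "video"
  else NA_character_
}

#' Enumerate media candidates under a directory
#'
#' Depth-first traversal in deterministic order (lexicographic by relative
#' path, bytewise). Hidden entries (leading `.`) are not descended; hidden
#' and unsupported regular files are counted as skipped. Symlinked
#' directories are followed at most once via a visited set on resolved
#' paths, so cycles terminate and every real file is classified exactly
#' once.
#'
#' @param sourceRoot Readable directory.
#' @return List with `candidates` (data.frame: `path`, `relative_folder`,
#'   `media_type`, `file_size`, ordered), `skipped` (count) and
#'   `skipped_paths`.
#' @export
enumerateMedia <- function(sourceRoot) {
  if (!dir.exists(sourceRoot))
    deckNotFoundError(paste0("source root does not exist: ", sourceRoot))
  if (file.access(sourceRoot, 4L) != 0L)
    deckPermissionError(paste0("source root is not readable: ", sourceRoot))
  sourceRoot <- normalizePath(sourceRoot)
  visited <- new.env(parent = emptyenv())
  cand <- list(); skipped <- character()
  walk <- function(dirPath, rel) {
    real <- tryCatch(normalizePath(dirPath), error = function(e) dirPath)
    if (!is.null(visited[[real]])) return(invisible())
    visited[[real]] <- TRUE
    if (file.access(dirPath, 4L) != 0L) {
      skipped <<- c(skipped, paste0(dirPath, " [unreadable directory]"))
      return(invisible())
    }
    entries <- list.files(dirPath, all.files = TRUE, no.. = TRUE)
    entries <- sort(entries, method = "radix")
    for (e in entries) {
      p <- file.path(dirPath, e)
      r <- if (nzchar(rel)) paste0(rel, "/", e) else e
      hidden <- startsWith(e, ".")
      if (dir.exists(p)) {
        if (!hidden) walk(p, r)          # hidden dirs: never descended
      } else if (hidden) {
        skipped <<- c(skipped, p)
      } else {
        mt <- classifyExtension(e)
        if (is.na(mt)) {
          skipped <<- c(skipped, p)
        } else {
          cand[[length(cand) + 1L]] <<- list(
            path = p, relative_folder = if (nzchar(rel)) dirname(r) else "",
            media_type = mt, file_size = file.size(p))
        }
      }
    }
  }
  walk(sourceRoot, "")
  candidates <- if (length(cand)) {
    df <- do.call(rbind, lapply(cand, as.data.frame))
    df$relative_folder[df$relative_folder == "."] <- ""
    df
  } else {
    data.frame(path = character(), relative_folder = character(),
               media_type = character(), file_size = numeric())
  }
  list(candidates = candidates, skipped = length(skipped), skipped_paths = skipped)
}

## Metadata extraction ------------------------------------------------------

#' Pixel dimensions and format of an image file
#'
#' Decodes the image and reports its true pixel dimensions; for JPEGs a
#' minimal EXIF scan applies the orientation tag, so rotated captures report
#' their display dimensions (orientations 5--8 swap width and height).
#'
#' @param path Image file.
#' @return List `width`, `height`, `format`.
#' @export
extractImageMetadata <- function(path) {
  img <- readImageRGB(path)
  w <- dim(img)[2]; h <- dim(img)[1]
  ext <- fileExtLower(path)
  fmt <- switch(ext, png = "PNG", jpg = , jpeg = "JPEG", tif = , tiff = "TIFF", toupper(ext))
  if (fmt == "JPEG") {
    orient <- tryCatch(jpegExifOrientation(path), error = function(e) 1L)
    if (orient %in% 5:8) { tmp <- w; w <- h; h <- tmp }
  }
  list(width = as.integer(w), height = as.integer(h), format = fmt)
}

#' Dimensions, duration and container of a video file
#'
#' Uses an `ffprobe`-compatible external prober in JSON mode. When the
#' prober is not on the PATH this raises an environment error naming the
#' dependency; import jobs count such candidates as failed rather than
#' aborting.
#'
#' @param path Video file.
#' @return List `width`, `height`, `duration` (seconds), `format`.
#' @export
extractVideoMetadata <- function(path) {
  probe <- toolkitPath("ffprobe")
  if (!nzchar(probe))
    deckEnvironmentError("video probing requires 'ffprobe' on the PATH")
  if (!file.exists(path) || file.size(path) == 0)
    deckStop("mediadeck_decode_error", paste0("empty or missing video file: ", path))
  out <- suppressWarnings(system2(probe,
    c("-v", "error", "-print_format", "json", "-show_format", "-show_streams",
      shQuote(path)), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  parsed <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "\n"),
                                        simplifyDataFrame = TRUE),
                     error = function(e) NULL)
  if (status != 0L || is.null(parsed) || is.null(parsed$streams))
    deckStop("mediadeck_decode_error", paste0("cannot probe video: ", path))
  st <- parsed$streams
  vs <- st[st$codec_type == "video", , drop = FALSE]
  if (!nrow(vs)) deckStop("mediadeck_decode_error", paste0("no video stream in: ", path))
  dur <- suppressWarnings(as.numeric(parsed$format$duration))
  if (!length(dur) || is.na(dur)) dur <- suppressWarnings(as.numeric(vs$duration[1]))
  if (!length(dur) || is.na(dur))
    deckStop("mediadeck_decode_error", paste0("no duration in container: ", path))
  fmt <- toupper(strsplit(parsed$format$format_name %||% fileExtLower(path), ",")[[1]][1])
  list(width = as.integer(vs$width[1]), height = as.integer(vs$height[1]),
       duration = dur, format = fmt)
}

## Jobs ---------------------------------------------------------------------

#' Queue an import job
#'
#' Registers a pending job for the worker ([runImportJob()] or [pollJobs()]).
#'
#' @param lib A [MediaLibrary-class].
#' @param sourceRoot Directory tree to import (copied, never moved).
#' @param sourceLabel Provenance label applied to every asset of the job.
#' @return The new job id (integer).
#' @export
submitImportJob <- function(lib, sourceRoot, sourceLabel = "") {
  con <- dbcon(lib)
  DBI::dbExecute(con,
    "INSERT INTO import_jobs (source_root, source_label, created_at)
     VALUES (?,?,?)", params = list(sourceRoot, sourceLabel, utcNow()))
  as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id)
}

#' Fetch import job rows
#' @param lib A [MediaLibrary-class].
#' @param jobId Job id.
#' @return One-row (or, for `listImportJobs`, many-row) data.frame.
#' @export
getImportJob <- function(lib, jobId) {
  df <- DBI::dbGetQuery(dbcon(lib), "SELECT * FROM import_jobs WHERE id = ?",
                        params = list(as.integer(jobId)))
  if (!nrow(df)) deckNotFoundError(paste0("no import job with id ", jobId))
  df
}

#' @rdname getImportJob
#' @export
listImportJobs <- function(lib) {
  DBI::dbGetQuery(dbcon(lib), "SELECT * FROM import_jobs ORDER BY id")
}

#' Duplicate events recorded for a job (or the whole library)
#' @param lib A [MediaLibrary-class].
#' @param jobId Optional job id filter.
#' @return data.frame of duplicate events.
#' @export
duplicateEvents <- function(lib, jobId = NULL) {
  if (is.null(jobId))
    DBI::dbGetQuery(dbcon(lib), "SELECT * FROM duplicate_events ORDER BY id")
  else
    DBI::dbGetQuery(dbcon(lib),
      "SELECT * FROM duplicate_events WHERE import_job_id = ? ORDER BY id",
      params = list(as.integer(jobId)))
}

bumpJobCount <- function(lib, jobId, col) {
  DBI::dbExecute(dbcon(lib),
    sprintf("UPDATE import_jobs SET %s = %s + 1 WHERE id = ?", col, col),
    params = list(jobId))
}

jobLog <- function(logFile, ...) {
  cat(paste0("[", utcNow(), "] ", paste0(...), "\n"), file = logFile, append = TRUE)
}

## Atomically claim a pending job (oldest first). BEGIN IMMEDIATE takes the
## write lock before the read, so two workers can never claim the same job.
claimNextImportJob <- function(lib) {
  con <- dbcon(lib)
  withTransaction(lib, {
    id <- DBI::dbGetQuery(con,
      "SELECT id FROM import_jobs WHERE status = 'pending' ORDER BY id LIMIT 1")$id
    if (!length(id)) return(NA_integer_)
    DBI::dbExecute(con,
      "UPDATE import_jobs SET status = 'running', started_at = ?
       WHERE id = ? AND status = 'pending'", params = list(utcNow(), id))
    as.integer(id)
  })
}

#' Execute one import job
#'
#' Runs the full pipeline for a pending job: enumerate candidates
#' ([enumerateMedia()]), hash each file ([sha256File()]), check for
#' duplicates library-wide; duplicates produce a duplicate-event record,
#' novel files are copied into `originals/` under their content-addressed
#' name `<sha256>.<ext>`, the copy's digest is verified against the source,
#' metadata is extracted, derivatives are generated, and the asset row is
#' inserted (copy-verify-insert ordering, so a crash never leaves a
#' registered asset without its bytes). Every skipped, failed or duplicate
#' file gets one line in the job's log under `logs/`.
#'
#' On completion the accounting identity holds exactly:
#' `discovered = processed + duplicates + skipped + failed`.
#'
#' @param lib A [MediaLibrary-class].
#' @param jobId Id of a pending job (see [submitImportJob()]).
#' @param derivSpec A [DerivativeSpec-class]; defaults to `derivativeSpec()`.
#' @param claimed Internal: set when [pollJobs()] already flipped the status.
#' @return The completed job row (one-row data.frame).
#' @export
runImportJob <- function(lib, jobId, derivSpec = derivativeSpec(), claimed = FALSE) {
  con <- dbcon(lib)
  job <- getImportJob(lib, jobId)
  if (!claimed) {
    if (job$status != "pending")
      deckValidationError(paste0("job ", jobId, " is not pending (status: ", job$status, ")"))
    DBI::dbExecute(con,
      "UPDATE import_jobs SET status = 'running', started_at = ? WHERE id = ?",
      params = list(utcNow(), jobId))
  }
  logFile <- file.path(libraryRoot(lib), "logs", sprintf("import-%d.log", jobId))
  DBI::dbExecute(con, "UPDATE import_jobs SET log_path = ? WHERE id = ?",
                 params = list(file.path("logs", basename(logFile)), jobId))
  jobLog(logFile, "job ", jobId, " started: ", job$source_root)
  failJob <- function(reason) {
    jobLog(logFile, "JOB FAILED: ", reason)
    DBI::dbExecute(con,
      "UPDATE import_jobs SET status = 'failed', finished_at = ?, failure_reason = ?
       WHERE id = ?", params = list(utcNow(), reason, jobId))
    getImportJob(lib, jobId)
  }
  if (!dir.exists(job$source_root))
    return(failJob(paste0("source root does not exist: ", job$source_root)))

  enumr <- tryCatch(enumerateMedia(job$source_root),
                    error = function(e) e)
  if (inherits(enumr, "error")) return(failJob(conditionMessage(enumr)))

  discovered <- nrow(enumr$candidates) + enumr$skipped
  DBI::dbExecute(con,
    "UPDATE import_jobs SET discovered_count = ?, skipped_count = ? WHERE id = ?",
    params = list(discovered, enumr$skipped, jobId))
  for (p in enumr$skipped_paths) jobLog(logFile, "SKIPPED ", p)

  for (i in seq_len(nrow(enumr$candidates))) {
    cnd <- enumr$candidates[i, ]
    res <- tryCatch({
      dg <- sha256File(cnd$path)
      existing <- detectDuplicate(lib, dg)
      if (!is.na(existing)) {
        DBI::dbExecute(con,
          "INSERT INTO duplicate_events (import_job_id, candidate_path, sha256,
             existing_asset_id, detected_at) VALUES (?,?,?,?,?)",
          params = list(jobId, cnd$path, dg, existing, utcNow()))
        bumpJobCount(lib, jobId, "duplicate_count")
        jobLog(logFile, "DUPLICATE ", cnd$path, " == asset ", existing)
      } else {
        ingestCandidate(lib, jobId, cnd, dg, job$source_label, derivSpec)
        bumpJobCount(lib, jobId, "processed_count")
      }
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      bumpJobCount(lib, jobId, "failed_count")
      jobLog(logFile, "FAILED ", cnd$path, ": ", conditionMessage(res))
    }
  }

  DBI::dbExecute(con,
    "UPDATE import_jobs SET status = 'completed', finished_at = ? WHERE id = ?",
    params = list(utcNow(), jobId))
  getImportJob(lib, jobId)
}

## Copy-verify-register for one novel candidate. Any error propagates to the
## caller which counts the file as failed; a partial copy is removed.
ingestCandidate <- function(lib, jobId, cnd, dg, sourceLabel, derivSpec) {
  root <- libraryRoot(lib)
  ext <- fileExtLower(cnd$path)
  relOriginal <- file.path("originals", paste0(dg, ".", ext))
  dest <- file.path(root, relOriginal)

  meta <- if (cnd$media_type == "image") extractImageMetadata(cnd$path)
          else extractVideoMetadata(cnd$path)

  if (!file.copy(cnd$path, dest, overwrite = FALSE) && !file.exists(dest))
    deckStop("mediadeck_io_error", paste0("copy failed: ", cnd$path))
  if (!identical(sha256File(dest), dg)) {
    unlink(dest)
    deckIntegrityError(paste0("copy verification failed for ", cnd$path))
  }

  paths <- if (cnd$media_type == "image") {
    d <- makeImageDerivatives(lib, dest, dg, spec = derivSpec)
    list(thumbnail_path = d$thumbnail_path, preview_path = d$preview_path,
         poster_path = NULL)
  } else {
    d <- makeVideoDerivatives(lib, dest, meta$duration, dg, spec = derivSpec)
    list(thumbnail_path = d$thumbnail_path, preview_path = d$clip_path,
         poster_path = d$poster_path)
  }

  created <- formatUTC(file.mtime(cnd$path))
  putAsset(lib, list(
    original_filename = basename(cnd$path),
    display_name = tools::file_path_sans_ext(basename(cnd$path)),
    folder_context = cnd$relative_folder,
    source_label = sourceLabel,
    media_type = cnd$media_type,
    width = meta$width, height = meta$height,
    duration = if (cnd$media_type == "video") meta$duration else NULL,
    file_size = file.size(dest),
    sha256 = dg,
    created_at = created,
    original_path = relOriginal,
    thumbnail_path = paths$thumbnail_path,
    preview_path = paths$preview_path,
    poster_path = paths$poster_path))
}

#' Poll and run queued jobs (worker loop)
#'
#' Repeatedly claims the oldest pending import or export job with an atomic
#' pending-to-running update (two workers can never claim the same job), runs
#' it, and either stops when the queue is drained (`drain = TRUE`) or sleeps
#' `interval` seconds and polls again until `maxJobs` jobs have run.
#'
#' @param lib A [MediaLibrary-class].
#' @param interval Sleep between polls, seconds (default 2).
#' @param drain Stop as soon as no pending job remains (default `TRUE`).
#' @param maxJobs Safety bound on jobs executed in this call.
#' @return Invisibly, the number of jobs executed.
#' @export
pollJobs <- function(lib, interval = 2, drain = TRUE, maxJobs = Inf) {
  ran <- 0L
  repeat {
    id <- claimNextImportJob(lib)
    if (!is.na(id)) {
      runImportJob(lib, id, claimed = TRUE)
      ran <- ran + 1L
    } else {
      eid <- claimNextExportJob(lib)
      if (!is.na(eid)) {
        runExportJob(lib, eid, claimed = TRUE)
        ran <- ran + 1L
      } else if (drain) {
        break
      } else {
        Sys.sleep(interval)
      }
    }
    if (ran >= maxJobs) break
  }
  invisible(ran)
}

#' Convenience: submit and synchronously run an import
#'
#' @param lib A [MediaLibrary-class].
#' @param sourceRoot Directory tree to import.
#' @param sourceLabel Provenance label for this import.
#' @param derivSpec A [DerivativeSpec-class].
#' @return The completed job row.
#' @export
importDirectory <- function(lib, sourceRoot, sourceLabel = "",
                            derivSpec = derivativeSpec()) {
  jobId <- submitImportJob(lib, sourceRoot, sourceLabel)
  runImportJob(lib, jobId, derivSpec = derivSpec)
}
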