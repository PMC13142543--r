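## Asynchronous packaging of selected originals into ZIP archives, with
## collision-safe member names and byte-identical round-trips.

#' Collision-safe archive member name
#'
#' Returns the candidate unchanged if unused; otherwise appends `-1`, `-2`,
#' ... before the extension until an unused name is found. Deterministic.
#'
#' @param existing Character vector of names already in the archive.
#' @param candidate Proposed file name (non-empty).
#' @return The de-collided member name.
#' @examples
#' uniqueMemberName(c("a.jpg", "a-1.jpg"), "a.jpg")  # "a-2.jpg"
#' @export
uniqueMemberName <- function(existing, candidate) {
  if (!nzchar(candidate)) deckValidationError("member name must be non-empty")
  if (!candidate %in% existing) return(candidate)
  ext <- tools::file_ext(candidate)
  stem <- tools::file_path_sans_ext(candidate)
  k <- 1L
  repeat {
    nm <- if (nzchar(ext)) paste0(stem, "-", k, ".", ext) else paste0(stem, "-", k)
    if (!nm %in% existing) return(nm)
    k <- k + 1L
  }
}

#' Queue an export job
#'
#' @param lib A [MediaLibrary-class].
#' @param assetIds Non-empty integer vector of asset ids to package.
#' @return The new export job id.
#' @export
submitExportJob <- function(lib, assetIds) {
  if (!length(assetIds))
    deckValidationError("export selection must contain at least one asset")
  con <- dbcon(lib)
  DBI::dbExecute(con,
    "INSERT INTO export_jobs (asset_ids, created_at) VALUES (?, ?)",
    params = list(jsonlite::toJSON(as.integer(assetIds)), utcNow()))
  as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id)
}

#' Fetch export job rows
#' @param lib A [MediaLibrary-class].
#' @param jobId Export job id.
#' @return One-row data.frame.
#' @export
getExportJob <- function(lib, jobId) {
  df <- DBI::dbGetQuery(dbcon(lib), "SELECT * FROM export_jobs WHERE id = ?",
                        params = list(as.integer(jobId)))
  if (!nrow(df)) deckNotFoundError(paste0("no export job with id ", jobId))
  df
}

claimNextExportJob <- function(lib) {
  con <- dbcon(lib)
  withTransaction(lib, {
    id <- DBI::dbGetQuery(con,
      "SELECT id FROM export_jobs WHERE status = 'pending' ORDER BY id LIMIT 1")$id
    if (!length(id)) return(NA_integer_)
    DBI::dbExecute(con,
      "UPDATE export_jobs SET status = 'running' WHERE id = ? AND status = 'pending'",
      params = list(id))
    as.integer(id)
  })
}

#' Execute one export job
#'
#' Packages each selected asset's original bytes into a ZIP under `zips/`,
#' in selection order, under its original filename de-collided with
#' [uniqueMemberName()]. Member timestamps are set to each asset's
#' `imported_at`. Extracted members are byte-identical to the stored
#' originals.
#'
#' @param lib A [MediaLibrary-class].
#' @param jobId Id of a pending export job ([submitExportJob()]).
#' @param claimed Internal: set when [pollJobs()] already flipped the status.
#' @return The completed export job row.
#' @export
runExportJob <- function(lib, jobId, claimed = FALSE) {
  con <- dbcon(lib)
  job <- getExportJob(lib, jobId)
  if (!claimed && job$status != "pending")
    deckValidationError(paste0("export job ", jobId, " is not pending"))
  DBI::dbExecute(con, "UPDATE export_jobs SET status = 'running' WHERE id = ?",
                 params = list(jobId))
  ids <- as.integer(jsonlite::fromJSON(job$asset_ids))
  root <- libraryRoot(lib)
  res <- tryCatch({
    stage <- tempfile("export-stage-")
    dir.create(stage)
    on.exit(unlink(stage, recursive = TRUE), add = TRUE)
    members <- character()
    for (id in ids) {
      a <- getAsset(lib, id)
      nm <- uniqueMemberName(members, a$original_filename)
      members <- c(members, nm)
      src <- file.path(root, a$original_path)
      if (!file.copy(src, file.path(stage, nm)))
        deckStop("mediadeck_io_error", paste0("cannot stage asset ", id))
      Sys.setFileTime(file.path(stage, nm), parseUTC(a$imported_at))
    }
    zipRel <- file.path("zips", sprintf("export-%d-%s.zip", jobId,
      format(Sys.time(), "%Y%m%dT%H%M%SZ", tz = "UTC")))
    zip::zip(file.path(root, zipRel), files = members, root = stage,
             mode = "cherry-pick")
    DBI::dbExecute(con,
      "UPDATE export_jobs SET status = 'completed', zip_path = ?,
         member_count = ?, finished_at = ? WHERE id = ?",
      params = list(zipRel, length(members), utcNow(), jobId))
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) {
    DBI::dbExecute(con,
      "UPDATE export_jobs SET status = 'failed', failure_reason = ?,
         finished_at = ? WHERE id = ?",
      params = list(conditionMessage(res), utcNow(), jobId))
  }
  getExportJob(lib, jobId)
}

#' Convenience: submit and synchronously run an export
#' @param lib A [MediaLibrary-class].
#' @param assetIds Non-empty integer vector of asset ids.
#' @return The completed export job row.
#' @export
exportAssets <- function(lib, assetIds) {
  runExportJob(lib, submitExportJob(lib, assetIds))
}
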