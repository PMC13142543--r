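## Embedded metadata store: a single SQLite file (library.db) at the managed
## root, with an FTS5 companion table for ranked text retrieval.

SCHEMA_VERSION <- "1"

## The FTS tokenizer treats "-" and "_" as separators so that snake/kebab-cased
## biomedical filenames split into searchable tokens.
FTS_TOKENIZE <- "unicode61 separators '-_'"

librarySchema <- function() c(
  "CREATE TABLE IF NOT EXISTS assets (
     id INTEGER PRIMARY KEY,
     original_filename TEXT NOT NULL,
     display_name TEXT NOT NULL,
     folder_context TEXT NOT NULL DEFAULT '',
     source_label TEXT NOT NULL DEFAULT '',
     media_type TEXT NOT NULL CHECK (media_type IN ('image','video')),
     width INTEGER NOT NULL CHECK (width > 0),
     height INTEGER NOT NULL CHECK (height > 0),
     duration REAL,
     file_size INTEGER NOT NULL,
     sha256 TEXT NOT NULL UNIQUE CHECK (length(sha256) = 64),
     created_at TEXT NOT NULL,
     imported_at TEXT NOT NULL,
     original_path TEXT NOT NULL,
     thumbnail_path TEXT,
     preview_path TEXT,
     poster_path TEXT,
     searchable_text TEXT NOT NULL DEFAULT ''
   )",
  "CREATE UNIQUE INDEX IF NOT EXISTS idx_assets_sha ON assets(sha256)",
  "CREATE TABLE IF NOT EXISTS tags (
     id INTEGER PRIMARY KEY,
     name TEXT NOT NULL,
     UNIQUE (name COLLATE NOCASE)
   )",
  "CREATE TABLE IF NOT EXISTS asset_tags (
     asset_id INTEGER NOT NULL REFERENCES assets(id),
     tag_id INTEGER NOT NULL REFERENCES tags(id),
     UNIQUE (asset_id, tag_id)
   )",
  "CREATE TABLE IF NOT EXISTS collections (
     id INTEGER PRIMARY KEY,
     name TEXT NOT NULL UNIQUE
   )",
  "CREATE TABLE IF NOT EXISTS collection_members (
     collection_id INTEGER NOT NULL REFERENCES collections(id),
     asset_id INTEGER NOT NULL REFERENCES assets(id),
     ord INTEGER NOT NULL,
     UNIQUE (collection_id, asset_id)
   )",
  "CREATE TABLE IF NOT EXISTS import_jobs (
     id INTEGER PRIMARY KEY,
     source_root TEXT NOT NULL,
     source_label TEXT NOT NULL DEFAULT '',
     status TEXT NOT NULL DEFAULT 'pending'
       CHECK (status IN ('pending','running','completed','failed')),
     discovered_count INTEGER NOT NULL DEFAULT 0,
     processed_count INTEGER NOT NULL DEFAULT 0,
     duplicate_count INTEGER NOT NULL DEFAULT 0,
     skipped_count INTEGER NOT NULL DEFAULT 0,
     failed_count INTEGER NOT NULL DEFAULT 0,
     created_at TEXT NOT NULL,
     started_at TEXT,
     finished_at TEXT,
     log_path TEXT,
     failure_reason TEXT
   )",
  "CREATE TABLE IF NOT EXISTS duplicate_events (
     id INTEGER PRIMARY KEY,
     import_job_id INTEGER REFERENCES import_jobs(id),
     candidate_path TEXT NOT NULL,
     sha256 TEXT NOT NULL,
     existing_asset_id INTEGER NOT NULL REFERENCES assets(id),
     detected_at TEXT NOT NULL
   )",
  "CREATE TABLE IF NOT EXISTS export_jobs (
     id INTEGER PRIMARY KEY,
     asset_ids TEXT NOT NULL,
     status TEXT NOT NULL DEFAULT 'pending'
       CHECK (status IN ('pending','running','completed','failed')),
     zip_path TEXT,
     member_count INTEGER NOT NULL DEFAULT 0,
     created_at TEXT NOT NULL,
     finished_at TEXT,
     failure_reason TEXT
   )",
  "CREATE TABLE IF NOT EXISTS saved_searches (
     id INTEGER PRIMARY KEY,
     name TEXT NOT NULL,
     query TEXT NOT NULL CHECK (length(trim(query)) > 0),
     created_at TEXT NOT NULL
   )",
  "CREATE TABLE IF NOT EXISTS settings (
     key TEXT PRIMARY KEY,
     value TEXT NOT NULL
   )",
  sprintf("CREATE VIRTUAL TABLE IF NOT EXISTS assets_fts USING fts5(
     searchable_text, asset_id UNINDEXED, tokenize=\"%s\")", FTS_TOKENIZE)
)

## Connection helpers -------------------------------------------------------

dbcon <- function(lib) {
  con <- lib@state$con
  if (is.null(con) || !DBI::dbIsValid(con)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), lib@dbfile)
    DBI::dbExecute(con, "PRAGMA busy_timeout = 10000")
    DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
    lib@state$con <- con
  }
  con
}

dbScalar <- function(lib, sql, params = list()) {
  DBI::dbGetQuery(dbcon(lib), sql, params = params)[[1]]
}

withTransaction <- function(lib, expr) {
  con <- dbcon(lib)
  DBI::dbExecute(con, "BEGIN IMMEDIATE")
  ok <- FALSE
  on.exit(if (!ok) try(DBI::dbExecute(con, "ROLLBACK"), silent = TRUE))
  res <- force(expr)
  DBI::dbExecute(con, "COMMIT")
  ok <- TRUE
  res
}

## Library lifecycle --------------------------------------------------------

#' Initialize (or reopen) a managed media library
#'
#' Creates the managed directory layout (`originals/`, `thumbnails/`,
#' `previews/`, `posters/`, `zips/`, `logs/`) and the SQLite metadata store
#' `library.db` with its FTS5 index, recording the schema version in the
#' settings table. Idempotent: calling it on an existing library opens it
#' without touching existing data.
#'
#' @param root Directory to hold the library; created if absent. Must be
#'   writable and either empty or already a library.
#' @return A [MediaLibrary-class] handle.
#' @examples
#' lib <- initLibrary(file.path(tempdir(), "demo-lib"))
#' libraryRoot(lib)
#' closeLibrary(lib)
#' @export
initLibrary <- function(root) {
  root <- suppressWarnings(normalizePath(root, mustWork = FALSE))
  if (!dir.exists(root) && !dir.create(root, recursive = TRUE, showWarnings = FALSE))
    deckPermissionError(paste0("cannot create library root: ", root))
  if (file.access(root, 2L) != 0L)
    deckPermissionError(paste0("library root is not writable: ", root))
  for (d in LIBRARY_SUBDIRS)
    dir.create(file.path(root, d), showWarnings = FALSE)
  dbfile <- file.path(root, "library.db")
  existed <- file.exists(dbfile)
  lib <- new("MediaLibrary", root = normalizePath(root), dbfile = dbfile,
             state = new.env(parent = emptyenv()))
  con <- dbcon(lib)
  if (existed) checkLibraryDatabase(lib)
  for (stmt in librarySchema()) DBI::dbExecute(con, stmt)
  if (is.na(getSetting(lib, "schema_version")))
    setSetting(lib, "schema_version", SCHEMA_VERSION)
  validObject(lib)
  lib
}

checkLibraryDatabase <- function(lib) {
  con <- dbcon(lib)
  ok <- tryCatch({
    tabs <- DBI::dbListTables(con)
    length(tabs) == 0L || "settings" %in% tabs
  }, error = function(e) FALSE)
  if (!ok)
    deckIntegrityError(paste0("not a media library database: ", lib@dbfile))
  if (length(DBI::dbListTables(con)) > 0L) {
    v <- tryCatch(getSetting(lib, "schema_version"), error = function(e) NA_character_)
    if (is.na(v))
      deckIntegrityError(paste0("not a media library database: ", lib@dbfile))
  }
  invisible(TRUE)
}

#' @rdname initLibrary
#' @export
openLibrary <- function(root) {
  root <- normalizePath(root, mustWork = FALSE)
  if (!file.exists(file.path(root, "library.db")))
    deckNotFoundError(paste0("no library at: ", root))
  initLibrary(root)
}

#' Close a library's database connection
#' @param lib A [MediaLibrary-class].
#' @return Invisibly `TRUE`.
#' @export
closeLibrary <- function(lib) {
  con <- lib@state$con
  if (!is.null(con) && DBI::dbIsValid(con)) DBI::dbDisconnect(con)
  lib@state$con <- NULL
  invisible(TRUE)
}

## Settings -----------------------------------------------------------------

#' Read or write a library setting
#' @param lib A [MediaLibrary-class].
#' @param key Setting name (unique).
#' @param value Setting value (coerced to text).
#' @return `getSetting` returns the value or `NA` if unset.
#' @export
getSetting <- function(lib, key) {
  v <- DBI::dbGetQuery(dbcon(lib), "SELECT value FROM settings WHERE key = ?",
                       params = list(key))$value
  if (length(v)) v else NA_character_
}

#' @rdname getSetting
#' @export
setSetting <- function(lib, key, value) {
  DBI::dbExecute(dbcon(lib),
    "INSERT INTO settings (key, value) VALUES (?, ?)
     ON CONFLICT(key) DO UPDATE SET value = excluded.value",
    params = list(key, as.character(value)))
  invisible(value)
}

## Assets -------------------------------------------------------------------

assetSearchableText <- function(asset, tagNames = character()) {
  parts <- c(asset$original_filename, asset$display_name, asset$source_label,
             asset$folder_context, tagNames)
  paste(parts[nzchar(parts)], collapse = " ")
}

validateAsset <- function(asset) {
  req <- c("original_filename", "media_type", "width", "height", "file_size",
           "sha256", "original_path")
  miss <- setdiff(req, names(asset))
  if (length(miss))
    deckValidationError(paste0("asset is missing fields: ", paste(miss, collapse = ", ")))
  if (!asset$media_type %in% c("image", "video"))
    deckValidationError("media_type must be 'image' or 'video'")
  if (asset$width <= 0 || asset$height <= 0)
    deckValidationError("asset dimensions must be positive")
  if (!grepl("^[0-9a-f]{64}$", asset$sha256))
    deckValidationError("sha256 must be 64 lowercase hex characters")
  if (asset$media_type == "video" && is.null(asset$duration))
    deckValidationError("video assets must carry a duration")
  if (asset$media_type == "image" && !is.null(asset$duration))
    deckValidationError("image assets must not carry a duration")
  invisible(asset)
}

#' Persist an asset row (with its full-text index entry)
#'
#' Inserts the asset and its FTS row in one transaction; the searchable text
#' is rebuilt from the current fields. The content hash is uniquely indexed:
#' attempting to store a second asset with the same `sha256` fails, which is
#' the store-level half of the dedup guarantee (importers must use
#' [detectDuplicate()] and record a duplicate event instead).
#'
#' @param lib A [MediaLibrary-class].
#' @param asset Named list with the Asset fields (`original_filename`,
#'   `display_name`, `folder_context`, `source_label`, `media_type`, `width`,
#'   `height`, `duration` (videos), `file_size`, `sha256`, `created_at`,
#'   `imported_at`, `original_path`, derivative paths).
#' @return The new asset id (integer).
#' @export
putAsset <- function(lib, asset) {
  validateAsset(asset)
  dup <- detectDuplicate(lib, asset$sha256)
  if (!is.na(dup))
    deckStop("mediadeck_uniqueness_error",
             paste0("sha256 already present (asset ", dup, "): ", asset$sha256))
  now <- utcNow()
  asset$display_name <- asset$display_name %||%
    tools::file_path_sans_ext(asset$original_filename)
  asset$folder_context <- asset$folder_context %||% ""
  asset$source_label <- asset$source_label %||% ""
  asset$created_at <- asset$created_at %||% now
  asset$imported_at <- asset$imported_at %||% now
  st <- assetSearchableText(asset)
  con <- dbcon(lib)
  withTransaction(lib, {
    DBI::dbExecute(con,
      "INSERT INTO assets (original_filename, display_name, folder_context,
         source_label, media_type, width, height, duration, file_size, sha256,
         created_at, imported_at, original_path, thumbnail_path, preview_path,
         poster_path, searchable_text)
       VALUES (?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?)",
      params = list(asset$original_filename, asset$display_name,
                    asset$folder_context, asset$source_label, asset$media_type,
                    as.integer(asset$width), as.integer(asset$height),
                    asset$duration %||% NA_real_, as.numeric(asset$file_size),
                    asset$sha256, asset$created_at, asset$imported_at,
                    asset$original_path, asset$thumbnail_path %||% NA_character_,
                    asset$preview_path %||% NA_character_,
                    asset$poster_path %||% NA_character_, st))
    id <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id
    DBI::dbExecute(con,
      "INSERT INTO assets_fts (searchable_text, asset_id) VALUES (?, ?)",
      params = list(st, id))
    as.integer(id)
  })
}

#' Fetch one asset by id
#' @param lib A [MediaLibrary-class].
#' @param id Asset id.
#' @return One-row data.frame of the asset, or a not-found error.
#' @export
getAsset <- function(lib, id) {
  df <- DBI::dbGetQuery(dbcon(lib), "SELECT * FROM assets WHERE id = ?",
                        params = list(as.integer(id)))
  if (!nrow(df)) deckNotFoundError(paste0("no asset with id ", id))
  df
}

#' List all assets
#' @param lib A [MediaLibrary-class].
#' @return data.frame of all asset rows ordered by id.
#' @export
listAssets <- function(lib) {
  DBI::dbGetQuery(dbcon(lib), "SELECT * FROM assets ORDER BY id")
}

refreshAssetSearchText <- function(lib, assetId) {
  con <- dbcon(lib)
  a <- getAsset(lib, assetId)
  tags <- assetTags(lib, assetId)
  st <- assetSearchableText(as.list(a), tags)
  DBI::dbExecute(con, "UPDATE assets SET searchable_text = ? WHERE id = ?",
                 params = list(st, assetId))
  DBI::dbExecute(con, "DELETE FROM assets_fts WHERE asset_id = ?",
                 params = list(assetId))
  DBI::dbExecute(con,
    "INSERT INTO assets_fts (searchable_text, asset_id) VALUES (?, ?)",
    params = list(st, assetId))
  invisible(st)
}

## Full-text search ---------------------------------------------------------

#' Ranked full-text search over the library
#'
#' Matches the tokenized query against each asset's aggregated searchable
#' text (filename, display name, source label, folder context, tag names).
#' Results are ordered by FTS rank (bm25), ties broken by `imported_at`
#' descending then id ascending, so result order is deterministic. Optional
#' filters are applied conjunctively.
#'
#' @param lib A [MediaLibrary-class].
#' @param query FTS query text (single terms, phrases, AND/OR/NOT).
#' @param mediaType Optional `"image"` or `"video"` filter.
#' @param source Optional exact source-label filter.
#' @param tag Optional tag-name filter (case-insensitive).
#' @return data.frame of matching asset rows (possibly empty).
#' @export
## Bare terms containing separators ("-", "_", ".") collide with FTS5 query
## syntax; wrap them as phrases so "he-stain" or "tile_042.png" search as the
## token sequences the tokenizer produced. Operators and quoted phrases pass
## through untouched, so advanced syntax (AND/OR/NOT, prefix*) still works.
prepareFtsQuery <- function(query) {
  toks <- strsplit(trimws(query), "[[:space:]]+")[[1]]
  quoted <- vapply(toks, function(t) {
    if (t %in% c("AND", "OR", "NOT", "NEAR")) t
    else if (grepl('^[A-Za-z0-9_.-]+$', t)) paste0('"', t, '"')
    else t
  }, character(1))
  paste(quoted, collapse = " ")
}

ftsSearch <- function(lib, query, mediaType = NULL, source = NULL, tag = NULL) {
  con <- dbcon(lib)
  query <- prepareFtsQuery(query)
  sql <- "SELECT a.* FROM assets_fts f JOIN assets a ON a.id = f.asset_id
          WHERE assets_fts MATCH ?"
  params <- list(query)
  if (!is.null(mediaType)) { sql <- paste(sql, "AND a.media_type = ?"); params <- c(params, mediaType) }
  if (!is.null(source))    { sql <- paste(sql, "AND a.source_label = ?"); params <- c(params, source) }
  if (!is.null(tag)) {
    sql <- paste(sql, "AND EXISTS (SELECT 1 FROM asset_tags at JOIN tags t
                   ON t.id = at.tag_id WHERE at.asset_id = a.id
                   AND t.name = ? COLLATE NOCASE)")
    params <- c(params, tag)
  }
  sql <- paste(sql, "ORDER BY f.rank, a.imported_at DESC, a.id ASC")
  tryCatch(DBI::dbGetQuery(con, sql, params = params),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("fts5", msg, fixed = TRUE))
        deckQueryError(paste0("malformed search query '", query, "': ", msg))
      stop(e)
    })
}

#' Rebuild the full-text index from the asset table
#'
#' Recovery path: drops every FTS row and re-inserts one per asset from its
#' stored searchable text. On an uncorrupted library, search results are
#' identical before and after.
#'
#' @param lib A [MediaLibrary-class].
#' @return Number of indexed assets (integer).
#' @export
rebuildFtsIndex <- function(lib) {
  con <- dbcon(lib)
  withTransaction(lib, {
    DBI::dbExecute(con, "DELETE FROM assets_fts")
    DBI::dbExecute(con,
      "INSERT INTO assets_fts (searchable_text, asset_id)
       SELECT searchable_text, id FROM assets")
    ## dbExecute's change count includes FTS5 shadow-table writes; report the
    ## number of indexed assets instead.
    as.integer(DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM assets_fts")$n)
  })
}

## Tags ---------------------------------------------------------------------

assetTags <- function(lib, assetId) {
  DBI::dbGetQuery(dbcon(lib),
    "SELECT t.name FROM tags t JOIN asset_tags at ON at.tag_id = t.id
     WHERE at.asset_id = ? ORDER BY at.rowid", params = list(assetId))$name
}

#' Tag an asset
#'
#' Creates the tag if absent (names are unique case-insensitively; the first
#' spelling seen is stored), associates it with the asset idempotently, and
#' refreshes the asset's searchable text so the tag is findable via
#' [ftsSearch()].
#'
#' @param lib A [MediaLibrary-class].
#' @param assetId Asset id.
#' @param tagName Non-empty tag name.
#' @return The updated asset row (data.frame).
#' @export
tagAsset <- function(lib, assetId, tagName) {
  tagName <- trimws(tagName)
  if (!nzchar(tagName)) deckValidationError("tag name must be non-empty")
  getAsset(lib, assetId)                       # not-found check
  con <- dbcon(lib)
  withTransaction(lib, {
    tagId <- DBI::dbGetQuery(con,
      "SELECT id FROM tags WHERE name = ? COLLATE NOCASE", params = list(tagName))$id
    if (!length(tagId)) {
      DBI::dbExecute(con, "INSERT INTO tags (name) VALUES (?)", params = list(tagName))
      tagId <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id
    }
    DBI::dbExecute(con,
      "INSERT OR IGNORE INTO asset_tags (asset_id, tag_id) VALUES (?, ?)",
      params = list(as.integer(assetId), as.integer(tagId)))
  })
  refreshAssetSearchText(lib, assetId)
  getAsset(lib, assetId)
}

## Collections --------------------------------------------------------------

#' Add assets to or remove assets from a named collection
#'
#' The collection is created on first use. Member order is the order of first
#' insertion; re-adding an existing member is a no-op, as is removing a
#' non-member.
#'
#' @param lib A [MediaLibrary-class].
#' @param name Collection name.
#' @param assetIds Integer asset ids (must exist).
#' @param action `"add"` or `"remove"`.
#' @return List with `id`, `name` and ordered `member_ids`.
#' @export
manageCollection <- function(lib, name, assetIds, action = c("add", "remove")) {
  action <- match.arg(action)
  con <- dbcon(lib)
  for (id in assetIds) getAsset(lib, id)       # not-found check
  withTransaction(lib, {
    cid <- DBI::dbGetQuery(con, "SELECT id FROM collections WHERE name = ?",
                           params = list(name))$id
    if (!length(cid)) {
      DBI::dbExecute(con, "INSERT INTO collections (name) VALUES (?)", params = list(name))
      cid <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id
    }
    if (action == "add") {
      for (id in assetIds) {
        nxt <- DBI::dbGetQuery(con,
          "SELECT COALESCE(MAX(ord), 0) + 1 AS o FROM collection_members
           WHERE collection_id = ?", params = list(cid))$o
        DBI::dbExecute(con,
          "INSERT OR IGNORE INTO collection_members (collection_id, asset_id, ord)
           VALUES (?,?,?)", params = list(cid, as.integer(id), nxt))
      }
    } else {
      for (id in assetIds)
        DBI::dbExecute(con,
          "DELETE FROM collection_members WHERE collection_id = ? AND asset_id = ?",
          params = list(cid, as.integer(id)))
    }
  })
  members <- DBI::dbGetQuery(con,
    "SELECT asset_id FROM collection_members WHERE collection_id =
       (SELECT id FROM collections WHERE name = ?) ORDER BY ord",
    params = list(name))$asset_id
  list(id = as.integer(DBI::dbGetQuery(con,
         "SELECT id FROM collections WHERE name = ?", params = list(name))$id),
       name = name, member_ids = as.integer(members))
}

## Saved searches -----------------------------------------------------------

#' Save or list named searches
#' @param lib A [MediaLibrary-class].
#' @param name Search name.
#' @param query Non-empty FTS query text.
#' @return `saveSearch` the new row id; `listSavedSearches` a data.frame.
#' @export
saveSearch <- function(lib, name, query) {
  if (!nzchar(trimws(query))) deckValidationError("saved search query must be non-empty")
  con <- dbcon(lib)
  DBI::dbExecute(con,
    "INSERT INTO saved_searches (name, query, created_at) VALUES (?,?,?)",
    params = list(name, query, utcNow()))
  as.integer(DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id)
}

#' @rdname saveSearch
#' @export
listSavedSearches <- function(lib) {
  DBI::dbGetQuery(dbcon(lib), "SELECT * FROM saved_searches ORDER BY id")
}
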