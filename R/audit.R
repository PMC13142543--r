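#' Audit a library's integrity
#'
#' Full-library scan verifying the invariants the managed store promises:
#'
#' * immutability: `sha256File(original)` equals the stored hash for every
#'   asset, and every stored path resolves to an existing file;
#' * dedup guarantee: no two assets share a `sha256`;
#' * accounting identity on every completed import job:
#'   `discovered = processed + duplicates + skipped + failed`;
#' * referential integrity: tag associations, collection members and
#'   duplicate events all reference existing assets;
#' * orphan report: files under `originals/` with no asset row (tolerated,
#'   reported).
#'
#' @param lib A [MediaLibrary-class].
#' @return List with `ok` (logical), per-check counts, and a data.frame
#'   `problems` (one row per violation, empty when clean).
#' @export
auditLibrary <- function(lib) {
  root <- libraryRoot(lib)
  con <- dbcon(lib)
  assets <- listAssets(lib)
  problems <- list()
  note <- function(kind, detail)
    problems[[length(problems) + 1L]] <<- data.frame(kind = kind, detail = detail)

  hashOk <- 0L
  for (i in seq_len(nrow(assets))) {
    a <- assets[i, ]
    p <- file.path(root, a$original_path)
    if (!file.exists(p)) {
      note("missing_original", paste0("asset ", a$id, ": ", a$original_path))
    } else if (!identical(sha256File(p), a$sha256)) {
      note("hash_mismatch", paste0("asset ", a$id, ": ", a$original_path))
    } else hashOk <- hashOk + 1L
    for (col in c("thumbnail_path", "preview_path", "poster_path")) {
      rp <- a[[col]]
      if (!is.na(rp) && nzchar(rp) && !file.exists(file.path(root, rp)))
        note("missing_derivative", paste0("asset ", a$id, ": ", rp))
    }
  }

  dupSha <- DBI::dbGetQuery(con,
    "SELECT sha256, COUNT(*) n FROM assets GROUP BY sha256 HAVING n > 1")
  for (s in dupSha$sha256) note("sha_collision", s)

  jobs <- DBI::dbGetQuery(con,
    "SELECT * FROM import_jobs WHERE status = 'completed'")
  for (i in seq_len(nrow(jobs))) {
    j <- jobs[i, ]
    if (j$discovered_count !=
        j$processed_count + j$duplicate_count + j$skipped_count + j$failed_count)
      note("accounting_identity", paste0("job ", j$id))
  }

  for (q in c(
    "SELECT 'tag_ref' kind, asset_id detail FROM asset_tags
       WHERE asset_id NOT IN (SELECT id FROM assets)",
    "SELECT 'collection_ref' kind, asset_id detail FROM collection_members
       WHERE asset_id NOT IN (SELECT id FROM assets)",
    "SELECT 'dup_event_ref' kind, existing_asset_id detail FROM duplicate_events
       WHERE existing_asset_id NOT IN (SELECT id FROM assets)")) {
    bad <- DBI::dbGetQuery(con, q)
    for (i in seq_len(nrow(bad))) note(bad$kind[i], as.character(bad$detail[i]))
  }

  onDisk <- list.files(file.path(root, "originals"))
  known <- basename(assets$original_path)
  orphans <- setdiff(onDisk, known)

  problems <- if (length(problems)) do.call(rbind, problems)
              else data.frame(kind = character(), detail = character())
  list(ok = nrow(problems) == 0L,
       assets = nrow(assets), hash_verified = hashOk,
       completed_jobs = nrow(jobs), orphan_originals = orphans,
       problems = problems)
}
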