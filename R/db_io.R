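# Persistence of the normative database. A database is a plain R list (no
# environments, no formulas) so RDS serialization is lossless and
# deterministic: load(save(db)) reproduces every numeric field bit-exactly.

NORMDB_SCHEMA_VERSION <- 1L

#' Save a normative database
#'
#' Serializes the database, including all fitted age models, kept-control
#' residues, reliability and artifact models and the provenance manifest, to
#' a single RDS file. The round trip through [load_db()] is bit-exact.
#'
#' @param db A `normative_db` object from [build_normative_db()].
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  if (!inherits(db, "normative_db")) abort("`db` must be a normative_db object")
  saveRDS(db, path)
  invisible(path)
}

#' Load a normative database
#'
#' @param path Path written by [save_db()].
#' @return The `normative_db` object.
#' @export
load_db <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  db <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Integrity error reading normative database from ", path,
                 ": ", conditionMessage(e)))
  })
  if (!inherits(db, "normative_db")) {
    abort(paste0(path, " does not contain a normative database"))
  }
  ver <- db$provenance$schema_version
  if (is.null(ver) || ver != NORMDB_SCHEMA_VERSION) {
    abort(paste0("Normative database schema version mismatch: file has ",
                 ver %||% "<none>", ", this package reads ",
                 NORMDB_SCHEMA_VERSION))
  }
  db
}
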