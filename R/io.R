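# Reading and writing morphometric tables and subject/visit metadata.
# The canonical internal representation is the long format; the wide
# FreeSurfer-style dialect is converted on read so there is one statistics
# path. Missing values are carried explicitly and excluded per key at fit
# time, never imputed.

long_csv_columns <- c("subject_id", "visit_id", "region", "hemisphere",
                      "parameter", "value")

#' Read a morphometric stats table
#'
#' Reads per-region morphometric measurements into the long format used by
#' every downstream stage: one row per (subject, visit, region, hemisphere,
#' parameter) with the value in native physical units (mm^3, mm, mm^2,
#' dimensionless). Two dialects are supported:
#'
#' * `"long_csv"`: columns `subject_id, visit_id, region, hemisphere,
#'   parameter, value` (UTF-8, header required).
#' * `"freesurfer_wide_tsv"`: first column is a subject/visit identifier
#'   (either `subject` or `subject:visit`), remaining columns are
#'   region-measure pairs as produced by FreeSurfer's `aparcstats2table` /
#'   `asegstats2table` exporters, e.g. `lh_superiorfrontal_thickness`.
#'   FreeSurfer measure suffixes (`thickness`, `thicknessstd`, `area`,
#'   `grayvol`, `volume`, `meancurv`, `gauscurv`, `curvind`, `foldind`) are
#'   mapped onto the parameter taxonomy; columns whose suffix matches no
#'   known measure are reported with a warning, never silently dropped.
#'
#' Values read as `NA` are kept as explicitly missing records (missing is
#' not zero). Unknown parameter or hemisphere labels are rejected.
#'
#' @param path Path to the file.
#' @param dialect `"long_csv"` or `"freesurfer_wide_tsv"`.
#' @return A tibble with columns `subject_id, visit_id, region, hemisphere,
#'   parameter, value` and one row per measurement.
#' @seealso [write_stats_table()], [join_metadata()]
#' @export
read_stats_table <- function(path, dialect = c("long_csv", "freesurfer_wide_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tab <- switch(dialect,
    long_csv = read_long_csv(path),
    freesurfer_wide_tsv = read_freesurfer_wide_tsv(path)
  )
  assert_taxonomy(tab$parameter, tab$hemisphere)
  dup <- duplicated(tab[c("subject_id", "visit_id", "region", "hemisphere",
                          "parameter")])
  if (any(dup)) {
    abort(paste0("Duplicate (subject, visit, key) entries in ", path, ", e.g. ",
                 paste(utils::head(tab$subject_id[dup], 3), collapse = ", ")))
  }
  bad <- !is.na(tab$value) & !is.finite(tab$value)
  if (any(bad)) {
    abort(paste0("Non-finite measurement values in ", path, " at row(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  tab
}

read_long_csv <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(long_csv_columns, header)
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed header in ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(header, long_csv_columns)
  if (length(extra) > 0) {
    warn(paste0("Ignoring unknown column(s) in ", path, ": ",
                paste(extra, collapse = ", ")))
  }
  tab <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      visit_id = readr::col_character(),
      region = readr::col_character(),
      hemisphere = readr::col_character(),
      parameter = readr::col_character(),
      value = readr::col_double(),
      .default = readr::col_character()
    )
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Non-numeric or malformed value in ", path, " at row ", probs$row[1],
      ", column ", probs$col[1], " (expected ", probs$expected[1], ", got ",
      probs$actual[1], ")"
    ))
  }
  tibble::as_tibble(tab[long_csv_columns])
}

# Parse one FreeSurfer-style wide column name into (region, hemisphere,
# parameter); returns NULL if the measure suffix is unknown.
parse_wide_column <- function(name) {
  hemi <- "none"
  rest <- name
  if (grepl("^(lh|rh)[._]", name)) {
    hemi <- if (substr(name, 1, 2) == "lh") "left" else "right"
    rest <- sub("^(lh|rh)[._]", "", name)
  }
  aliases <- freesurfer_measure_aliases()
  suffixes <- c(setNames(morph_parameters(), morph_parameters()), aliases)
  # longest suffix first so thickness_sd wins over a hypothetical sd
  ord <- order(nchar(names(suffixes)), decreasing = TRUE)
  for (i in ord) {
    suf <- names(suffixes)[i]
    pat <- paste0("[._]", suf, "$")
    if (grepl(pat, rest)) {
      region <- sub(pat, "", rest)
      if (nzchar(region)) {
        return(list(region = region, hemisphere = hemi,
                    parameter = unname(suffixes[i])))
      }
    }
  }
  NULL
}

read_freesurfer_wide_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 2) {
    abort(paste0("Malformed header in ", path,
                 ": need an identifier column plus measure columns"))
  }
  id_col <- names(tab)[1]
  parsed <- lapply(names(tab)[-1], parse_wide_column)
  unknown <- names(tab)[-1][vapply(parsed, is.null, logical(1))]
  if (length(unknown) > 0) {
    warn(paste0("Unrecognized measure column(s) in ", path, ": ",
                paste(unknown, collapse = ", "), " (dropped)"))
  }
  keep <- which(!vapply(parsed, is.null, logical(1)))
  if (length(keep) == 0) abort(paste0("No parseable measure columns in ", path))

  ids <- tab[[1]]
  has_visit <- grepl(":", ids, fixed = TRUE)
  subject_id <- ifelse(has_visit, sub(":.*$", "", ids), ids)
  visit_id <- ifelse(has_visit, sub("^[^:]*:", "", ids), ids)

  pieces <- lapply(keep, function(i) {
    info <- parsed[[i]]
    raw <- tab[[i + 1]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "NA" & is.na(val))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric value '", raw[bad[1]], "' in ", path,
                   ", column ", names(tab)[i + 1], ", row ", bad[1]))
    }
    tibble::tibble(
      subject_id = subject_id, visit_id = visit_id,
      region = info$region, hemisphere = info$hemisphere,
      parameter = info$parameter, value = val
    )
  })
  dplyr::bind_rows(pieces)
}

#' Write a morphometric stats table
#'
#' Inverse of [read_stats_table()]. The long dialect preserves every value at
#' full precision; the wide dialect writes one row per visit and one column
#' per (hemisphere, region, parameter) combination.
#'
#' @param table Long-format tibble as returned by [read_stats_table()].
#' @param path Output path.
#' @param dialect `"long_csv"` or `"freesurfer_wide_tsv"`.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(table, path,
                              dialect = c("long_csv", "freesurfer_wide_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    readr::write_csv(table[long_csv_columns], path)
  } else {
    wide <- table |>
      dplyr::mutate(
        column = paste0(
          dplyr::case_when(
            .data$hemisphere == "left" ~ "lh_",
            .data$hemisphere == "right" ~ "rh_",
            TRUE ~ ""
          ),
          .data$region, "_", .data$parameter
        ),
        id = paste(.data$subject_id, .data$visit_id, sep = ":")
      ) |>
      dplyr::select("id", "column", "value") |>
      tidyr::pivot_wider(names_from = "column", values_from = "value")
    readr::write_tsv(wide, path)
  }
  invisible(path)
}

#' Read a subject/visit metadata table
#'
#' Metadata CSV with columns `subject_id, visit_id, age, sex, scanner_model,
#' sequence, etiv, group`: age in years, eTIV in mm^3, `sex` in `{F, M}`,
#' `group` in `{control, patient}`. The table is validated on read: ages must
#' be finite and positive, eTIV positive, and (subject, visit) unique.
#'
#' @param path Path to the CSV file.
#' @return Validated tibble of per-visit metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  need <- c("subject_id", "visit_id", "age", "sex", "scanner_model",
            "sequence", "etiv", "group")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(need, header)
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed metadata header in ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      visit_id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      scanner_model = readr::col_character(),
      sequence = readr::col_character(),
      etiv = readr::col_double(),
      group = readr::col_character(),
      .default = readr::col_character()
    )
  )
  validate_metadata(meta)
}

#' Validate subject/visit metadata
#'
#' @param meta Tibble with the metadata columns of [read_metadata()].
#' @return The validated tibble, invisibly usable in pipelines.
#' @export
validate_metadata <- function(meta) {
  need <- c("subject_id", "visit_id", "age", "sex", "scanner_model",
            "sequence", "etiv", "group")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(meta$age) | meta$age <= 0)) {
    abort("Metadata ages must be finite and positive")
  }
  if (any(!is.finite(meta$etiv) | meta$etiv <= 0)) {
    abort("Metadata eTIV must be finite and positive (mm^3)")
  }
  if (!all(meta$sex %in% c("F", "M"))) {
    abort("Metadata sex must be one of {F, M}")
  }
  if (!all(meta$group %in% c("control", "patient"))) {
    abort("Metadata group must be one of {control, patient}")
  }
  dup <- duplicated(meta[c("subject_id", "visit_id")])
  if (any(dup)) {
    abort(paste0("Duplicate metadata rows for visit(s): ",
                 paste(unique(paste0(meta$subject_id[dup], "/",
                                     meta$visit_id[dup])), collapse = ", ")))
  }
  tibble::as_tibble(meta)
}

#' Join measurements with subject/visit metadata
#'
#' Attaches the full metadata record to every measurement row. Every
#' (subject, visit) present in the measurement table must appear exactly once
#' in the metadata; unmatched visits are an error naming the missing ids, so
#' no rows can be lost silently.
#'
#' @param table Long-format measurement tibble ([read_stats_table()]).
#' @param meta Metadata tibble ([read_metadata()]).
#' @return The measurement tibble with metadata columns appended; the row
#'   count is exactly `nrow(table)`.
#' @export
join_metadata <- function(table, meta) {
  meta <- validate_metadata(meta)
  joined <- dplyr::left_join(table, meta, by = c("subject_id", "visit_id"))
  unmatched <- is.na(joined$age)
  if (any(unmatched)) {
    ids <- unique(paste0(joined$subject_id[unmatched], "/",
                         joined$visit_id[unmatched]))
    abort(paste0("No metadata for visit(s): ",
                 paste(utils::head(ids, 10), collapse = ", ")))
  }
  stopifnot(nrow(joined) == nrow(table))
  joined
}
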