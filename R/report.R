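# Standardized result export: TSV tables, a navigable HTML index with
# yellow/red highlight colours, run manifests, and a thin command-line
# dispatcher over the package functions.

#' Write an assessment table as TSV
#'
#' @param assessment A `visit_assessment`, `series_assessment` or
#'   `loocv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessment_tsv <- function(assessment, path) {
  readr::write_tsv(tibble::as_tibble(assessment), path)
  invisible(path)
}

highlight_color <- function(h) {
  c(none = "#ffffff", yellow = "#ffe97f", red = "#ff9c9c")[as.character(h)]
}

#' Write an HTML index for an assessment
#'
#' Emulates the automatically generated result pages: one table row per
#' key with the highlight colour as background, compiled twice — ordered by
#' region and ordered by parameter — to allow switching between
#' region-based and measure-based views. The index enumerates exactly the
#' keys present in the assessment table.
#'
#' @param assessment A `visit_assessment` or `series_assessment`.
#' @param path Output HTML path.
#' @param title Page title.
#' @return `path`, invisibly.
#' @export
write_html_index <- function(assessment, path, title = "normorph assessment") {
  d <- tibble::as_tibble(assessment)
  pcol <- if ("p_slope" %in% names(d)) "p_slope" else "p_ucor"
  stat <- if ("slope" %in% names(d)) "slope" else "residue"
  row_html <- function(r) {
    sprintf(
      "<tr style=\"background:%s\"><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
      highlight_color(r$highlight), r$region, r$hemisphere, r$parameter,
      r$variant, signif_or_na(r[[stat]]), signif_or_na(r[[pcol]]),
      as.character(r$highlight)
    )
  }
  section <- function(d, label) {
    rows <- vapply(seq_len(nrow(d)), function(i) row_html(d[i, ]),
                   character(1))
    paste0(
      "<h2>", label, "</h2>\n<table border=\"1\" cellspacing=\"0\">",
      "<tr><th>region</th><th>hemisphere</th><th>parameter</th>",
      "<th>variant</th><th>", stat, "</th><th>p</th><th>highlight</th></tr>\n",
      paste(rows, collapse = "\n"), "</table>\n"
    )
  }
  by_region <- d[order(d$region, d$hemisphere, d$parameter, d$variant), ]
  by_param <- d[order(d$parameter, d$variant, d$region, d$hemisphere), ]
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>", title,
    "</title></head><body>\n<h1>", title, "</h1>\n",
    section(by_region, "By region"),
    section(by_param, "By parameter"),
    "</body></html>\n"
  )
  writeLines(html, path)
  invisible(path)
}

signif_or_na <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", as.character(signif(x, digits)))
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version of a run as JSON so
#' outputs can be reproduced exactly.
#'
#' @param path Output path.
#' @param config Named list of configuration values.
#' @param seed Integer seed used for the run (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = NULL) {
  manifest <- list(
    package = "normorph",
    version = as.character(utils::packageVersion("normorph")),
    seed = seed,
    config = config,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_run_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

default_run_config <- function() {
  list(alpha = 0.05, alpha_fit = 0.05, n_min = 10,
       variants = c("raw", "normalized", "asymmetry"), seed = 1L)
}

merge_run_config <- function(config) {
  cfg <- modifyList(default_run_config(), config)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)")
  if (cfg$alpha_fit <= 0 || cfg$alpha_fit >= 1) {
    abort("alpha_fit must be in (0, 1)")
  }
  cfg
}

#' Build a normative database from files
#'
#' Reads control measurements and metadata, builds the database, writes it
#' with a manifest and a per-key fit/reliability summary TSV.
#'
#' @param stats_path,meta_path Input files ([read_stats_table()],
#'   [read_metadata()]).
#' @param out_path Output `.rds` path for the database.
#' @param config Named list overriding the default run configuration
#'   (`alpha_fit`, `variants`, `seed`).
#' @param dialect Stats table dialect.
#' @return The `normative_db`, invisibly.
#' @export
run_build_db <- function(stats_path, meta_path, out_path, config = list(),
                         dialect = "long_csv") {
  cfg <- merge_run_config(config)
  tab <- read_stats_table(stats_path, dialect)
  meta <- read_metadata(meta_path)
  joined <- join_metadata(tab, meta)
  db <- build_normative_db(joined, variants = cfg$variants,
                           alpha_fit = cfg$alpha_fit, seed = cfg$seed)
  save_db(db, out_path)
  readr::write_tsv(tidy(db), paste0(out_path, ".summary.tsv"))
  write_manifest(paste0(out_path, ".manifest.json"), cfg, cfg$seed)
  invisible(db)
}

#' Assess a patient visit from files
#'
#' @param db_path Path to a saved database.
#' @param stats_path,meta_path Patient measurement and metadata files.
#' @param out_dir Output directory (TSV + HTML index + manifest).
#' @param visit_id Visit to assess; defaults to the only visit present.
#' @param config Run configuration overrides (`alpha`, `n_min`).
#' @param dialect Stats table dialect.
#' @return The `visit_assessment`, invisibly.
#' @export
run_assess_visit <- function(db_path, stats_path, meta_path, out_dir,
                             visit_id = NULL, config = list(),
                             dialect = "long_csv") {
  cfg <- merge_run_config(config)
  db <- load_db(db_path)
  tab <- read_stats_table(stats_path, dialect)
  meta <- read_metadata(meta_path)
  joined <- join_metadata(tab, meta)
  if (!is.null(visit_id)) {
    joined <- dplyr::filter(joined, .data$visit_id == !!visit_id)
  }
  va <- assess_visit(db, joined, alpha = cfg$alpha, n_min = cfg$n_min)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assessment_tsv(va, file.path(out_dir, "visit_assessment.tsv"))
  write_html_index(va, file.path(out_dir, "index.html"),
                   title = paste("Visit assessment:",
                                 attr(va, "patient")$subject_id,
                                 attr(va, "patient")$visit_id))
  write_manifest(file.path(out_dir, "manifest.json"), cfg, cfg$seed)
  invisible(va)
}

#' Assess a patient follow-up series from files
#'
#' @inheritParams run_assess_visit
#' @param exclusions_path Optional CSV with manual exclusions (`key`,
#'   `visit_id`).
#' @return The `series_assessment`, invisibly.
#' @export
run_assess_series <- function(db_path, stats_path, meta_path, out_dir,
                              exclusions_path = NULL, config = list(),
                              dialect = "long_csv") {
  cfg <- merge_run_config(config)
  db <- load_db(db_path)
  tab <- read_stats_table(stats_path, dialect)
  meta <- read_metadata(meta_path)
  joined <- join_metadata(tab, meta)
  if (length(unique(joined$visit_id)) < 3) {
    abort("Fewer than 3 visits: use the single-visit assessment instead")
  }
  excl <- NULL
  if (!is.null(exclusions_path)) {
    excl <- readr::read_csv(exclusions_path, show_col_types = FALSE)
  }
  sa <- assess_series(db, joined, alpha = cfg$alpha, n_min = cfg$n_min,
                      exclusions = excl)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assessment_tsv(sa, file.path(out_dir, "series_assessment.tsv"))
  write_html_index(sa, file.path(out_dir, "index.html"),
                   title = paste("Series assessment:",
                                 attr(sa, "patient")$subject_id))
  write_manifest(file.path(out_dir, "manifest.json"), cfg, cfg$seed)
  invisible(sa)
}

#' Run a LOOCV calibration from files
#'
#' @inheritParams run_build_db
#' @param out_dir Output directory.
#' @param config Overrides (`alphas`, `variants`, `n_test_subjects`,
#'   `seed`).
#' @return The `loocv_report`, invisibly.
#' @export
run_loocv <- function(stats_path, meta_path, out_dir, config = list(),
                      dialect = "long_csv") {
  cfg <- merge_run_config(config)
  cfg$alphas <- cfg$alphas %||% c(0.01, 0.05)
  cfg$n_test_subjects <- cfg$n_test_subjects %||% 34
  tab <- read_stats_table(stats_path, dialect)
  meta <- read_metadata(meta_path)
  joined <- join_metadata(tab, meta)
  set.seed(cfg$seed)
  rep <- loocv_assess(joined, n_test_subjects = cfg$n_test_subjects,
                      alphas = cfg$alphas, variants = cfg$variants,
                      alpha_fit = cfg$alpha_fit, n_min = cfg$n_min)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assessment_tsv(rep, file.path(out_dir, "loocv_report.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), cfg, cfg$seed)
  invisible(rep)
}

#' Simulate a cohort (and optional patient series) to files
#'
#' @param out_dir Output directory; writes `hc_long.csv`, `hc_meta.csv`,
#'   `truth_artifacts.csv` and, if requested, `patient_long.csv` /
#'   `patient_meta.csv`.
#' @param config Overrides for [cohort_config()] fields plus optional
#'   `patient` sublist for [patient_series_config()].
#' @return Invisibly, the simulation list.
#' @export
run_simulate <- function(out_dir, config = list()) {
  patient_cfg <- config$patient
  config$patient <- NULL
  allowed <- names(formals(cohort_config))
  cfg <- do.call(cohort_config, config[intersect(names(config), allowed)])
  sim <- simulate_cohort(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$table, file.path(out_dir, "hc_long.csv"))
  readr::write_csv(sim$meta, file.path(out_dir, "hc_meta.csv"))
  readr::write_csv(sim$truth$artifact_flags,
                   file.path(out_dir, "truth_artifacts.csv"))
  if (!is.null(patient_cfg)) {
    pa <- names(formals(patient_series_config))
    pcfg <- do.call(patient_series_config,
                    patient_cfg[intersect(names(patient_cfg), pa)])
    pat <- simulate_patient_series(pcfg, sim$truth)
    readr::write_csv(pat$table, file.path(out_dir, "patient_long.csv"))
    readr::write_csv(pat$meta, file.path(out_dir, "patient_meta.csv"))
  }
  write_manifest(file.path(out_dir, "manifest.json"), config,
                 cfg$seed)
  invisible(sim)
}

#' Command-line dispatcher
#'
#' Thin shell entry point over the `run_*()` functions; see
#' `inst/cli/normorph.R`. Subcommands: `simulate`, `build-db`,
#' `assess-visit`, `assess-series`, `loocv`. Each accepts `--config FILE`
#' (JSON) plus subcommand-specific paths.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status 0 on success (invisibly); errors abort with a
#'   message.
#' @export
morph_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: normorph <subcommand> [options]",
    "subcommands:",
    "  simulate      --out DIR [--config FILE]",
    "  build-db      --stats FILE --meta FILE --out FILE [--config FILE] [--dialect D]",
    "  assess-visit  --db FILE --stats FILE --meta FILE --out DIR [--visit ID] [--config FILE]",
    "  assess-series --db FILE --stats FILE --meta FILE --out DIR [--exclusions FILE] [--config FILE]",
    "  loocv         --stats FILE --meta FILE --out DIR [--config FILE]",
    sep = "\n")
  if (length(args) == 0) abort(usage)
  sub <- args[1]
  opts <- parse_cli_options(args[-1])
  cfg <- read_run_config(opts$config)
  switch(sub,
    "simulate" = run_simulate(req_opt(opts, "out"), cfg),
    "build-db" = run_build_db(req_opt(opts, "stats"), req_opt(opts, "meta"),
                              req_opt(opts, "out"), cfg,
                              dialect = opts$dialect %||% "long_csv"),
    "assess-visit" = run_assess_visit(
      req_opt(opts, "db"), req_opt(opts, "stats"), req_opt(opts, "meta"),
      req_opt(opts, "out"), visit_id = opts$visit, config = cfg,
      dialect = opts$dialect %||% "long_csv"),
    "assess-series" = run_assess_series(
      req_opt(opts, "db"), req_opt(opts, "stats"), req_opt(opts, "meta"),
      req_opt(opts, "out"), exclusions_path = opts$exclusions, config = cfg,
      dialect = opts$dialect %||% "long_csv"),
    "loocv" = run_loocv(req_opt(opts, "stats"), req_opt(opts, "meta"),
                        req_opt(opts, "out"), cfg,
                        dialect = opts$dialect %||% "long_csv"),
    abort(paste0("Unknown subcommand '", sub, "'\n", usage))
  )
  invisible(0L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort(paste0("Unexpected argument: ", a))
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      abort(paste0("Option --", key, " needs a value"))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

req_opt <- function(opts, name) {
  val <- opts[[name]]
  if (is.null(val)) abort(paste0("Missing required option --", name))
  val
}
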