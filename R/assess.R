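# Cross-sectional assessment of one patient visit against the normative
# database: per-key residues, measurement-error-inflated p-values, FDR flags,
# highlight levels and validity odds.

#' Assess a single patient visit
#'
#' Scores every modelled key of one patient visit against the matched
#' control subset (same sex, scanner model and acquisition sequence). For
#' each key the patient value is transformed into the key's variant (eTIV
#' scaling, contrast normalization, asymmetry) with the factors frozen in
#' the database, converted to a residue against the control age trend, and
#' assigned the Eq.-style tail p-value with measurement-error-inflated
#' variance. Significance decisions use the calibrated two-sided p:
#' `p < alpha` gives a yellow highlight, surviving Benjamini-Hochberg FDR
#' over all keys of the visit a red one. Keys with too few matched controls
#' are carried as missing rows (`skip_reason`), never silently dropped.
#'
#' @param db A `normative_db`.
#' @param patient_data Long measurement table joined with metadata for
#'   exactly one visit.
#' @param alpha Significance level (the pipeline convention uses 0.01 or
#'   0.05).
#' @param n_min Minimal matched-control count per key.
#' @return A `visit_assessment` tibble, one row per key: `value`, `residue`,
#'   `x_norm`, `sigma_norm`, `sigma_meas`, `sigma` (combined), `n_matched`,
#'   `p_ucor` (toward-the-observation tail), `p_two` (two-sided), `L`
#'   (signed log10 feature), `fdr_significant`, `highlight`, `odds`,
#'   `extrapolated`, `skip_reason`.
#' @export
assess_visit <- function(db, patient_data, alpha = 0.05, n_min = 10) {
  stopifnot(inherits(db, "normative_db"))
  if (nrow(patient_data) == 0) abort("Empty patient table")
  visits <- dplyr::distinct(patient_data, .data$subject_id, .data$visit_id)
  if (nrow(visits) != 1) {
    abort(paste0("assess_visit() scores exactly one visit; got ",
                 nrow(visits), " (use assess_series() for follow-up series)"))
  }
  pmeta <- patient_data[1, c("subject_id", "visit_id", "age", "sex",
                             "scanner_model", "sequence", "etiv")]

  derived <- suppressWarnings(derive_variant_table(
    patient_data, db$variants, db$etiv_ref, db$contrast_ref))
  derived$.key <- key_id(derived$region, derived$hemisphere,
                         derived$parameter, derived$variant)
  derived <- derived[!duplicated(derived$.key), , drop = FALSE]
  keys <- intersect(names(db$entries), derived$.key)
  if (length(keys) == 0) abort("No overlap between patient keys and database")

  rows <- purrr::map_dfr(keys, function(kid) {
    e <- db$entries[[kid]]
    value <- derived$value[match(kid, derived$.key)]
    base <- tibble::tibble(
      key = kid, region = e$region, hemisphere = e$hemisphere,
      parameter = e$parameter, variant = e$variant,
      value = value, residue = NA_real_, x_norm = NA_real_,
      sigma_norm = NA_real_, sigma_meas = e$sigma_meas, sigma = NA_real_,
      n_matched = NA_integer_, p_ucor = NA_real_, p_two = NA_real_,
      odds = e$odds, extrapolated = NA, skip_reason = NA_character_
    )
    if (!is.finite(value)) {
      base$skip_reason <- "missing value"
      return(base)
    }
    matched <- withCallingHandlers(
      match_controls(e, pmeta, n_min),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(matched)) {
      base$skip_reason <- "insufficient matched controls"
      return(base)
    }
    if (!is.finite(matched$sigma_norm) || matched$sigma_norm <= 0) {
      base$skip_reason <- "degenerate normative spread"
      return(base)
    }
    fitted <- predict(e$trend, pmeta$age)
    base$residue <- value - fitted
    base$x_norm <- matched$x_norm
    base$sigma_norm <- matched$sigma_norm
    base$n_matched <- matched$n_matched
    base$sigma <- sqrt(matched$sigma_norm^2 + e$sigma_meas^2)
    base$p_ucor <- visit_pvalue(base$residue, matched$x_norm,
                                matched$sigma_norm, e$sigma_meas, "toward")
    base$p_two <- visit_pvalue(base$residue, matched$x_norm,
                               matched$sigma_norm, e$sigma_meas, "two_sided")
    base$extrapolated <- pmeta$age < e$trend$age_range[1] |
      pmeta$age > e$trend$age_range[2]
    base
  })

  rows$fdr_significant <- fdr_flags(rows$p_two, alpha)
  rows$L <- -sign(rows$residue - rows$x_norm) * log10(rows$p_ucor)
  rows$highlight <- highlight_level(rows$p_two, rows$fdr_significant, alpha)
  rows <- rows[order(rows$key), ]

  structure(rows,
            class = c("visit_assessment", class(tibble::tibble()))) |>
    set_assessment_attrs(alpha = alpha, n_min = n_min, patient = pmeta)
}

set_assessment_attrs <- function(x, alpha, n_min, patient) {
  attr(x, "alpha") <- alpha
  attr(x, "n_min") <- n_min
  attr(x, "patient") <- patient
  x
}

#' Summary counts for a visit assessment
#'
#' @param x A `visit_assessment`.
#' @param ... Unused.
#' @return One-row tibble with test, yellow and red counts.
#' @export
glance.visit_assessment <- function(x, ...) {
  tested <- !is.na(x$p_two)
  tibble::tibble(
    n_keys = nrow(x),
    n_tested = sum(tested),
    n_skipped = sum(!tested),
    n_yellow = sum(x$highlight == "yellow", na.rm = TRUE),
    n_red = sum(x$highlight == "red", na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}
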