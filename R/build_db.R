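# Building the normative database: derive value variants (raw, eTIV /
# scanner-sequence normalized, asymmetry), fit per-key age trends with
# two-pass outlier rejection, estimate measurement error from repeats, and
# attach the artifact / validity-odds model.

# Derive the requested variants as additional long-format rows carrying a
# `variant` column. `contrast_ref` is a per-key, per-group factor table
# estimated from controls; patient rows in groups absent from it are dropped
# with a warning (unmatchable scanner-sequence combination).
derive_variant_table <- function(data, variants, etiv_ref, contrast_ref) {
  pieces <- list()
  if ("raw" %in% variants) {
    pieces$raw <- dplyr::mutate(data, variant = "raw")
  }
  if ("normalized" %in% variants) {
    geom <- dplyr::filter(data, .data$parameter != "gw_contrast",
                          .data$parameter != "clinical_score")
    if (nrow(geom) > 0) {
      geom <- dplyr::mutate(
        geom,
        value = normalize_etiv(.data$value, .data$etiv, etiv_ref,
                               scaling_exponent(.data$parameter)),
        variant = "normalized"
      )
    }
    contr <- dplyr::filter(data, .data$parameter == "gw_contrast")
    if (nrow(contr) > 0) {
      contr <- dplyr::mutate(
        contr, group = paste(.data$scanner_model, .data$sequence, sep = ":"))
      contr <- dplyr::left_join(
        contr, contrast_ref,
        by = c("region", "hemisphere", "parameter", "group"))
      miss <- is.na(contr$factor)
      if (any(miss)) {
        warn(paste0(
          "Dropping ", sum(miss), " contrast value(s) in scanner-sequence ",
          "combination(s) absent from the control set: ",
          paste(unique(contr$group[miss]), collapse = ", ")))
        contr <- contr[!miss, , drop = FALSE]
      }
      contr <- dplyr::mutate(contr, value = .data$value * .data$factor,
                             variant = "normalized")
      contr <- dplyr::select(contr, -"group", -"factor")
    }
    pieces$normalized <- dplyr::bind_rows(geom, contr)
  }
  if ("asymmetry" %in% variants) {
    paired <- data |>
      dplyr::filter(.data$hemisphere %in% c("left", "right")) |>
      tidyr::pivot_wider(names_from = "hemisphere", values_from = "value")
    if (all(c("left", "right") %in% names(paired))) {
      pieces$asymmetry <- paired |>
        dplyr::filter(!is.na(.data$left), !is.na(.data$right)) |>
        dplyr::mutate(
          value = asymmetry_index(.data$right, .data$left),
          hemisphere = "bilateral", variant = "asymmetry"
        ) |>
        dplyr::select(-"left", -"right")
    }
  }
  dplyr::bind_rows(pieces)
}

# Per-key scanner-sequence contrast factors from control data.
build_contrast_ref <- function(hc_data) {
  contr <- dplyr::filter(hc_data, .data$parameter == "gw_contrast",
                         is.finite(.data$value))
  if (nrow(contr) == 0) {
    return(tibble::tibble(region = character(), hemisphere = character(),
                          parameter = character(), group = character(),
                          factor = double()))
  }
  contr |>
    dplyr::mutate(group = paste(.data$scanner_model, .data$sequence,
                                sep = ":")) |>
    dplyr::group_by(.data$region, .data$hemisphere, .data$parameter) |>
    dplyr::group_modify(function(d, g) {
      fac <- contrast_factors(d$value, d$group)
      dplyr::select(fac, "group", "factor")
    }) |>
    dplyr::ungroup()
}

# Fit + reliability + artifact model for one key's data frame.
build_entry <- function(kd, key, alpha_fit) {
  meta_cols <- c("subject_id", "visit_id", "sex", "scanner_model", "sequence")
  trend <- withCallingHandlers(
    fit_age_trend(kd$age, kd$value, alpha_fit, meta = kd[meta_cols]),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(trend)) return(NULL)
  residues <- trend$data
  trend$data <- NULL

  kept <- residues$kept
  rel <- estimate_sigma_meas(residues$residue[kept],
                             residues$subject_id[kept],
                             residues$age[kept])

  n_out <- trend$n_rejected_raw + trend$n_rejected_residual
  sigma_out <- estimate_sigma_out(residues$residue[!kept])
  if (n_out > 0 && is.finite(sigma_out) && sigma_out > 0) {
    p_out <- artifact_p_out(trend$bounds_residual[1],
                            trend$bounds_residual[2], sigma_out)
    art <- artifact_probability(n_out, nrow(residues), p_out)
  } else {
    p_out <- NA_real_
    art <- list(p_art = 0, odds = Inf, lower_limit = TRUE)
  }

  list(
    key = key$id, region = key$region, hemisphere = key$hemisphere,
    parameter = key$parameter, variant = key$variant,
    trend = trend, residues = residues,
    n_kept = trend$n_kept, sigma_norm_all = trend$sigma_norm_all,
    sigma_meas = rel$sigma_meas,
    n_repeat_subjects = rel$n_repeat_subjects,
    no_reliability_data = rel$no_reliability_data,
    n_out = n_out, sigma_out = sigma_out, p_out = p_out,
    p_art = art$p_art, odds = art$odds, odds_lower_limit = art$lower_limit
  )
}

#' Build a normative database from a control cohort
#'
#' For every measurement key (region x hemisphere x parameter x variant) the
#' builder runs the two-pass outlier rejection and degree-selected
#' polynomial age fit, stores the kept-control residues with their metadata,
#' estimates the measurement error from short-interval repeat scans, and
#' derives the artifact model (outlier width `sigma_out`, detectability
#' `p_out`, artifact probability `p_art`, validity odds). The eTIV reference
#' (mean over all control visits) and the per-key scanner-sequence contrast
#' factors are frozen into the database.
#'
#' @param data Long-format measurement table joined with metadata
#'   ([join_metadata()]); only `group == "control"` rows are used.
#' @param variants Variants to model: subset of
#'   `c("raw", "normalized", "asymmetry")`.
#' @param alpha_fit Level of the degree-selection F-test.
#' @param min_values Keys with fewer finite control values are skipped (with
#'   a warning summary).
#' @param seed Optional integer recorded in the provenance (the builder
#'   itself is deterministic).
#' @return A `normative_db` object.
#' @export
build_normative_db <- function(data, variants = c("raw", "normalized", "asymmetry"),
                               alpha_fit = 0.05, min_values = 4, seed = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  need <- c(long_csv_columns, "age", "sex", "scanner_model", "sequence",
            "etiv", "group")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Input is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 " - join measurements with metadata first"))
  }
  assert_taxonomy(data$parameter, data$hemisphere)
  hc <- dplyr::filter(data, .data$group == "control")
  if (nrow(hc) == 0) abort("No control rows in the input")

  visits <- dplyr::distinct(hc, .data$subject_id, .data$visit_id,
                            .keep_all = TRUE)
  etiv_ref <- mean(visits$etiv)
  contrast_ref <- build_contrast_ref(hc)

  full <- derive_variant_table(hc, variants, etiv_ref, contrast_ref)
  full$.key <- key_id(full$region, full$hemisphere, full$parameter,
                      full$variant)
  split_keys <- split(seq_len(nrow(full)), full$.key)

  entries <- list()
  skipped <- character()
  for (kid in names(split_keys)) {
    kd <- full[split_keys[[kid]], , drop = FALSE]
    if (sum(is.finite(kd$value)) < max(4, min_values)) {
      skipped <- c(skipped, kid)
      next
    }
    key <- list(id = kid, region = kd$region[1], hemisphere = kd$hemisphere[1],
                parameter = kd$parameter[1], variant = kd$variant[1])
    entry <- build_entry(kd, key, alpha_fit)
    if (is.null(entry)) skipped <- c(skipped, kid) else entries[[kid]] <- entry
  }
  if (length(skipped) > 0) {
    warn(paste0(length(skipped), " key(s) skipped for insufficient data: ",
                paste(utils::head(skipped, 5), collapse = ", "),
                if (length(skipped) > 5) ", ..."))
  }
  if (length(entries) == 0) abort("No keys could be modelled")

  structure(list(
    entries = entries,
    etiv_ref = etiv_ref,
    contrast_ref = contrast_ref,
    variants = variants,
    alpha_fit = alpha_fit,
    age_range = range(visits$age),
    provenance = list(
      schema_version = NORMDB_SCHEMA_VERSION,
      n_hc_subjects = length(unique(hc$subject_id)),
      n_hc_visits = nrow(visits),
      n_keys = length(entries),
      n_skipped = length(skipped),
      seed = seed,
      package_version = as.character(utils::packageVersion("normorph"))
    )
  ), class = "normative_db")
}

#' @export
print.normative_db <- function(x, ...) {
  p <- x$provenance
  cat("<normative_db>", p$n_keys, "keys |", p$n_hc_visits, "control visits",
      "from", p$n_hc_subjects, "subjects | variants:",
      paste(x$variants, collapse = ", "), "\n")
  cat("  eTIV reference:", format(x$etiv_ref, big.mark = ","), "mm^3 |",
      "age range:", paste(signif(x$age_range, 4), collapse = "-"), "y\n")
  invisible(x)
}

#' Per-key summary of a normative database
#'
#' One row per modelled key: fitted degree, kept/rejected counts, normative
#' spread, measurement error, and the artifact model (the data behind
#' region-wise validity-odds maps). This is the exportable fit/reliability
#' table.
#'
#' @param x A `normative_db`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.normative_db <- function(x, ...) {
  purrr::map_dfr(x$entries, function(e) {
    tibble::tibble(
      key = e$key, region = e$region, hemisphere = e$hemisphere,
      parameter = e$parameter, variant = e$variant,
      degree = e$trend$degree,
      n_kept = e$n_kept,
      n_rejected_raw = e$trend$n_rejected_raw,
      n_rejected_residual = e$trend$n_rejected_residual,
      bound_lower = e$trend$bounds_residual[1],
      bound_upper = e$trend$bounds_residual[2],
      sigma_norm = e$sigma_norm_all,
      sigma_meas = e$sigma_meas,
      n_out = e$n_out, sigma_out = e$sigma_out, p_out = e$p_out,
      p_art = e$p_art, odds = e$odds, odds_lower_limit = e$odds_lower_limit
    )
  })
}

#' One-row provenance summary of a normative database
#'
#' @param x A `normative_db`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.normative_db <- function(x, ...) {
  p <- x$provenance
  tibble::tibble(
    n_keys = p$n_keys, n_hc_subjects = p$n_hc_subjects,
    n_hc_visits = p$n_hc_visits, n_skipped = p$n_skipped,
    etiv_ref = x$etiv_ref, age_min = x$age_range[1], age_max = x$age_range[2],
    alpha_fit = x$alpha_fit, schema_version = p$schema_version
  )
}

#' Coefficient table of a fitted age trend
#'
#' @param x A `morph_trend`.
#' @param ... Unused.
#' @return Tibble with `term` (`age^0`, `age^1`, ...) and `estimate` in
#'   natural age units.
#' @export
tidy.morph_trend <- function(x, ...) {
  tibble::tibble(
    term = paste0("age^", seq_along(x$coefficients) - 1),
    estimate = x$coefficients
  )
}

#' One-row summary of a fitted age trend
#'
#' @param x A `morph_trend`.
#' @param ... Unused.
#' @return A one-row tibble with degree, point counts and residue spread.
#' @export
glance.morph_trend <- function(x, ...) {
  tibble::tibble(
    degree = x$degree, n_kept = x$n_kept,
    n_rejected_raw = x$n_rejected_raw,
    n_rejected_residual = x$n_rejected_residual,
    sigma_norm_all = x$sigma_norm_all,
    age_min = x$age_range[1], age_max = x$age_range[2]
  )
}
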