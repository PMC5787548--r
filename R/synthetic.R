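# Synthetic normative cohorts and patient follow-up series with known ground
# truth. The generator states a world mirroring the reference-cohort setting:
# 323 control visits with a wide (7-79 y) age range, a mild female excess,
# a Verio/Trio scanner mix with several acquisition sequences, polynomial age
# trends per key, additive sex and scanner-sequence offsets, a Gaussian
# between-subject effect shared across repeat scans, Gaussian within-subject
# measurement noise, and a wide-Gaussian artifact component that replaces a
# measurement's subject+noise term at random. Keys are simulated
# independently: inter-regional correlation is deliberately not emulated.

#' Construct synthetic key set
#'
#' Builds a key table of `n_regions` pseudo-regions crossed with hemispheres
#' and parameters, used as the default measurement inventory of
#' [simulate_cohort()].
#'
#' @param n_regions Number of pseudo-atlas regions.
#' @param parameters Parameter names (subset of [morph_parameters()]).
#' @param hemispheres Hemisphere labels per region.
#' @return Tibble with columns `region, hemisphere, parameter`.
#' @export
synthetic_keys <- function(n_regions = 6,
                           parameters = c("volume", "thickness_mean"),
                           hemispheres = c("left", "right")) {
  assert_taxonomy(parameters, hemispheres)
  tidyr::expand_grid(
    region = sprintf("roi%03d", seq_len(n_regions)),
    hemisphere = hemispheres,
    parameter = parameters
  )
}

#' Configuration for a synthetic normative cohort
#'
#' Defaults state the modelled world: 323 subjects aged uniformly 7-79 years,
#' 56% female, four scanner-sequence combinations with reference-like
#' weights, 31 subjects rescanned within two years, unit between-subject SD,
#' half-unit measurement noise, 1% artifact contamination five times wider
#' than the normative spread.
#'
#' @param n_subjects Number of control subjects (each has one visit; repeat
#'   subjects get a second).
#' @param age_range Age interval in years, sampled uniformly.
#' @param sex_ratio Fraction of female subjects.
#' @param scanner_sequence_mix Named weights, names `"scanner:sequence"`.
#' @param keys Key tibble as from [synthetic_keys()]; `NULL` for the default.
#' @param trend_coeffs Optional named list (key id -> numeric coefficients in
#'   increasing powers of age, natural units). Drawn from the seed if `NULL`.
#' @param trend_degrees Degrees to cycle through when drawing trends.
#' @param sigma_norm_true Between-subject SD per key (native units).
#' @param sigma_meas_true Within-subject measurement SD.
#' @param artifact_fraction Probability that a measurement is an artifact.
#' @param artifact_sigma_true SD of the wide artifact component; must exceed
#'   `sigma_norm_true`.
#' @param sex_offset_sd SD of the per-key additive male-vs-female offset.
#' @param group_offset_sd SD of per-key scanner-sequence offsets.
#' @param n_repeat_subjects Subjects with a second scan less than 2 years
#'   after the first.
#' @param repeat_interval_range Interval range (years) for repeat scans.
#' @param etiv_mean,etiv_sd eTIV distribution (mm^3) by sex.
#' @param etiv_scaling If `TRUE`, values are additionally scaled by
#'   `(etiv/reference)^exponent` so that eTIV normalization has something to
#'   remove; off by default (the stated world keeps keys and head size
#'   independent).
#' @param residue_df Degrees of freedom of a Student-t between-subject
#'   effect; `Inf` (default) is Gaussian. Finite values give the heavy-tailed
#'   world used to probe anomaly-rate inflation.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 323,
                          age_range = c(7, 79),
                          sex_ratio = 0.56,
                          scanner_sequence_mix = c(
                            "Verio:MDEFT" = 0.27,
                            "Verio:MPRAGE_vdK" = 0.25,
                            "Trio:MDEFT" = 0.26,
                            "Trio:MPRAGE_std" = 0.22
                          ),
                          keys = NULL,
                          trend_coeffs = NULL,
                          trend_degrees = c(0, 1, 1, 2),
                          sigma_norm_true = 1,
                          sigma_meas_true = 0.5,
                          artifact_fraction = 0.01,
                          artifact_sigma_true = 5,
                          sex_offset_sd = 0.5,
                          group_offset_sd = 0.5,
                          n_repeat_subjects = 31,
                          repeat_interval_range = c(0.1, 1.9),
                          etiv_mean = c(F = 1.45e6, M = 1.6e6),
                          etiv_sd = 1.2e5,
                          etiv_scaling = FALSE,
                          residue_df = Inf,
                          seed = 1L) {
  keys <- keys %||% synthetic_keys()
  cfg <- list(
    n_subjects = n_subjects, age_range = age_range, sex_ratio = sex_ratio,
    scanner_sequence_mix = scanner_sequence_mix, keys = keys,
    trend_coeffs = trend_coeffs, trend_degrees = trend_degrees,
    sigma_norm_true = sigma_norm_true, sigma_meas_true = sigma_meas_true,
    artifact_fraction = artifact_fraction,
    artifact_sigma_true = artifact_sigma_true,
    sex_offset_sd = sex_offset_sd, group_offset_sd = group_offset_sd,
    n_repeat_subjects = n_repeat_subjects,
    repeat_interval_range = repeat_interval_range,
    etiv_mean = etiv_mean, etiv_sd = etiv_sd, etiv_scaling = etiv_scaling,
    residue_df = residue_df, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (diff(range(cfg$age_range)) <= 0) {
    abort("Degenerate age range: zero width")
  }
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction >= 0.5) {
    abort("artifact_fraction must satisfy 0 <= f < 0.5")
  }
  if (cfg$sigma_norm_true <= 0) abort("sigma_norm_true must be > 0")
  if (cfg$sigma_meas_true < 0) abort("sigma_meas_true must be >= 0")
  if (cfg$artifact_sigma_true <= cfg$sigma_norm_true) {
    abort("artifact_sigma_true must exceed sigma_norm_true")
  }
  if (cfg$n_repeat_subjects > cfg$n_subjects) {
    abort("n_repeat_subjects cannot exceed n_subjects")
  }
  invisible(cfg)
}

eval_poly <- function(coeffs, x) {
  # increasing powers, natural units
  y <- rep(0, length(x))
  for (k in rev(seq_along(coeffs))) y <- y * x + coeffs[k]
  y
}

draw_trend_coeffs <- function(keys, degrees) {
  n <- nrow(keys)
  deg <- rep_len(degrees, n)
  lapply(seq_len(n), function(i) {
    c0 <- stats::rnorm(1, 100, 20)
    if (deg[i] == 0) return(c0)
    c1 <- stats::runif(1, -1, 1)
    if (deg[i] == 1) return(c(c0, c1))
    c(c0, c1, stats::runif(1, -0.005, 0.005))
  })
}

#' Simulate a normative control cohort
#'
#' Generates a long-format measurement table, a metadata table and a ground
#' truth record under a [cohort_config()]. Each measurement is
#' `polynomial(age) + sex offset + scanner-sequence offset + subject effect +
#' measurement noise`; with probability `artifact_fraction` the subject+noise
#' term is replaced by a draw from the wide zero-centred artifact Gaussian
#' and the measurement is flagged in the ground truth. Repeat subjects share
#' their subject effect across both visits, so scan-rescan differences
#' estimate measurement error, not between-subject variance.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `table` (long measurements), `meta`
#'   (per-visit metadata) and `truth` (generating parameters plus per-record
#'   artifact flags).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)

  n <- cfg$n_subjects
  subjects <- sprintf("S%04d", seq_len(n))
  age1 <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "F", "M")
  mix <- cfg$scanner_sequence_mix / sum(cfg$scanner_sequence_mix)
  combo <- sample(names(mix), n, replace = TRUE, prob = mix)
  etiv <- stats::rnorm(n, unname(cfg$etiv_mean[sex]), cfg$etiv_sd)
  etiv <- pmax(etiv, 8e5)

  repeat_idx <- seq_len(cfg$n_repeat_subjects)
  interval <- stats::runif(cfg$n_repeat_subjects,
                           cfg$repeat_interval_range[1],
                           cfg$repeat_interval_range[2])

  visit <- tibble::tibble(
    subject = c(seq_len(n), repeat_idx),
    visit_id = c(rep("V1", n), rep("V2", length(repeat_idx))),
    age = c(age1, age1[repeat_idx] + interval)
  )
  nv <- nrow(visit)

  keys <- cfg$keys
  nk <- nrow(keys)
  kid <- key_id(keys$region, keys$hemisphere, keys$parameter, "raw")
  trend <- cfg$trend_coeffs %||% setNames(
    draw_trend_coeffs(keys, cfg$trend_degrees), kid)
  if (!all(kid %in% names(trend))) {
    abort("trend_coeffs must be named by raw key id for every key")
  }
  sex_off <- setNames(stats::rnorm(nk, 0, cfg$sex_offset_sd), kid)
  combos <- names(mix)
  grp_off <- matrix(stats::rnorm(nk * length(combos), 0, cfg$group_offset_sd),
                    nrow = nk, dimnames = list(kid, combos))

  tdf <- cfg$residue_df
  subj_eff <- if (is.finite(tdf)) {
    matrix(stats::rt(n * nk, df = tdf) * cfg$sigma_norm_true /
             sqrt(tdf / (tdf - 2)), nrow = n)
  } else {
    matrix(stats::rnorm(n * nk, 0, cfg$sigma_norm_true), nrow = n)
  }

  values <- matrix(0, nrow = nv, ncol = nk)
  for (k in seq_len(nk)) {
    values[, k] <- eval_poly(trend[[kid[k]]], visit$age) +
      sex_off[k] * (sex[visit$subject] == "M") +
      grp_off[k, combo[visit$subject]] +
      subj_eff[visit$subject, k] +
      stats::rnorm(nv, 0, cfg$sigma_meas_true)
  }
  artifact <- matrix(stats::runif(nv * nk) < cfg$artifact_fraction, nrow = nv)
  if (any(artifact)) {
    nart <- sum(artifact)
    base <- matrix(0, nrow = nv, ncol = nk)
    for (k in seq_len(nk)) {
      base[, k] <- eval_poly(trend[[kid[k]]], visit$age) +
        sex_off[k] * (sex[visit$subject] == "M") +
        grp_off[k, combo[visit$subject]]
    }
    values[artifact] <- base[artifact] +
      stats::rnorm(nart, 0, cfg$artifact_sigma_true)
  }

  if (cfg$etiv_scaling) {
    etiv_center <- cfg$sex_ratio * cfg$etiv_mean[["F"]] +
      (1 - cfg$sex_ratio) * cfg$etiv_mean[["M"]]
    expo <- scaling_exponent(keys$parameter)
    expo[is.na(expo)] <- 0
    scale_mat <- outer((etiv[visit$subject] / etiv_center), expo, `^`)
    values <- values * scale_mat
  }

  meta <- tibble::tibble(
    subject_id = subjects[visit$subject],
    visit_id = visit$visit_id,
    age = visit$age,
    sex = sex[visit$subject],
    scanner_model = sub(":.*$", "", combo[visit$subject]),
    sequence = sub("^[^:]*:", "", combo[visit$subject]),
    etiv = etiv[visit$subject],
    group = "control"
  )

  table <- tidyr::expand_grid(
    v = seq_len(nv), k = seq_len(nk)
  ) |>
    dplyr::mutate(
      subject_id = subjects[visit$subject[.data$v]],
      visit_id = visit$visit_id[.data$v],
      region = keys$region[.data$k],
      hemisphere = keys$hemisphere[.data$k],
      parameter = keys$parameter[.data$k],
      value = values[cbind(.data$v, .data$k)],
      artifact = artifact[cbind(.data$v, .data$k)]
    )

  truth <- list(
    keys = keys, trend_coeffs = trend, sex_offsets = sex_off,
    group_offsets = grp_off,
    sigma_norm_true = cfg$sigma_norm_true,
    sigma_meas_true = cfg$sigma_meas_true,
    artifact_fraction = cfg$artifact_fraction,
    artifact_sigma_true = cfg$artifact_sigma_true,
    artifact_flags = table[c("subject_id", "visit_id", "region", "hemisphere",
                             "parameter", "artifact")],
    config = cfg
  )
  list(
    table = dplyr::select(table, dplyr::all_of(long_csv_columns)),
    meta = meta,
    truth = truth
  )
}

#' Configuration for a synthetic patient follow-up series
#'
#' @param n_visits Number of follow-up scans (at least 3; slope testing needs
#'   `n - 2 >= 1` residual degrees of freedom).
#' @param interval Scan interval in years (default 0.55, the reference
#'   cohort's mean interval).
#' @param slope_true Injected deviation from the normative age trend in
#'   units/year: a scalar or a vector named by raw key id.
#' @param offset_true Baseline residue offset (same conventions).
#' @param sigma_meas_true Measurement noise SD; defaults to the cohort's.
#' @param age_start Patient age at the first scan.
#' @param sex,scanner_model,sequence,etiv Patient characteristics.
#' @param subject_id Identifier used in the output tables.
#' @param seed Integer seed.
#' @return A `patient_series_config` list.
#' @export
patient_series_config <- function(n_visits = 10,
                                  interval = 0.55,
                                  slope_true = 0,
                                  offset_true = 0,
                                  sigma_meas_true = NULL,
                                  age_start = 30,
                                  sex = "F",
                                  scanner_model = "Verio",
                                  sequence = "MPRAGE_vdK",
                                  etiv = 1.45e6,
                                  subject_id = "P0001",
                                  seed = 1L) {
  if (n_visits < 3) {
    abort("n_visits must be >= 3: slope testing needs n - 2 >= 1")
  }
  structure(list(
    n_visits = n_visits, interval = interval, slope_true = slope_true,
    offset_true = offset_true, sigma_meas_true = sigma_meas_true,
    age_start = age_start, sex = sex, scanner_model = scanner_model,
    sequence = sequence, etiv = etiv, subject_id = subject_id,
    seed = as.integer(seed)
  ), class = "patient_series_config")
}

per_key_param <- function(x, kid) {
  if (length(x) == 1 && is.null(names(x))) {
    setNames(rep(x, length(kid)), kid)
  } else {
    out <- setNames(rep(0, length(kid)), kid)
    out[intersect(names(x), kid)] <- x[intersect(names(x), kid)]
    out
  }
}

#' Simulate a patient follow-up series
#'
#' Visit values follow the cohort's normative trend for the patient's
#' demographic cell plus a baseline offset, a linear deviation
#' `slope_true * t` and Gaussian measurement noise, giving series with a
#' known atrophy-progression ground truth.
#'
#' @param config A [patient_series_config()].
#' @param truth Ground truth from [simulate_cohort()] (supplies trends and
#'   offsets).
#' @return List with `table` (long measurements), `meta` (per-visit
#'   metadata, `group = "patient"`) and `truth` (per-key injected slope and
#'   offset).
#' @export
simulate_patient_series <- function(config, truth) {
  cfg <- config
  if (cfg$n_visits < 3) abort("n_visits must be >= 3")
  set.seed(cfg$seed)

  keys <- truth$keys
  kid <- key_id(keys$region, keys$hemisphere, keys$parameter, "raw")
  slope <- per_key_param(cfg$slope_true, kid)
  offset <- per_key_param(cfg$offset_true, kid)
  sig <- cfg$sigma_meas_true %||% truth$sigma_meas_true

  t_rel <- (seq_len(cfg$n_visits) - 1) * cfg$interval
  ages <- cfg$age_start + t_rel
  combo <- paste(cfg$scanner_model, cfg$sequence, sep = ":")
  grp <- if (combo %in% colnames(truth$group_offsets)) {
    truth$group_offsets[, combo]
  } else {
    setNames(rep(0, length(kid)), kid)
  }

  rows <- lapply(seq_along(kid), function(k) {
    val <- eval_poly(truth$trend_coeffs[[kid[k]]], ages) +
      truth$sex_offsets[k] * (cfg$sex == "M") + grp[k] +
      offset[kid[k]] + slope[kid[k]] * t_rel +
      stats::rnorm(cfg$n_visits, 0, sig)
    tibble::tibble(
      subject_id = cfg$subject_id,
      visit_id = sprintf("T%02d", seq_len(cfg$n_visits)),
      region = keys$region[k], hemisphere = keys$hemisphere[k],
      parameter = keys$parameter[k], value = val
    )
  })
  meta <- tibble::tibble(
    subject_id = cfg$subject_id,
    visit_id = sprintf("T%02d", seq_len(cfg$n_visits)),
    age = ages, sex = cfg$sex, scanner_model = cfg$scanner_model,
    sequence = cfg$sequence, etiv = cfg$etiv, group = "patient"
  )
  list(
    table = dplyr::bind_rows(rows),
    meta = meta,
    truth = list(slope_true = slope, offset_true = offset,
                 sigma_meas_true = sig, times = t_rel)
  )
}
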