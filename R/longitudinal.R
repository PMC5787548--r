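# Longitudinal trend estimation for patient follow-up series: linear residue
# trends, their uncertainty, consistency with measurement error, slope and
# mean-position tests, and clinical score series.
#
# Conventions: the residual variance S^2 is RSS/n (maximum-likelihood
# convention) and sigma_t^2 is the population (divide-by-n) variance of the
# visit times. Under exactly these conventions the slope uncertainty
# Delta_a = S / (sigma_t * sqrt(n - 2)) reproduces the textbook OLS slope
# standard error sqrt((RSS/(n-2)) / sum((t - tbar)^2)) identically.

#' Fit a linear trend to a residue series
#'
#' Ordinary least squares of `x(t) = a * t + x_0` on a patient's residues at
#' visit times `t` (years).
#'
#' @param times Visit times in years (not all equal).
#' @param residues Residues against the normative age trend.
#' @return List with slope `a` (units/year), intercept `x0`, residual
#'   variance `S2 = RSS / n`, `rss`, `sigma_t` (population SD of times) and
#'   `n`; or `NULL` (key skipped) when fewer than 3 points are available.
#' @export
#' @examples
#' fit_series(c(0, 1, 2), c(0, 2, 0)) # a = 0, x0 = 2/3, S2 = 8/9
fit_series <- function(times, residues) {
  ok <- is.finite(times) & is.finite(residues)
  times <- times[ok]; residues <- residues[ok]
  n <- length(times)
  if (n < 3) {
    warn("Fewer than 3 usable visits: key skipped")
    return(NULL)
  }
  if (diff(range(times)) == 0) abort("Zero spread of visit times")
  tbar <- mean(times)
  a <- sum((times - tbar) * (residues - mean(residues))) /
    sum((times - tbar)^2)
  x0 <- mean(residues) - a * tbar
  rss <- sum((residues - (a * times + x0))^2)
  list(a = a, x0 = x0, S2 = rss / n, rss = rss,
       sigma_t = sqrt(sum((times - tbar)^2) / n), n = n)
}

#' Slope uncertainty of a linear residue trend
#'
#' `Delta_a = sqrt(S2) / (sigma_t * sqrt(n - 2))` with `S2 = RSS/n` and
#' `sigma_t` the population SD of the visit times; algebraically identical
#' to the classical OLS slope standard error.
#'
#' @param S2 Residual variance `RSS / n`.
#' @param sigma_t Population SD of visit times (> 0).
#' @param n Number of visits used (>= 3).
#' @return `Delta_a` (units/year).
#' @export
slope_uncertainty <- function(S2, sigma_t, n) {
  if (n < 3) abort("Slope uncertainty needs n >= 3")
  if (!is.finite(sigma_t) || sigma_t <= 0) abort("sigma_t must be > 0")
  sqrt(S2) / (sigma_t * sqrt(n - 2))
}

#' Chi-squared consistency of a linear trend with measurement error
#'
#' Tests whether the residual variance of the linear fit exceeds what the
#' measurement error allows: the statistic `n * S2 / sigma_meas^2`
#' (= RSS / sigma_meas^2) is compared with the upper tail of a chi-squared
#' distribution with `n - 2` degrees of freedom. A small p-value means the
#' linear model fits worse than pure measurement noise would, so its slope
#' should not be interpreted.
#'
#' @param S2 Residual variance `RSS / n` of the linear fit.
#' @param sigma_meas Measurement error SD (> 0; a zero value skips the test).
#' @param n Number of visits used.
#' @return Upper-tail p-value, or `NA` when `sigma_meas` is zero/unknown.
#' @export
consistency_chi2 <- function(S2, sigma_meas, n) {
  if (!is.finite(sigma_meas) || sigma_meas <= 0) return(NA_real_)
  pchisq(n * S2 / sigma_meas^2, df = n - 2, lower.tail = FALSE)
}

#' z-test of a slope against zero
#'
#' Two-sided normal test `p = 2 (1 - Phi(|a| / Delta_a))` of whether the
#' fitted annual change rate differs from zero, i.e. whether the patient's
#' trajectory deviates from the cross-sectional aging already subtracted in
#' the residues.
#'
#' @param a Fitted slope.
#' @param delta_a Slope uncertainty from [slope_uncertainty()].
#' @return Two-sided p-value (exactly 0 for a noiseless nonzero trend, 1
#'   for a zero slope).
#' @export
slope_test <- function(a, delta_a) {
  if (a == 0) return(1)
  if (delta_a == 0) return(0)
  2 * pnorm(-abs(a) / delta_a)
}

#' Welch test of mean residue position
#'
#' Two-sample t-test (unequal group sizes and variances,
#' Welch-Satterthwaite degrees of freedom) of whether a patient's residues
#' sit at a different mean level than the matched controls'.
#'
#' @param patient_residues,control_residues Numeric vectors (>= 2 values
#'   each).
#' @return Two-sided p-value; degenerate zero-variance inputs give 1 for
#'   equal means and 0 otherwise.
#' @export
mean_position_test <- function(patient_residues, control_residues) {
  x <- patient_residues[is.finite(patient_residues)]
  y <- control_residues[is.finite(control_residues)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Both groups need at least 2 values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  t.test(x, y)$p.value
}

#' Outlier rejection within a follow-up series
#'
#' Applies the same Tukey-fence rejection used in the control cohort to the
#' patient's own residue series, and honours a manual exclusion list (the
#' automated scheme is meant to be followed by visual inspection, with rare
#' manual exclusions).
#'
#' @param residues Residue series.
#' @param bounds Optional list with `lower`/`upper`; computed from the
#'   series itself via [iqr_bounds()] when `NULL`.
#' @param manual_exclude Integer indices to exclude regardless of bounds.
#' @return Integer vector of kept indices (`NULL` with a warning when fewer
#'   than 3 survive).
#' @export
#' @examples
#' series_outlier_rejection(c(0.1, 0, -0.1, 50)) # drops the 50
series_outlier_rejection <- function(residues, bounds = NULL,
                                     manual_exclude = integer(0)) {
  b <- bounds %||% iqr_bounds(residues)
  if (is.null(b)) return(NULL)
  keep <- which(is.finite(residues) & residues >= b$lower &
                  residues <= b$upper)
  keep <- setdiff(keep, manual_exclude)
  if (length(keep) < 3) {
    warn("Fewer than 3 surviving visits after outlier rejection: key skipped")
    return(NULL)
  }
  keep
}

# ---- Spearman with exact permutation p for small n (handles ties) --------

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

spearman_test <- function(x, y, exact_max_n = 9) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- all_permutations(n)
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    rxc <- rx - mean(rx)
    num <- as.vector(ryp %*% rxc)
    den <- sqrt(sum(rxc^2)) * sqrt(sum((ry - mean(ry))^2))
    rho_perm <- num / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Trend statistics for a clinical score series
#'
#' Applies the same linear-trend machinery to clinical series (disability
#' scores such as the EDSS, or lesion volume): annual change rate with a
#' z-test against zero, plus the Spearman rank correlation of the score
#' with age. The Spearman p-value is computed by exact permutation
#' enumeration for `n <= 9` (handles tied ordinal scores correctly) and by
#' the t-approximation for larger series.
#'
#' @param times Visit times (years), strictly increasing.
#' @param scores Clinical scores (ordinal or continuous).
#' @return Tibble with `annual_rate`, `p_rate`, `spearman_rho`,
#'   `p_spearman`, `n`. Constant scores give rate 0 and a missing rho.
#' @export
clinical_trend <- function(times, scores) {
  if (any(diff(times) <= 0)) abort("Visit times must be strictly increasing")
  fs <- fit_series(times, scores)
  if (is.null(fs)) abort("Clinical trend needs at least 3 visits")
  if (fs$S2 == 0 && fs$a == 0) {
    p_rate <- 1
  } else {
    p_rate <- slope_test(fs$a, slope_uncertainty(fs$S2, fs$sigma_t, fs$n))
  }
  sp <- spearman_test(times, scores)
  tibble::tibble(
    annual_rate = fs$a, p_rate = p_rate,
    spearman_rho = sp$rho, p_spearman = sp$p, n = fs$n
  )
}

#' Assess a patient's follow-up series
#'
#' For every modelled key, converts the patient's visits into residues
#' against the control age trend (same variant machinery as
#' [assess_visit()]), rejects within-series outliers, fits the linear model
#' `x(t) = a t + x_0`, and reports the slope with its uncertainty, the
#' chi-squared consistency check against the measurement error, the
#' two-sided z-test of the slope against zero (i.e. against pure
#' cross-sectional aging, already subtracted in the residues), and the
#' Welch test of the mean residue position against the matched controls.
#' Highlighting follows the same yellow/red convention as single visits,
#' with FDR over the slope tests of all keys.
#'
#' @param db A `normative_db`.
#' @param patient_data Long measurement table joined with metadata for one
#'   patient with at least 3 visits.
#' @param alpha Significance level.
#' @param n_min Minimal matched-control count per key.
#' @param exclusions Optional manual exclusion table with columns `key` and
#'   `visit_id`.
#' @return A `series_assessment` tibble, one row per key.
#' @export
assess_series <- function(db, patient_data, alpha = 0.05, n_min = 10,
                          exclusions = NULL) {
  stopifnot(inherits(db, "normative_db"))
  if (nrow(patient_data) == 0) abort("Empty patient table")
  if (length(unique(patient_data$subject_id)) != 1) {
    abort("assess_series() expects one patient")
  }
  visits <- dplyr::distinct(patient_data, .data$visit_id, .data$age)
  if (nrow(visits) < 3) {
    abort("Follow-up analysis needs at least 3 visits; use assess_visit()")
  }
  pmeta <- patient_data[1, c("subject_id", "sex", "scanner_model",
                             "sequence", "etiv")]

  derived <- suppressWarnings(derive_variant_table(
    patient_data, db$variants, db$etiv_ref, db$contrast_ref))
  derived$.key <- key_id(derived$region, derived$hemisphere,
                         derived$parameter, derived$variant)
  keys <- intersect(names(db$entries), unique(derived$.key))
  if (length(keys) == 0) abort("No overlap between patient keys and database")

  rows <- purrr::map_dfr(keys, function(kid) {
    e <- db$entries[[kid]]
    kd <- derived[derived$.key == kid, , drop = FALSE]
    kd <- kd[order(kd$age), ]
    base <- tibble::tibble(
      key = kid, region = e$region, hemisphere = e$hemisphere,
      parameter = e$parameter, variant = e$variant,
      n_used = NA_integer_, n_excluded = NA_integer_,
      slope = NA_real_, intercept = NA_real_, S2 = NA_real_,
      sigma_t = NA_real_, delta_a = NA_real_,
      p_consistency = NA_real_, p_slope = NA_real_, p_welch = NA_real_,
      odds = e$odds, skip_reason = NA_character_
    )
    res <- kd$value - predict(e$trend, kd$age)
    ok <- is.finite(res)
    if (sum(ok) < 3) {
      base$skip_reason <- "fewer than 3 usable visits"
      return(base)
    }
    manual <- integer(0)
    if (!is.null(exclusions)) {
      manual <- which(kd$visit_id %in%
                        exclusions$visit_id[exclusions$key == kid])
    }
    keep <- withCallingHandlers(
      series_outlier_rejection(res, manual_exclude = manual),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(keep)) {
      base$skip_reason <- "fewer than 3 visits after outlier rejection"
      return(base)
    }
    fs <- withCallingHandlers(fit_series(kd$age[keep], res[keep]),
                              warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fs)) {
      base$skip_reason <- "series fit failed"
      return(base)
    }
    base$n_used <- fs$n
    base$n_excluded <- sum(ok) - length(keep)
    base$slope <- fs$a
    base$intercept <- fs$x0
    base$S2 <- fs$S2
    base$sigma_t <- fs$sigma_t
    base$delta_a <- slope_uncertainty(fs$S2, fs$sigma_t, fs$n)
    base$p_consistency <- consistency_chi2(fs$S2, e$sigma_meas, fs$n)
    base$p_slope <- slope_test(fs$a, base$delta_a)
    matched <- withCallingHandlers(
      match_controls(e, pmeta, n_min),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(matched) && length(keep) >= 2) {
      base$p_welch <- mean_position_test(res[keep], matched$residues)
    }
    base
  })

  rows$fdr_significant <- fdr_flags(rows$p_slope, alpha)
  rows$highlight <- highlight_level(rows$p_slope, rows$fdr_significant, alpha)
  rows <- rows[order(rows$key), ]
  structure(rows,
            class = c("series_assessment", class(tibble::tibble()))) |>
    set_assessment_attrs(alpha = alpha, n_min = n_min, patient = pmeta)
}

#' Summary counts for a series assessment
#'
#' @param x A `series_assessment`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.series_assessment <- function(x, ...) {
  tested <- !is.na(x$p_slope)
  tibble::tibble(
    n_keys = nrow(x), n_tested = sum(tested), n_skipped = sum(!tested),
    n_yellow = sum(x$highlight == "yellow", na.rm = TRUE),
    n_red = sum(x$highlight == "red", na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}
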