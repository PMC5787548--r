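# Measurement error from short-interval repeat scans, and the artifact /
# validity-odds model estimated from observed outlier rates.

#' Estimate measurement error from repeat scans
#'
#' The region- and parameter-specific measurement accuracy is the pooled
#' within-subject standard deviation of age-trend residues across subjects
#' with more than one scan acquired less than 2 years apart:
#' `sigma_meas = sqrt( sum_i sum_j (x_ij - mean_i)^2 / sum_i (k_i - 1) )`.
#' Short separation makes the repeats measure scan-rescan reliability rather
#' than aging.
#'
#' @param residues Age-trend residues (kept points only).
#' @param subject Subject identifier per residue.
#' @param age Age (years) per residue; a subject qualifies when they have at
#'   least two residues spanning less than `max_separation` years.
#' @param max_separation Qualification threshold in years (default 2).
#' @return List with `sigma_meas`, `n_repeat_subjects`, `n_repeat_visits`,
#'   and `no_reliability_data` (`TRUE` with `sigma_meas = 0` when no subject
#'   qualifies).
#' @export
estimate_sigma_meas <- function(residues, subject, age,
                                max_separation = 2) {
  ok <- is.finite(residues) & is.finite(age)
  residues <- residues[ok]; subject <- subject[ok]; age <- age[ok]
  split_res <- split(residues, subject)
  split_age <- split(age, subject)
  qual <- vapply(seq_along(split_res), function(i) {
    length(split_res[[i]]) >= 2 &&
      diff(range(split_age[[i]])) < max_separation
  }, logical(1))
  if (!any(qual)) {
    return(list(sigma_meas = 0, n_repeat_subjects = 0L, n_repeat_visits = 0L,
                no_reliability_data = TRUE))
  }
  ss <- 0; dfree <- 0; nvis <- 0
  for (x in split_res[qual]) {
    ss <- ss + sum((x - mean(x))^2)
    dfree <- dfree + length(x) - 1
    nvis <- nvis + length(x)
  }
  list(
    sigma_meas = sqrt(ss / dfree),
    n_repeat_subjects = sum(qual),
    n_repeat_visits = as.integer(nvis),
    no_reliability_data = FALSE
  )
}

#' Width of the artifact distribution
#'
#' Artifact-caused residues are modelled as a zero-centred Gaussian whose
#' width is estimated by the mean absolute fit residue of all controls that
#' were discarded as outliers.
#'
#' @param outlier_residues Final-fit residues of the rejected controls.
#' @return `sigma_out` (mean absolute residue), or `NA` when no outliers
#'   were observed (the artifact model then takes the `p_art = 0` branch).
#' @export
#' @examples
#' estimate_sigma_out(c(4, -6)) # 5
estimate_sigma_out <- function(outlier_residues) {
  x <- outlier_residues[is.finite(outlier_residues)]
  if (length(x) == 0) return(NA_real_)
  mean(abs(x))
}

#' Probability of detecting an artifact as an outlier
#'
#' Given the residual-scale outlier thresholds and the artifact width, the
#' probability that an artifact-related measurement falls outside the
#' detection window is
#' `p_out = Phi_sigma(x_lower) + 1 - Phi_sigma(x_upper)`, the two-tail mass
#' of the zero-centred artifact Gaussian beyond the fences. Artifacts inside
#' the window remain undetected, which is why observed outlier rates must be
#' scaled up by `1 / p_out`.
#'
#' @param x_lower,x_upper Residual-scale outlier thresholds.
#' @param sigma_out Artifact width (> 0).
#' @return `p_out` in `[0, 1]`.
#' @export
#' @examples
#' artifact_p_out(-1.96, 1.96, 1) # ~0.05
artifact_p_out <- function(x_lower, x_upper, sigma_out) {
  if (!is.finite(sigma_out) || sigma_out <= 0) {
    abort("sigma_out must be a positive number")
  }
  pnorm(x_lower / sigma_out) + 1 - pnorm(x_upper / sigma_out)
}

#' Artifact probability and validity odds
#'
#' Scales the empirical outlier rate up by the detectability factor:
#' `p_art = (N_out / N) / p_out` (capped at 1), and converts it to the odds
#' for a valid as opposed to an artifact-corrupted observation,
#' `odds = (1 - p_art) / p_art`. If no outliers were observed, `p_art = 0`
#' and the odds are infinite; this is only a lower limit of the true
#' artifact probability and is flagged as such.
#'
#' @param n_out Observed outlier count.
#' @param n Number of control measurements.
#' @param p_out Detectability from [artifact_p_out()].
#' @return List with `p_art`, `odds`, and `lower_limit` (TRUE when no
#'   outliers were observed).
#' @export
#' @examples
#' artifact_probability(3, 323, 0.5) # p_art ~0.0186, odds ~52.8
artifact_probability <- function(n_out, n, p_out) {
  if (n <= 0 || n_out < 0 || n_out > n) {
    abort("Need 0 <= n_out <= n and n > 0")
  }
  if (n_out == 0) {
    return(list(p_art = 0, odds = Inf, lower_limit = TRUE))
  }
  if (!is.finite(p_out) || p_out <= 0) {
    abort("Inconsistent artifact model: outliers observed but p_out = 0")
  }
  p_art <- min(1, (n_out / n) / p_out)
  odds <- if (p_art > 0) (1 - p_art) / p_art else Inf
  list(p_art = p_art, odds = odds, lower_limit = FALSE)
}
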