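# Scoring a single observation against the matched normative subset:
# measurement-error-inflated p-values, FDR flags, highlight levels and
# signed-log feature vectors.

#' Matched control subset for a patient
#'
#' Restricts a database entry's kept control residues to those controls who
#' match the patient exactly on sex, scanner model and acquisition sequence,
#' and computes the subset statistics used in the p-value. Matching trades a
#' smaller reference set for the removal of known categorical confounders;
#' the polynomial age trend itself is always fitted on all controls.
#'
#' @param entry A `normative_db` entry (see [build_normative_db()]).
#' @param patient_meta One-row data frame (or list) with `sex`,
#'   `scanner_model`, `sequence`.
#' @param n_min Minimal matched-subset size; below it the key is skipped
#'   with a warning rather than silently falling back to unmatched controls.
#' @return List with `x_norm` (subset mean residue), `sigma_norm` (subset
#'   SD), `n_matched` and `residues`; or `NULL` when fewer than `n_min`
#'   controls match.
#' @export
match_controls <- function(entry, patient_meta, n_min = 10) {
  d <- entry$residues
  sel <- d$kept &
    d$sex == patient_meta$sex &
    d$scanner_model == patient_meta$scanner_model &
    d$sequence == patient_meta$sequence
  x <- d$residue[sel]
  if (length(x) < n_min) {
    warn(paste0("Insufficient matched controls (", length(x), " < ", n_min,
                ") for key ", entry$key %||% "", ": skipped"))
    return(NULL)
  }
  list(x_norm = mean(x), sigma_norm = sd(x), n_matched = length(x),
       residues = x)
}

#' Measurement-error-aware p-value of an observation
#'
#' The probability of finding an observation at residue `x` when the
#' normative residues are Gaussian with mean `x_norm` and SD `sigma_norm`
#' and the observation itself carries measurement error `sigma_meas`; the
#' variances add, `sigma^2 = sigma_norm^2 + sigma_meas^2`. Three tail
#' conventions are available:
#'
#' * `"toward"` (default): the tail toward the observation,
#'   `1 - Phi((x - x_norm)/sigma)` above the mean and
#'   `Phi((x - x_norm)/sigma)` below it. This is the quantity reported per
#'   key; it lives in `(0, 0.5]` and equals 0.5 at the mean ("no evidence").
#' * `"upper"`: the smooth upper-tail probability `1 - Phi(z)`, for which
#'   `p(x_norm + d) + p(x_norm - d) = 1` holds exactly.
#' * `"two_sided"`: `2 * min(upper, 1 - upper)`, Uniform(0, 1) under the
#'   null; this is the p-value used for significance decisions (yellow/red
#'   highlighting, FDR, anomaly counting) so that "p < alpha" flags a
#'   fraction alpha of normal measurements.
#'
#' @param x Observed residue(s).
#' @param x_norm Matched-subset mean residue.
#' @param sigma_norm Matched-subset SD (> 0).
#' @param sigma_meas Measurement error SD (>= 0).
#' @param tail Tail convention, see above.
#' @return p-value(s).
#' @export
#' @examples
#' visit_pvalue(5, 0, 3, 4)              # z = 1, p = 0.159
#' visit_pvalue(0, 0, 1, 0)              # at the mean: 0.5
#' visit_pvalue(-1.6449, 0, 1, 0)        # ~0.05
visit_pvalue <- function(x, x_norm, sigma_norm, sigma_meas = 0,
                         tail = c("toward", "upper", "two_sided")) {
  tail <- match.arg(tail)
  if (any(!is.finite(sigma_norm) | sigma_norm <= 0)) {
    abort("sigma_norm must be > 0 (degenerate normative spread: skip the key)")
  }
  if (any(sigma_meas < 0)) abort("sigma_meas must be >= 0")
  sigma <- sqrt(sigma_norm^2 + sigma_meas^2)
  z <- (x - x_norm) / sigma
  upper <- pnorm(z, lower.tail = FALSE)
  switch(tail,
    toward = ifelse(z > 0, upper, pnorm(z)),
    upper = upper,
    two_sided = pmin(1, 2 * pmin(upper, 1 - upper))
  )
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false-discovery-rate control over all tests of one dataset.
#'
#' @param p p-values (NAs allowed, never flagged).
#' @param alpha FDR level.
#' @return Logical vector: `TRUE` where the test survives FDR correction.
#' @export
#' @examples
#' fdr_flags(c(0.001, 0.02, 0.03, 0.04), 0.05) # all TRUE
fdr_flags <- function(p, alpha = 0.05) {
  adj <- p.adjust(p, method = "BH")
  !is.na(adj) & adj <= alpha
}

#' Highlight level of a deviation
#'
#' Mirrors the standardized report colouring: deviations significant before
#' multiple-comparison correction get a yellow background (statistical
#' anomalies requiring secondary expert inspection), deviations that remain
#' significant after FDR correction a red one.
#'
#' @param p Significance p-value(s).
#' @param fdr_flag Logical FDR survival flag(s).
#' @param alpha Significance level.
#' @return Factor with levels `none`, `yellow`, `red`.
#' @export
highlight_level <- function(p, fdr_flag, alpha = 0.05) {
  lev <- ifelse(!is.na(fdr_flag) & fdr_flag, "red",
                ifelse(!is.na(p) & p < alpha, "yellow", "none"))
  factor(lev, levels = c("none", "yellow", "red"))
}

#' Feature vector of signed log p-values
#'
#' `L = -sign(x - x_norm) * log10(p)`: large positive values flag
#' significantly increased measurements, large negative values significantly
#' decreased ones, values near zero insignificant deviations. Skipped keys
#' are carried as missing entries in a deterministic key order.
#'
#' @param assessment A `visit_assessment` tibble from [assess_visit()], or
#'   any data frame with columns `key`, `residue`, `x_norm`, `p_ucor`.
#' @return Named numeric vector (names = key ids, ordered by key id).
#' @export
feature_vector <- function(assessment) {
  d <- assessment[order(assessment$key), ]
  L <- -sign(d$residue - d$x_norm) * log10(d$p_ucor)
  setNames(L, d$key)
}

#' Pearson correlation matrix of feature vectors
#'
#' Correlations between feature vectors of different scans quantify how
#' reproducible the deviation pattern is: repeat scans of one subject, or
#' scans of one patient, correlate strongly while unrelated controls do not.
#'
#' @param vectors Matrix with one column per scan (rows = keys), or a list
#'   of equally-named feature vectors.
#' @param min_shared Minimal number of shared non-missing entries for a
#'   pair; below it the cell is `NA`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation_matrix <- function(vectors, min_shared = 3) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(cbind, vectors)
  }
  if (ncol(vectors) < 2) abort("Need at least 2 feature vectors")
  r <- suppressWarnings(cor(vectors, use = "pairwise.complete.obs"))
  obs <- !is.na(vectors)
  shared <- crossprod(obs)
  r[shared < min_shared] <- NA_real_
  diag(r) <- 1
  r
}
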