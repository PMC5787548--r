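# Polynomial age-trend modelling with two-pass outlier rejection.
#
# Quality control first rejects raw values more than 1.5 interquartile ranges
# outside the 25%/75% percentiles, then repeats the same rejection on the
# residues of a provisional polynomial fit, and finally refits on the doubly
# cleaned data. The polynomial degree is increased stepwise from zero until
# the higher degree ceases to reduce the residue variance significantly in a
# nested-model F-test, with a per-step Bonferroni correction of the level
# (alpha / d at step d) and a heuristic upper limit d_max = floor(N / 20).
#
# Quartile convention: linear interpolation between order statistics
# (stats::quantile type 7). Fits are performed on a centred/scaled age axis
# for conditioning; reported coefficients are in natural age units.

#' Tukey-fence outlier bounds
#'
#' Computes the within-group thresholds `lower = Q25 - 1.5 IQR` and
#' `upper = Q75 + 1.5 IQR` (type-7 quantiles) and flags values strictly
#' outside them.
#'
#' @param values Numeric vector; at least 4 finite values are required
#'   (otherwise `NULL` is returned with a warning and the key is skipped).
#' @return List with `lower`, `upper`, `keep` (logical per input element,
#'   `NA` for missing values), and `n_rejected`; or `NULL` if too few values.
#' @export
#' @examples
#' iqr_bounds(c(0, 0, 0, 0, 1000))$n_rejected # the 1000 is rejected
iqr_bounds <- function(values) {
  finite <- is.finite(values)
  if (sum(finite) < 4) {
    warn("Fewer than 4 finite values: key skipped")
    return(NULL)
  }
  q <- quantile(values[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  keep <- ifelse(is.na(values) | !finite, NA,
                 values >= lower & values <= upper)
  list(lower = lower, upper = upper, keep = keep,
       n_rejected = sum(!keep, na.rm = TRUE))
}

# Least squares of y on powers 0..degree of z. Returns coefficients, RSS and
# the inverse cross-product needed for confidence bands.
polyfit_scaled <- function(z, y, degree) {
  X <- outer(z, 0:degree, `^`)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank,
       R = qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
}

# Stepwise-up degree selection; returns the accepted degree and its fit.
select_fit <- function(z, y, alpha_fit, d_max) {
  n <- length(y)
  fit <- polyfit_scaled(z, y, 0)
  degree <- 0
  d <- 1
  while (d <= d_max && n >= d + 2) {
    cand <- polyfit_scaled(z, y, d)
    df2 <- n - d - 1
    f <- (fit$rss - cand$rss) / (cand$rss / df2)
    accept <- if (is.nan(f)) FALSE else f > qf(1 - alpha_fit / d, 1, df2)
    if (!accept) break
    fit <- cand
    degree <- d
    d <- d + 1
  }
  list(degree = degree, fit = fit)
}

#' Select the polynomial degree of an age trend
#'
#' Starting from a constant fit, the degree is increased stepwise; at step
#' `d` the nested-model F statistic
#' `F = (RSS_{d-1} - RSS_d) / (RSS_d / (N - d - 1))` is compared with the
#' upper `alpha_fit / d` quantile of `F(1, N - d - 1)` (per-step Bonferroni
#' correction), and the procedure stops at the first non-significant step.
#' The maximal degree is `floor(N / 20)`; fewer than 20 points force a
#' constant fit.
#'
#' @param ages,values Paired numeric vectors (non-finite pairs are dropped).
#' @param alpha_fit Significance level of the stepwise F-test (default 0.05).
#' @param d_max Maximal degree; default `floor(N / 20)`.
#' @return The selected degree (integer).
#' @export
#' @examples
#' max_degree(323) # 16
select_degree <- function(ages, values, alpha_fit = 0.05, d_max = NULL) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(values)
  d_max <- d_max %||% max_degree(n)
  s <- sd(ages)
  if (!is.finite(s) || s == 0) return(0L)
  z <- (ages - mean(ages)) / s
  as.integer(select_fit(z, values, alpha_fit, d_max)$degree)
}

#' Heuristic maximal polynomial degree
#'
#' @param n Number of fitted points.
#' @return `floor(n / 20)` (0 for fewer than 20 points).
#' @export
max_degree <- function(n) {
  max(0L, as.integer(floor(n / 20)))
}

# polynomial arithmetic on coefficient vectors (increasing powers)
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# coefficients of sum_k b_k ((x - m)/s)^k in natural powers of x
natural_coeffs <- function(b, m, s) {
  b <- unname(b)
  out <- b[1]
  base <- c(-m / s, 1 / s)
  cur <- 1
  for (k in seq_along(b)[-1]) {
    cur <- polymul(cur, base)
    out <- c(out, numeric(max(0, length(cur) - length(out))))
    out[seq_along(cur)] <- out[seq_along(cur)] + b[k] * cur
  }
  out
}

# Lean two-pass pipeline used by both the database builder and the LOOCV
# loop. Operates on bare vectors; returns everything downstream statistics
# need. `idx` indexes the original input vectors.
fit_pipeline <- function(ages, values, alpha_fit = 0.05) {
  ok <- is.finite(ages) & is.finite(values)
  if (sum(ok) < 4) return(NULL)
  idx <- which(ok)
  a <- ages[idx]; v <- values[idx]

  b1 <- iqr_bounds(v)
  keep1 <- b1$keep
  a1 <- a[keep1]; v1 <- v[keep1]

  m <- mean(a1); s <- sd(a1)
  if (!is.finite(s) || s == 0) s <- 1
  n1 <- length(v1)
  prov <- select_fit((a1 - m) / s, v1, alpha_fit, max_degree(n1))
  res1 <- v1 - drop(outer((a1 - m) / s, 0:prov$degree, `^`) %*% prov$fit$coef)

  b2 <- iqr_bounds(res1)
  if (is.null(b2)) return(NULL)
  keep2 <- b2$keep
  a2 <- a1[keep2]; v2 <- v1[keep2]

  m2 <- mean(a2); s2 <- sd(a2)
  if (!is.finite(s2) || s2 == 0) s2 <- 1
  fin <- select_fit((a2 - m2) / s2, v2, alpha_fit, max_degree(length(v2)))

  res_all <- v - drop(outer((a - m2) / s2, 0:fin$degree, `^`) %*% fin$fit$coef)
  kept <- keep1
  kept[keep1] <- keep2
  n_kept <- sum(kept)
  df_resid <- n_kept - fin$degree - 1

  list(
    idx = idx, ages = a, values = v, residues = res_all, kept = kept,
    degree = fin$degree, coef_scaled = fin$fit$coef, center = m2, scale = s2,
    R = fin$fit$R, sigma2 = if (df_resid > 0) fin$fit$rss / df_resid else NA_real_,
    df_resid = df_resid,
    n_rejected_raw = b1$n_rejected, n_rejected_residual = b2$n_rejected,
    bounds_raw = c(b1$lower, b1$upper),
    bounds_residual = c(b2$lower, b2$upper),
    n_kept = n_kept,
    sigma_norm_all = sd(res_all[kept]),
    age_range = range(a2)
  )
}

predict_pipeline <- function(fp, age) {
  drop(outer((age - fp$center) / fp$scale, 0:fp$degree, `^`) %*% fp$coef_scaled)
}

#' Fit a polynomial age trend with two-pass outlier rejection
#'
#' Runs the full quality-control and fitting pipeline for one measurement
#' key: Tukey-fence rejection on the raw values, a provisional
#' degree-selected polynomial fit, the same rejection on its residues, and a
#' final degree-selected fit on the doubly cleaned data. Residues are
#' computed against the final fit for all points (kept and rejected), and
#' rejected points retain their metadata so measurement-error and artifact
#' models can be estimated later.
#'
#' @param ages Ages in years.
#' @param values Measured values, native units.
#' @param alpha_fit Level of the stepwise degree-selection F-test.
#' @param meta Optional data frame (one row per point) with identification
#'   columns (`subject_id`, `visit_id`, `sex`, `scanner_model`, `sequence`,
#'   ...) carried into the stored residues.
#' @return A `morph_trend` object, or `NULL` (with a warning) when fewer
#'   than 4 finite values are available. Fields include the selected
#'   `degree`, `coefficients` in natural age units, `n_kept`, rejection
#'   counts and bounds, `sigma_norm_all` (SD of kept residues), and a `data`
#'   tibble of per-point residues.
#' @export
fit_age_trend <- function(ages, values, alpha_fit = 0.05, meta = NULL) {
  fp <- fit_pipeline(ages, values, alpha_fit)
  if (is.null(fp)) {
    warn("Too few values to fit an age trend: key skipped")
    return(NULL)
  }
  data <- tibble::tibble(
    age = fp$ages, value = fp$values, residue = fp$residues, kept = fp$kept
  )
  if (!is.null(meta)) {
    data <- dplyr::bind_cols(
      tibble::as_tibble(meta)[fp$idx, , drop = FALSE], data)
  }
  structure(list(
    degree = as.integer(fp$degree),
    coefficients = natural_coeffs(fp$coef_scaled, fp$center, fp$scale),
    center = fp$center, scale = fp$scale, coef_scaled = fp$coef_scaled,
    R = fp$R, sigma2 = fp$sigma2, df_resid = fp$df_resid,
    n_kept = fp$n_kept,
    n_rejected_raw = fp$n_rejected_raw,
    n_rejected_residual = fp$n_rejected_residual,
    bounds_raw = fp$bounds_raw, bounds_residual = fp$bounds_residual,
    sigma_norm_all = fp$sigma_norm_all,
    age_range = fp$age_range,
    alpha_fit = alpha_fit,
    data = data
  ), class = "morph_trend")
}

#' Evaluate a fitted age trend
#'
#' Evaluates the polynomial and a pointwise 95% confidence band (from the
#' coefficient covariance of the final fit) at the requested ages. Ages
#' outside the control age range are evaluated but flagged as extrapolated:
#' polynomial extrapolation loses reliability quickly outside the covered
#' range.
#'
#' @param model A `morph_trend` from [fit_age_trend()].
#' @param age Ages (years) at which to evaluate.
#' @return Tibble with columns `age`, `fit`, `ci_halfwidth`, `extrapolated`.
#' @export
evaluate_trend <- function(model, age) {
  stopifnot(inherits(model, "morph_trend"))
  z <- (age - model$center) / model$scale
  X <- outer(z, 0:model$degree, `^`)
  fit <- drop(X %*% model$coef_scaled)
  ci <- rep(NA_real_, length(age))
  if (is.finite(model$sigma2) && model$df_resid > 0) {
    V <- chol2inv(model$R)
    lev <- rowSums((X %*% V) * X)
    ci <- qt(0.975, model$df_resid) * sqrt(model$sigma2 * lev)
  }
  extrapolated <- age < model$age_range[1] | age > model$age_range[2]
  if (any(extrapolated)) {
    warn("Evaluating the age trend outside the control age range (extrapolation)")
  }
  tibble::tibble(age = age, fit = fit, ci_halfwidth = ci,
                 extrapolated = extrapolated)
}

#' @export
predict.morph_trend <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$age)) newdata <- newdata$age
  z <- (newdata - object$center) / object$scale
  drop(outer(z, 0:object$degree, `^`) %*% object$coef_scaled)
}

#' @export
print.morph_trend <- function(x, ...) {
  cat("<morph_trend> degree", x$degree, "| n_kept", x$n_kept,
      "| rejected", x$n_rejected_raw, "raw +", x$n_rejected_residual,
      "residual | sigma_norm", signif(x$sigma_norm_all, 4), "\n")
  invisible(x)
}
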