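# Leave-one-out cross-validation of anomaly rates in the control cohort.
# Every held-out subject is removed with ALL of their visits (subject-level
# LOO, so repeat scans cannot self-match), the per-key age trends and all
# downstream statistics are refitted on the remainder, and the held-out
# visits are scored exactly like patient visits. Anomaly counts per variant
# and significance level are compared with the nominal level (and optionally
# with empirical reference rates) by exact binomial tests.
#
# The eTIV reference and contrast factors are computed once from the full
# control set: both are per-key multiplicative scales under which z-scores
# and p-values are exactly invariant, so they cannot leak the held-out
# subject into any reported statistic.

#' Exact binomial test of an anomaly rate
#'
#' Two-sided exact binomial test (point-probability ordering) of whether
#' `count` anomalies in `n_tests` tests are consistent with rate `rate0`.
#'
#' @param count Observed anomaly count.
#' @param n_tests Number of tests.
#' @param rate0 Null rate in (0, 1).
#' @return Two-sided p-value.
#' @export
binomial_rate_test <- function(count, n_tests, rate0) {
  if (count < 0 || count > n_tests) abort("Need 0 <= count <= n_tests")
  if (rate0 <= 0 || rate0 >= 1) abort("rate0 must be in (0, 1)")
  binom.test(count, n_tests, rate0)$p.value
}

# Precompute per-key column vectors for the LOOCV loop.
prepare_loocv_keys <- function(data, variants, alpha_fit) {
  hc <- dplyr::filter(data, .data$group == "control")
  visits <- dplyr::distinct(hc, .data$subject_id, .data$visit_id,
                            .keep_all = TRUE)
  etiv_ref <- mean(visits$etiv)
  contrast_ref <- build_contrast_ref(hc)
  full <- suppressWarnings(
    derive_variant_table(hc, variants, etiv_ref, contrast_ref))
  full$.key <- key_id(full$region, full$hemisphere, full$parameter,
                      full$variant)
  idx <- split(seq_len(nrow(full)), full$.key)
  keys <- lapply(idx, function(i) {
    d <- full[i, , drop = FALSE]
    multi <- names(which(table(d$subject_id) >= 2))
    list(
      variant = d$variant[1],
      age = d$age, value = d$value, subject = d$subject_id,
      visit = d$visit_id, sex = d$sex, scanner = d$scanner_model,
      sequence = d$sequence,
      repeat_rows = which(d$subject_id %in% multi)
    )
  })
  list(keys = keys, subjects = unique(hc$subject_id))
}

# Score all visits of one held-out subject for one key; returns a data frame
# of tests (possibly zero rows).
loocv_score_key <- function(kd, subj, alpha_fit, n_min) {
  held <- which(kd$subject == subj)
  if (length(held) == 0) return(NULL)
  mask <- kd$subject != subj
  fp <- fit_pipeline(kd$age[mask], kd$value[mask], alpha_fit)
  if (is.null(fp)) return(NULL)
  # map pipeline results back to masked row positions
  midx <- which(mask)[fp$idx]
  kept_rows <- midx[fp$kept]
  res_kept <- fp$residues[fp$kept]

  rel_rows <- intersect(kept_rows, kd$repeat_rows)
  sigma_meas <- if (length(rel_rows) >= 2) {
    pos <- match(rel_rows, kept_rows)
    estimate_sigma_meas(res_kept[pos], kd$subject[rel_rows],
                        kd$age[rel_rows])$sigma_meas
  } else 0

  out <- vector("list", length(held))
  for (j in seq_along(held)) {
    h <- held[j]
    if (!is.finite(kd$value[h])) next
    sel <- kd$sex[kept_rows] == kd$sex[h] &
      kd$scanner[kept_rows] == kd$scanner[h] &
      kd$sequence[kept_rows] == kd$sequence[h]
    x <- res_kept[sel]
    if (length(x) < n_min) next
    sn <- sd(x)
    if (!is.finite(sn) || sn <= 0) next
    resid <- kd$value[h] - predict_pipeline(fp, kd$age[h])
    out[[j]] <- data.frame(
      visit = kd$visit[h],
      p_ucor = visit_pvalue(resid, mean(x), sn, sigma_meas, "toward"),
      p_two = visit_pvalue(resid, mean(x), sn, sigma_meas, "two_sided")
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Leave-one-out cross-validation of anomaly rates
#'
#' Holds out each test subject in turn (all of their visits), rebuilds the
#' normative statistics on the remaining controls — age-trend refit with
#' two-pass outlier rejection, matched-subset statistics, measurement-error
#' estimate — and scores the held-out visits like patient visits. The
#' fraction of tests with two-sided `p < alpha` is the empirical anomaly
#' rate; under a well-calibrated pipeline on Gaussian data it should be
#' close to `alpha`.
#'
#' @param data Long measurement table joined with metadata; controls only.
#' @param test_subjects Character vector of held-out subjects; when `NULL`,
#'   `n_test_subjects` are sampled at random (set the RNG seed for
#'   reproducibility).
#' @param n_test_subjects Number of subjects to sample when `test_subjects`
#'   is `NULL` (default 34, a ~10% subset of the reference-sized cohort).
#' @param alphas Significance levels to evaluate (default the pipeline's
#'   two printed levels 0.01 and 0.05).
#' @param variants Variants to test.
#' @param alpha_fit Degree-selection level of the refits.
#' @param n_min Minimal matched-control count per test.
#' @param reference_rates Optional tibble `variant, alpha, rate` of
#'   empirical reference rates (e.g. from a previous random-subset run); a
#'   second binomial test against them is then reported.
#' @return A `loocv_report` tibble: one row per variant x alpha with test
#'   counts, uncorrected and FDR-corrected anomaly counts and rates, and
#'   binomial p-values against the nominal (and optionally empirical)
#'   rates. The per-test table is attached as attribute `"tests"`.
#' @export
loocv_assess <- function(data, test_subjects = NULL, n_test_subjects = 34,
                         alphas = c(0.01, 0.05), variants = "raw",
                         alpha_fit = 0.05, n_min = 10,
                         reference_rates = NULL) {
  prep <- prepare_loocv_keys(data, variants, alpha_fit)
  if (is.null(test_subjects)) {
    if (n_test_subjects > length(prep$subjects)) {
      abort("n_test_subjects exceeds the number of control subjects")
    }
    test_subjects <- sample(prep$subjects, n_test_subjects)
  } else {
    missing_subj <- setdiff(test_subjects, prep$subjects)
    if (length(missing_subj) > 0) {
      abort(paste0("Test subject(s) not in the control set: ",
                   paste(missing_subj, collapse = ", ")))
    }
  }

  tests <- vector("list", length(test_subjects))
  for (i in seq_along(test_subjects)) {
    subj <- test_subjects[i]
    per_key <- lapply(names(prep$keys), function(kid) {
      r <- loocv_score_key(prep$keys[[kid]], subj, alpha_fit, n_min)
      if (is.null(r)) return(NULL)
      r$key <- kid
      r$variant <- prep$keys[[kid]]$variant
      r
    })
    per_key <- per_key[!vapply(per_key, is.null, logical(1))]
    if (length(per_key) == 0) next
    d <- do.call(rbind, per_key)
    d$subject <- subj
    tests[[i]] <- d
  }
  tests <- do.call(rbind, tests[!vapply(tests, is.null, logical(1))])
  if (is.null(tests) || nrow(tests) == 0) {
    abort("No LOOCV tests could be performed")
  }

  # FDR family: all keys x variants of one held-out visit
  visit_id <- paste(tests$subject, tests$visit, sep = ":")
  rows <- list()
  for (a in alphas) {
    flag_fdr <- logical(nrow(tests))
    for (ii in split(seq_len(nrow(tests)), visit_id)) {
      flag_fdr[ii] <- fdr_flags(tests$p_two[ii], a)
    }
    for (v in unique(tests$variant)) {
      sel <- tests$variant == v
      n <- sum(sel)
      n_unc <- sum(tests$p_two[sel] < a)
      n_fdr <- sum(flag_fdr[sel])
      rr <- NA_real_
      p_emp <- NA_real_
      if (!is.null(reference_rates)) {
        m <- reference_rates$variant == v &
          abs(reference_rates$alpha - a) < 1e-12
        if (any(m)) {
          rr <- reference_rates$rate[which(m)[1]]
          if (rr > 0 && rr < 1) p_emp <- binomial_rate_test(n_unc, n, rr)
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = v, alpha = a, test_count = n,
        n_uncorrected = n_unc, n_fdr = n_fdr,
        rate_uncorrected = n_unc / n, rate_fdr = n_fdr / n,
        p_binomial_nominal = binomial_rate_test(n_unc, n, a),
        rate_reference = rr, p_binomial_empirical = p_emp
      )
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "tests") <- tibble::as_tibble(tests)
  attr(report, "test_subjects") <- test_subjects
  class(report) <- c("loocv_report", class(tibble::tibble()))
  report
}
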