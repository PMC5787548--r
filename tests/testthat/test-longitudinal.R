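# Linear residue trends, slope uncertainty, consistency and clinical series.

test_that("fit_series matches closed-form OLS on small instances", {
  fs <- fit_series(c(0, 1, 2), c(0, 1, 2))
  expect_equal(fs$a, 1); expect_equal(fs$x0, 0); expect_equal(fs$S2, 0)

  fs2 <- fit_series(c(0, 1, 2), c(0, 2, 0))
  expect_equal(fs2$a, 0)
  expect_equal(fs2$x0, 2 / 3)
  expect_equal(fs2$S2, 8 / 9)

  fs3 <- fit_series(c(1, 4, 9), rep(2.5, 3))
  expect_equal(fs3$a, 0); expect_equal(fs3$x0, 2.5)

  expect_warning(expect_null(fit_series(c(0, 1), c(1, 2))), "skipped")
  expect_error(fit_series(c(1, 1, 1), c(0, 1, 2)), "Zero spread")
})

test_that("slope uncertainty equals the textbook OLS slope SE", {
  # worked example: times {0,1,2}, residues {0,2,0}
  fs <- fit_series(c(0, 1, 2), c(0, 2, 0))
  da <- slope_uncertainty(fs$S2, fs$sigma_t, fs$n)
  expect_equal(da, sqrt(8 / 9) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(da, 1.1547, tolerance = 1e-4)

  expect_equal(slope_uncertainty(0, 1, 5), 0)
  # doubling all time spacings halves delta_a at fixed S2 and n
  expect_equal(slope_uncertainty(2, 2 * 1.5, 8),
               slope_uncertainty(2, 1.5, 8) / 2)

  # algebraic identity on random instances vs brute-force lm() standard error
  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    t <- sort(runif(n, 0, 6))
    x <- 0.3 * t + rnorm(n)
    fs <- fit_series(t, x)
    da <- slope_uncertainty(fs$S2, fs$sigma_t, fs$n)
    se_lm <- summary(lm(x ~ t))$coefficients["t", "Std. Error"]
    expect_equal(da, se_lm, tolerance = 1e-10)
  }
})

test_that("chi-squared consistency test is exact and calibrated", {
  expect_equal(consistency_chi2(0, 1, 5), 1)
  # chi2 upper 5% point with 10 df is 18.307: RSS = n*S2
  expect_equal(consistency_chi2(18.307 / 12, 1, 12), 0.05, tolerance = 1e-4)
  expect_true(is.na(consistency_chi2(1, 0, 5)))

  # null calibration: p uniform for true-linear series with noise sigma_meas
  set.seed(14)
  p <- replicate(2000, {
    t <- 0:7
    x <- 1 - 0.5 * t + rnorm(8, 0, 0.8)
    fs <- fit_series(t, x)
    consistency_chi2(fs$S2, 0.8, fs$n)
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("slope z-test behaves at its edge cases and nominal level", {
  expect_equal(slope_test(0, 1), 1)
  expect_equal(slope_test(1.96, 1), 0.05, tolerance = 1e-3)
  expect_equal(slope_test(-2, 0), 0)   # noiseless injected slope

  # type-I error ~5% and slope estimates unbiased on synthetic series
  set.seed(15)
  res <- replicate(4000, {
    t <- (0:9) * 0.55
    x <- rnorm(10, 0, 1)
    fs <- fit_series(t, x)
    c(fs$a, slope_test(fs$a, slope_uncertainty(fs$S2, fs$sigma_t, fs$n)))
  })
  expect_lt(abs(mean(res[1, ])), 3 * sd(res[1, ]) / sqrt(4000))
  rej <- mean(res[2, ] < 0.05)
  # a z-test on 10 points is mildly anti-conservative: the exact rate is
  # 2 P(t_8 > 1.96) ~ 0.086, approaching 0.05 as the series grows
  expect_equal(rej, 2 * pt(qnorm(0.975), df = 8, lower.tail = FALSE),
               tolerance = 0.15)
  set.seed(18)
  rej_long <- mean(replicate(2000, {
    t <- seq_len(100)
    x <- rnorm(100)
    fs <- fit_series(t, x)
    slope_test(fs$a, slope_uncertainty(fs$S2, fs$sigma_t, fs$n)) < 0.05
  }))
  expect_equal(rej_long, 0.05, tolerance = 0.25)
})

test_that("Welch test handles degenerate groups and holds its level", {
  expect_equal(mean_position_test(c(1, 1), c(1, 1)), 1)
  expect_lt(mean_position_test(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6),
                               c(5, 5, 5, 5) + rnorm(4, 0, 1e-6)), 1e-3)
  set.seed(16)
  rej <- mean(replicate(4000, {
    mean_position_test(rnorm(8), rnorm(40, 0, 3)) < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.25)
})

test_that("series outlier rejection uses the series' own fences", {
  expect_equal(series_outlier_rejection(c(0.1, 0, -0.1, 0.05)), 1:4)
  expect_equal(series_outlier_rejection(c(0.1, 0, -0.1, 50)), 1:3)
  expect_equal(series_outlier_rejection(c(0.1, 0, -0.1, 0.05),
                                        manual_exclude = 3L),
               c(1L, 2L, 4L))
  expect_warning(
    expect_null(series_outlier_rejection(c(0.1, 0, -0.1, 50),
                                         manual_exclude = c(1L, 2L))),
    "skipped")
})

test_that("clinical trends: rho extremes and exact tied-permutation p", {
  up <- clinical_trend(1:5, c(1, 2, 4, 8, 9))
  expect_equal(up$spearman_rho, 1)

  flat <- clinical_trend(1:5, rep(2, 5))
  expect_equal(flat$annual_rate, 0)
  expect_true(is.na(flat$spearman_rho))
  expect_equal(flat$p_rate, 1)

  # tied ordinal scores: brute-force permutation oracle (independent code)
  t <- 1:6
  s <- c(2, 2, 2, 3, 3, 4)
  got <- clinical_trend(t, s)
  rt <- rank(t); rs <- rank(s)
  rho_obs <- cor(rt, rs)
  perms <- gtools_permutations <- NULL
  # enumerate all 720 orderings by recursion
  enum <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enum(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(enum(rs), function(p) cor(rt, p), numeric(1))
  p_oracle <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(got$spearman_rho, rho_obs)
  expect_equal(got$p_spearman, p_oracle)

  expect_error(clinical_trend(c(1, 1, 2), c(1, 2, 3)), "increasing")
})

test_that("series invariances: shifts move only the intercept", {
  set.seed(17)
  t <- sort(runif(6, 0, 4))
  x <- 0.7 * t + rnorm(6)
  a <- fit_series(t, x)
  b <- fit_series(t, x + 5)          # constant residue shift
  c2 <- fit_series(t + 10, x)        # time origin shift
  expect_equal(b$a, a$a); expect_equal(b$x0, a$x0 + 5)
  expect_equal(c2$a, a$a); expect_equal(c2$S2, a$S2)
  da <- slope_uncertainty(a$S2, a$sigma_t, a$n)
  expect_equal(slope_uncertainty(c2$S2, c2$sigma_t, c2$n), da)
})

test_that("assess_series recovers injected slopes and honours exclusions", {
  sim <- small_cohort(n_subjects = 80, n_keys = 4, seed = 19,
                      sigma_meas_true = 0.3)
  db <- quiet(build_normative_db(joined_cohort(sim), variants = "raw"))
  kid <- key_id("roi001", "left", "volume", "raw")
  pcfg <- patient_series_config(
    n_visits = 10, slope_true = setNames(-2, kid),
    sigma_meas_true = 0.3, scanner_model = "Verio", sequence = "MDEFT",
    seed = 4)
  pat <- simulate_patient_series(pcfg, sim$truth)
  pj <- join_metadata(pat$table, pat$meta)
  sa <- quiet(assess_series(db, pj, alpha = 0.05, n_min = 10))
  row <- sa[sa$key == kid, ]
  expect_equal(row$slope, -2, tolerance = 0.35)
  expect_lt(row$p_slope, 1e-4)
  expect_equal(as.character(row$highlight), "red")
  # the injected key dominates every other slope test by a wide margin
  others <- sa[sa$key != kid, ]
  expect_gt(min(others$p_slope, na.rm = TRUE), 1e3 * row$p_slope)

  # manual exclusion reduces the used visit count
  excl <- tibble::tibble(key = kid, visit_id = "T03")
  sa2 <- quiet(assess_series(db, pj, alpha = 0.05, n_min = 10,
                             exclusions = excl))
  expect_equal(sa2$n_used[sa2$key == kid], row$n_used - 1L)

  expect_error(assess_series(db, dplyr::filter(pj, visit_id %in%
                                                 c("T01", "T02"))),
               "at least 3")
})
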