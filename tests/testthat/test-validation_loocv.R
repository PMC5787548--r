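# Leave-one-out cross-validation machinery and binomial rate tests.

test_that("binomial rate test matches a full-pmf enumeration oracle", {
  # oracle: two-sided point-probability ordering, summed over the whole pmf
  oracle <- function(k, n, p0) {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
  }
  expect_equal(binomial_rate_test(0, 100, 0.01), oracle(0, 100, 0.01))
  expect_equal(binomial_rate_test(7, 100, 0.05), oracle(7, 100, 0.05))
  expect_equal(binomial_rate_test(3, 40, 0.2), oracle(3, 40, 0.2))

  # count at the exact expectation: maximal p
  expect_equal(binomial_rate_test(5, 100, 0.05), 1, tolerance = 0.1)
  expect_gte(binomial_rate_test(5, 100, 0.05),
             max(binomial_rate_test(4, 100, 0.05),
                 binomial_rate_test(6, 100, 0.05)))

  # the reported reference count is astronomically incompatible with 1%:
  # 1,088 anomalies in 67,558 tests prints as p = 0 to machine precision
  expect_equal(binomial_rate_test(1088, 67558, 0.01), 0)
})

test_that("LOOCV never leaks the held-out subject (dual-route check)", {
  sim <- small_cohort(n_subjects = 40, n_keys = 3, seed = 29,
                      sigma_meas_true = 0.3)
  joined <- joined_cohort(sim)
  subjects <- unique(joined$subject_id)
  held <- subjects[c(3, 11)]

  rep <- quiet(loocv_assess(joined, test_subjects = held,
                            alphas = 0.05, variants = "raw", n_min = 5))
  tests <- attr(rep, "tests")

  # independent route: rebuild the database without the subject via the main
  # builder and score their visit with assess_visit()
  for (s in held) {
    rest <- dplyr::filter(joined, .data$subject_id != s)
    db <- quiet(build_normative_db(rest, variants = "raw"))
    for (v in unique(joined$visit_id[joined$subject_id == s])) {
      pd <- dplyr::filter(joined, .data$subject_id == s, .data$visit_id == v)
      va <- quiet(assess_visit(db, pd, alpha = 0.05, n_min = 5))
      for (k in va$key[!is.na(va$p_ucor)]) {
        lean <- tests[tests$subject == s & tests$visit == v &
                        tests$key == k, ]
        expect_equal(lean$p_ucor, va$p_ucor[va$key == k], tolerance = 1e-12)
        expect_equal(lean$p_two, va$p_two[va$key == k], tolerance = 1e-12)
      }
    }
  }
})

test_that("FDR-corrected counts never exceed uncorrected counts", {
  sim <- small_cohort(n_subjects = 50, n_keys = 5, seed = 31,
                      sigma_meas_true = 0.2)
  rep <- quiet(loocv_assess(joined_cohort(sim), n_test_subjects = 6,
                            alphas = c(0.01, 0.05), variants = "raw",
                            n_min = 5))
  expect_true(all(rep$n_fdr <= rep$n_uncorrected))
  expect_true(all(rep$rate_uncorrected == rep$n_uncorrected / rep$test_count))
})

test_that("heavy-tailed residues inflate the anomaly rate above nominal", {
  cfg <- cohort_config(
    n_subjects = 150, n_repeat_subjects = 10,
    keys = synthetic_keys(30, "volume"),
    scanner_sequence_mix = c("Verio:MPRAGE_vdK" = 1),
    sigma_meas_true = 0, artifact_fraction = 0,
    sex_offset_sd = 0, group_offset_sd = 0,
    residue_df = 5, trend_degrees = 1, seed = 37)
  sim <- simulate_cohort(cfg)
  set.seed(38)
  rep <- quiet(loocv_assess(joined_cohort(sim), n_test_subjects = 15,
                            alphas = 0.01, variants = "raw"))
  # Student-t(5) tails: the rate must sit clearly above 1%
  expect_gt(rep$rate_uncorrected, 0.02)
  expect_lt(rep$p_binomial_nominal, 0.001)
})

test_that("empirical reference rates feed the second binomial test", {
  sim <- small_cohort(n_subjects = 40, n_keys = 3, seed = 41,
                      sigma_meas_true = 0.2)
  ref <- tibble::tibble(variant = "raw", alpha = 0.05, rate = 0.06)
  rep <- quiet(loocv_assess(joined_cohort(sim), n_test_subjects = 5,
                            alphas = 0.05, variants = "raw", n_min = 5,
                            reference_rates = ref))
  expect_equal(rep$rate_reference, 0.06)
  expect_false(is.na(rep$p_binomial_empirical))
  expect_equal(rep$p_binomial_empirical,
               binomial_rate_test(rep$n_uncorrected, rep$test_count, 0.06))
})
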