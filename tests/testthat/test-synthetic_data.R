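# Ground-truth recovery and determinism of the generators.

test_that("identical config and seed give bit-identical output", {
  cfg <- cohort_config(n_subjects = 30, n_repeat_subjects = 5,
                       keys = synthetic_keys(2), seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$meta, b$meta)
})

test_that("noiseless repeats are identical within subject", {
  cfg <- cohort_config(n_subjects = 20, n_repeat_subjects = 10,
                       keys = synthetic_keys(2), sigma_meas_true = 0,
                       artifact_fraction = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  # repeat visits differ only through the age trend; residues vs the true
  # trend are exactly the shared subject effect
  truth <- sim$truth
  joined <- joined_cohort(sim)
  joined$kid <- key_id(joined$region, joined$hemisphere, joined$parameter,
                       "raw")
  joined$resid_true <- joined$value - mapply(
    function(k, a) normorph:::eval_poly(truth$trend_coeffs[[k]], a),
    joined$kid, joined$age)
  per <- dplyr::summarise(
    joined, spread = diff(range(.data$resid_true)),
    n = dplyr::n(), .by = c("subject_id", "kid"))
  expect_true(all(per$spread[per$n == 2] < 1e-9))
})

test_that("generated residue spread matches the configured SD", {
  cfg <- cohort_config(n_subjects = 323, keys = synthetic_keys(8),
                       sigma_norm_true = 2, sigma_meas_true = 0,
                       artifact_fraction = 0, sex_offset_sd = 0,
                       group_offset_sd = 0, seed = 99)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  tab <- sim$table
  tab$kid <- key_id(tab$region, tab$hemisphere, tab$parameter, "raw")
  tab <- dplyr::left_join(tab, sim$meta, by = c("subject_id", "visit_id"))
  tab$resid <- tab$value - mapply(
    function(k, a) normorph:::eval_poly(truth$trend_coeffs[[k]], a),
    tab$kid, tab$age)
  one_per_subject <- tab[!duplicated(paste(tab$subject_id, tab$kid)), ]
  expect_equal(sd(one_per_subject$resid), 2, tolerance = 0.05)
})

test_that("flagged artifact measurements have the wide marginal SD", {
  cfg <- cohort_config(n_subjects = 323, keys = synthetic_keys(10),
                       artifact_fraction = 0.2, artifact_sigma_true = 8,
                       sigma_meas_true = 0, sex_offset_sd = 0,
                       group_offset_sd = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  tab <- dplyr::left_join(sim$table, sim$meta,
                          by = c("subject_id", "visit_id"))
  tab$kid <- key_id(tab$region, tab$hemisphere, tab$parameter, "raw")
  tab$resid <- tab$value - mapply(
    function(k, a) normorph:::eval_poly(truth$trend_coeffs[[k]], a),
    tab$kid, tab$age)
  art <- truth$artifact_flags$artifact
  expect_lt(abs(mean(art) - 0.2), 0.02)
  expect_lt(abs(sd(tab$resid[art]) - 8), 0.4)
  expect_lt(abs(sd(tab$resid[!art]) - 1), 0.05)
})

test_that("patient series recovers injected slopes", {
  sim <- small_cohort(n_subjects = 20, n_keys = 1, seed = 3)
  kid <- key_id(sim$truth$keys$region, sim$truth$keys$hemisphere,
                sim$truth$keys$parameter, "raw")

  # noiseless identity: injected slope -2 recovered exactly
  pcfg <- patient_series_config(n_visits = 10, slope_true = -2,
                                sigma_meas_true = 0, seed = 1)
  pat <- simulate_patient_series(pcfg, sim$truth)
  d <- dplyr::filter(pat$table, .data$region == sim$truth$keys$region[1],
                     .data$hemisphere == sim$truth$keys$hemisphere[1])
  t_rel <- pat$truth$times
  resid <- d$value - normorph:::eval_poly(
    sim$truth$trend_coeffs[[kid[1]]], pat$meta$age)
  fs <- fit_series(t_rel, resid)
  expect_equal(fs$a, -2, tolerance = 1e-10)
  expect_equal(fs$S2, 0, tolerance = 1e-18)

  # noiseless zero slope stays exactly zero
  pat0 <- simulate_patient_series(
    patient_series_config(n_visits = 5, slope_true = 0,
                          sigma_meas_true = 0, seed = 2), sim$truth)
  d0 <- dplyr::filter(pat0$table, .data$region == sim$truth$keys$region[1],
                      .data$hemisphere == sim$truth$keys$hemisphere[1])
  r0 <- d0$value - normorph:::eval_poly(
    sim$truth$trend_coeffs[[kid[1]]], pat0$meta$age)
  expect_equal(fit_series(pat0$truth$times, r0)$a, 0, tolerance = 1e-10)

  # parameter recovery under noise: mean recovered slope within MC CI of -2
  slopes <- vapply(1:500, function(s) {
    p <- simulate_patient_series(
      patient_series_config(n_visits = 10, slope_true = -2,
                            sigma_meas_true = 1, seed = s), sim$truth)
    dd <- dplyr::filter(p$table, .data$region == sim$truth$keys$region[1],
                        .data$hemisphere == sim$truth$keys$hemisphere[1])
    rr <- dd$value - normorph:::eval_poly(
      sim$truth$trend_coeffs[[kid[1]]], p$meta$age)
    fit_series(p$truth$times, rr)$a
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) + 2), 3 * se)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(age_range = c(30, 30)), "age range")
  expect_error(cohort_config(artifact_fraction = 0.6), "artifact_fraction")
  expect_error(cohort_config(artifact_sigma_true = 0.5), "exceed")
  expect_error(patient_series_config(n_visits = 2), "n_visits")
})
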