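# Matched subsets, tail p-values, FDR, highlighting and feature vectors.

test_that("visit p-values follow the variance-addition tail formula", {
  # at the mean: no evidence
  expect_equal(visit_pvalue(0, 0, 1, 0), 0.5)
  # 3-4-5 variance addition: sigma = 5, z = 1
  expect_equal(visit_pvalue(5, 0, 3, 4), 1 - pnorm(1), tolerance = 1e-12)
  expect_equal(visit_pvalue(5, 0, 3, 4), 0.1587, tolerance = 1e-3)
  # normal 5% quantile below the mean
  expect_equal(visit_pvalue(-1.6449, 0, 1, 0), 0.05, tolerance = 1e-4)
  expect_error(visit_pvalue(1, 0, 0, 0), "sigma_norm")
})

test_that("tail conventions: symmetry, uniformity and monotonicity", {
  deltas <- c(0.1, 0.7, 1.3, 2.9)
  # upper-tail symmetry identity p(+d) + p(-d) = 1
  up <- visit_pvalue(1 + deltas, 1, 2, 1, tail = "upper") +
    visit_pvalue(1 - deltas, 1, 2, 1, tail = "upper")
  expect_equal(up, rep(1, length(deltas)), tolerance = 1e-12)
  # the folded Eq-style tail is symmetric about the mean
  expect_equal(visit_pvalue(1 + deltas, 1, 2, 1),
               visit_pvalue(1 - deltas, 1, 2, 1))
  # and equals half the two-sided significance p
  expect_equal(2 * visit_pvalue(1 + deltas, 1, 2, 1),
               visit_pvalue(1 + deltas, 1, 2, 1, tail = "two_sided"))

  # calibration: two-sided p is Uniform(0,1) for draws from the normative
  # distribution with measurement noise (KS at 1% on 1e4 draws)
  set.seed(3)
  sn <- 1.5; sm <- 0.9
  x <- rnorm(1e4, 0, sqrt(sn^2 + sm^2))
  p2 <- visit_pvalue(x, 0, sn, sm, tail = "two_sided")
  ks <- suppressWarnings(ks.test(p2, "punif"))
  expect_gt(ks$p.value, 0.01)

  # increasing sigma_meas moves every p strictly toward 0.5
  p_lo <- visit_pvalue(c(-3, -1, 0.5, 2, 4), 0, 1, 0)
  p_hi <- visit_pvalue(c(-3, -1, 0.5, 2, 4), 0, 1, 2)
  expect_true(all(p_hi > p_lo))
  expect_true(all(p_hi <= 0.5))
})

test_that("BH step-up flags match the worked thresholds", {
  expect_equal(fdr_flags(c(0.001, 0.02, 0.03, 0.04), 0.05),
               rep(TRUE, 4))   # thresholds i*alpha/m = .0125,.025,.0375,.05
  expect_equal(fdr_flags(rep(0.5, 6), 0.05), rep(FALSE, 6))
  expect_true(fdr_flags(0.04, 0.05))    # m = 1
  # FDR flags never exceed uncorrected flags
  set.seed(4)
  p <- runif(200)^2
  expect_true(sum(fdr_flags(p, 0.05)) <= sum(p < 0.05))
})

test_that("highlight levels follow the yellow/red convention", {
  expect_equal(as.character(highlight_level(0.2, FALSE, 0.05)), "none")
  expect_equal(as.character(highlight_level(0.004, FALSE, 0.01)), "yellow")
  expect_equal(as.character(highlight_level(0.0001, TRUE, 0.01)), "red")
})

test_that("matched subsets filter on sex, scanner and sequence exactly", {
  resid <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:15), visit_id = "v1",
    sex = c(rep("F", 10), rep("M", 5)),
    scanner_model = "Verio", sequence = "MPRAGE",
    age = 30, value = 0, residue = rnorm(15), kept = TRUE
  )
  entry <- list(key = "k", residues = resid)
  pm <- list(sex = "F", scanner_model = "Verio", sequence = "MPRAGE")
  m <- match_controls(entry, pm, n_min = 10)
  expect_equal(m$n_matched, 10)
  expect_equal(m$x_norm, mean(resid$residue[1:10]))

  pm2 <- list(sex = "F", scanner_model = "Verio", sequence = "OTHER")
  expect_warning(expect_null(match_controls(entry, pm2, n_min = 10)),
                 "Insufficient matched")

  # all controls matching -> subset is the full kept residue set
  resid$sex <- "F"
  m3 <- match_controls(list(key = "k", residues = resid), pm, n_min = 10)
  expect_equal(m3$n_matched, 15)
})

test_that("feature vectors are signed log p-values with exact antisymmetry", {
  a <- tibble::tibble(key = c("k1", "k2", "k3"),
                      residue = c(2, -3, 0), x_norm = 0,
                      p_ucor = c(0.01, 0.001, 1))
  L <- feature_vector(a)
  expect_equal(unname(L), c(2, -3, 0))

  # reflecting a visit about x_norm negates L exactly
  x <- c(-2.3, -0.4, 1.1, 3.7)
  p_plus <- visit_pvalue(x, 0, 1, 0.5)
  p_minus <- visit_pvalue(-x, 0, 1, 0.5)
  L_plus <- -sign(x) * log10(p_plus)
  L_minus <- -sign(-x) * log10(p_minus)
  expect_equal(L_minus, -L_plus)
})

test_that("feature correlation matrices behave at the null and the extremes", {
  set.seed(5)
  v <- rnorm(500)
  expect_equal(feature_correlation_matrix(cbind(a = v, b = v))["a", "b"], 1)
  expect_equal(feature_correlation_matrix(cbind(a = v, b = -v))["a", "b"], -1)

  # null correlations of independent vectors: E|r| ~ sqrt(2/pi)/sqrt(n)
  m <- matrix(rnorm(2976 * 15), nrow = 2976)
  r <- feature_correlation_matrix(m)
  offdiag <- abs(r[upper.tri(r)])
  expect_equal(mean(offdiag), sqrt(2 / pi) / sqrt(2976), tolerance = 0.2)

  # too few shared entries -> NA cell
  x <- c(1, 2, NA, NA, NA)
  y <- c(NA, NA, 1, 2, 3)
  r2 <- feature_correlation_matrix(cbind(x, y, z = 1:5))
  expect_true(is.na(r2["x", "y"]))
})

test_that("assess_visit flags an injected +5 sigma anomaly red", {
  sim <- small_cohort(n_subjects = 80, n_keys = 6, seed = 13,
                      sigma_meas_true = 0.2)
  db <- quiet(build_normative_db(joined_cohort(sim), variants = "raw"))
  pat <- simulate_patient_series(
    patient_series_config(n_visits = 3, sigma_meas_true = 0,
                          scanner_model = "Verio", sequence = "MDEFT",
                          seed = 2),
    sim$truth)
  pj <- join_metadata(pat$table, pat$meta)
  v1 <- dplyr::filter(pj, visit_id == "T01")
  # inject a gross anomaly into one key
  hit <- v1$region == "roi001" & v1$hemisphere == "left"
  sigma_true <- sim$truth$sigma_norm_true
  v1$value[hit] <- v1$value[hit] + 8 * sigma_true
  va <- quiet(assess_visit(db, v1, alpha = 0.05, n_min = 10))
  hit_key <- key_id("roi001", "left", v1$parameter[hit][1], "raw")
  row <- va[va$key == hit_key, ]
  expect_equal(as.character(row$highlight), "red")
  expect_gt(row$L, 3)
  # empty patient table errors
  expect_error(assess_visit(db, v1[0, ]), "Empty")
})
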