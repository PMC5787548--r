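# Shared fixtures built in code. Small cohorts keep module tests fast; the
# acceptance tests build the full-size world themselves.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

small_cohort <- function(n_subjects = 60, n_keys = 4, seed = 1,
                         parameters = "volume", ...) {
  cfg <- cohort_config(
    n_subjects = n_subjects,
    n_repeat_subjects = min(8, n_subjects %/% 5),
    keys = synthetic_keys(n_keys, parameters),
    scanner_sequence_mix = c("Verio:MDEFT" = 0.5, "Verio:MPRAGE_vdK" = 0.5),
    seed = seed, ...
  )
  simulate_cohort(cfg)
}

joined_cohort <- function(sim) join_metadata(sim$table, sim$meta)

write_long_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# minimal valid metadata row set for hand-built tables
meta_fixture <- function(subject_id, visit_id, age = 30, sex = "F",
                         scanner = "Verio", sequence = "MPRAGE_vdK",
                         etiv = 1.5e6, group = "control") {
  tibble::tibble(
    subject_id = subject_id, visit_id = visit_id, age = age, sex = sex,
    scanner_model = scanner, sequence = sequence, etiv = etiv, group = group
  )
}
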