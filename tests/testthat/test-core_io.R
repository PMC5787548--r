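# Reading/writing measurement tables and metadata, and database persistence.

test_that("long_csv round-trips with record counts and values preserved", {
  tab <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 4),
    visit_id = "v1",
    region = rep(c("roi1", "roi1", "roi2", "roi2"), 2),
    hemisphere = rep(c("left", "right"), 4),
    parameter = "volume",
    value = c(1.25, 2.5, 3.125, exp(1), pi, 6.75, 7.0001, 1e-8)
  )
  path <- write_long_fixture(tab)
  got <- read_stats_table(path, "long_csv")
  expect_equal(nrow(got), 8)
  expect_equal(got$value, tab$value)

  # unknown extra columns are reported, not silently dropped
  tab2 <- dplyr::mutate(tab, mystery = 1)
  expect_warning(read_stats_table(write_long_fixture(tab2), "long_csv"),
                 "mystery")
})

test_that("missing values are carried as missing, not zero", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,visit_id,region,hemisphere,parameter,value",
    "s1,v1,roi1,left,volume,10",
    "s1,v1,roi2,left,volume,NA"
  ), path)
  got <- read_stats_table(path, "long_csv")
  expect_identical(got$value[2], NA_real_)
  expect_false(any(got$value == 0, na.rm = TRUE))
})

test_that("malformed headers and non-numeric values give located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,visit_id,region,parameter,value",
               "s1,v1,roi1,volume,1"), path)
  expect_error(read_stats_table(path, "long_csv"), "hemisphere")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,visit_id,region,hemisphere,parameter,value",
    "s1,v1,roi1,left,volume,abc"
  ), path2)
  expect_error(read_stats_table(path2, "long_csv"), "value")

  path3 <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,visit_id,region,hemisphere,parameter,value",
    "s1,v1,roi1,left,blood_pressure,7"
  ), path3)
  expect_error(read_stats_table(path3, "long_csv"), "blood_pressure")
})

test_that("freesurfer wide TSV round-trips through the synthetic writer", {
  sim <- small_cohort(n_subjects = 3, n_keys = 3,
                      parameters = c("thickness_mean", "surface_area"))
  tab <- sim$table
  path <- tempfile(fileext = ".tsv")
  write_stats_table(tab, path, "freesurfer_wide_tsv")
  got <- read_stats_table(path, "freesurfer_wide_tsv")
  key_cols <- c("subject_id", "visit_id", "region", "hemisphere", "parameter")
  merged <- dplyr::inner_join(tab, got, by = key_cols,
                              suffix = c("", ".rt"))
  expect_equal(nrow(merged), nrow(tab))   # 3 subjects x n_regions x ...
  expect_equal(merged$value.rt, merged$value)
})

test_that("freesurfer measure aliases are parsed from exporter-style headers", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "lh.aparc.thickness\tlh_bankssts_thickness\tlh_bankssts_thicknessstd\tlh_bankssts_area\tbrainseg_mysterymeasure",
    "subjA:v1\t2.5\t0.4\t1200\t9"
  ), path)
  expect_warning(got <- read_stats_table(path, "freesurfer_wide_tsv"),
                 "mysterymeasure")
  expect_setequal(got$parameter,
                  c("thickness_mean", "thickness_sd", "surface_area"))
  expect_equal(got$subject_id, rep("subjA", 3))
  expect_equal(got$hemisphere, rep("left", 3))
})

test_that("join_metadata attaches all rows and errors on unmatched/duplicate", {
  tab <- tibble::tibble(
    subject_id = c("s1", "s2"), visit_id = "v1", region = "roi1",
    hemisphere = "left", parameter = "volume", value = c(1, 2)
  )
  meta <- meta_fixture(c("s1", "s2"), "v1")
  joined <- join_metadata(tab, meta)
  expect_equal(nrow(joined), 2)
  expect_true(all(c("age", "sex", "etiv", "group") %in% names(joined)))

  expect_error(join_metadata(tab, meta[1, ]), "s2/v1")
  expect_error(join_metadata(tab, dplyr::bind_rows(meta, meta[1, ])),
               "Duplicate")
})

test_that("database save/load round trip is bit-exact and version-checked", {
  sim <- small_cohort(n_subjects = 40, n_keys = 3, seed = 7)
  db <- quiet(build_normative_db(joined_cohort(sim), variants = "raw",
                                 seed = 7L))
  path <- tempfile(fileext = ".rds")
  save_db(db, path)
  db2 <- load_db(path)
  expect_identical(db2, db)   # every residue and coefficient bit-exact
  expect_identical(db2$provenance$seed, 7L)

  # truncated file -> integrity error
  full <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(fileext = ".rds")
  writeBin(full[seq_len(length(full) %/% 2)], trunc)
  expect_error(load_db(trunc), "Integrity")

  # schema version mismatch -> refuse
  db_bad <- db
  db_bad$provenance$schema_version <- 999L
  saveRDS(db_bad, path)
  expect_error(load_db(path), "schema version")
})
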