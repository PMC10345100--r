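test_that("workbook write-then-read is the identity on valid investigations", {
  for (seed in c(21, 22)) {
    fx <- generate_fixture(random_spec(seed))
    d <- withr::local_tempdir()
    write_miappe_workbook(fx$investigation, d)
    rd <- read_miappe_workbook(d)
    expect_equal(rd$investigation, normalize_investigation(fx$investigation))
    expect_true(is_valid_report(rd$report))
  }
})

test_that("all eleven section tabs are emitted, even when empty", {
  d <- withr::local_tempdir()
  write_miappe_workbook(minimal_inv(), d)
  expect_setequal(list.files(d, pattern = "\\.tsv$"), unname(miappe_sections()))
})

test_that("a missing Sample tab is a warning, a missing Investigation tab fatal", {
  fx <- generate_fixture(tiny_spec(23))
  d <- withr::local_tempdir()
  write_miappe_workbook(fx$investigation, d)
  unlink(file.path(d, "sample.tsv"))
  rd <- read_miappe_workbook(d)
  expect_true(any(rd$report$warnings$code == "SECTION_MISSING" &
                    rd$report$warnings$object_id == "Sample"))
  expect_equal(rd$investigation, normalize_investigation(fx$investigation))
  unlink(file.path(d, "investigation.tsv"))
  expect_error(read_miappe_workbook(d), "Investigation")
})

test_that("unknown tabs are reported, not silently ignored", {
  d <- withr::local_tempdir()
  write_miappe_workbook(minimal_inv(), d)
  writeLines("a\tb", file.path(d, "mystery.tsv"))
  rd <- read_miappe_workbook(d)
  expect_true(any(rd$report$warnings$code == "SECTION_UNKNOWN" &
                    rd$report$warnings$object_id == "mystery.tsv"))
})

test_that("writing refuses an investigation with a date-less event", {
  inv <- minimal_inv()
  inv$studies[[1]]$events <- data.frame(
    event_type = "planting", description = "p", date = NA_character_,
    stringsAsFactors = FALSE)
  expect_error(write_miappe_workbook(inv, withr::local_tempdir()),
               "EVT_DATE_MISSING")
})

test_that("observation tables are sparse: one record per non-empty cell", {
  inv <- minimal_inv()
  inv$observed_variables <- rbind(inv$observed_variables, within(
    inv$observed_variables, id <- "v2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("observation_unit_id\tdate\tv1\tv2",
               "u1\t2000-06-01\t4.5\t"), f)
  recs <- read_observation_table(f, inv)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$value, "4.5")

  # full n x k grid gives n*k records
  n <- 7L
  lines <- c("observation_unit_id\tdate\tv1\tv2",
             sprintf("u1\t2000-06-%02d\t%d\t%d", seq_len(n), seq_len(n),
                     seq_len(n) * 10))
  writeLines(lines, f)
  expect_identical(nrow(read_observation_table(f, inv)), n * 2L)
})

test_that("undeclared variable columns and ragged rows are errors", {
  inv <- minimal_inv()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("observation_unit_id\tdate\ttottub", "u1\t2000-06-01\t3"), f)
  expect_error(read_observation_table(f, inv), "tottub")
  writeLines(c("observation_unit_id\tdate\tv1", "u1\t2000-06-01\t3\t9\t9"), f)
  expect_error(read_observation_table(f, inv), "line 2")
})

test_that("configurable NA tokens and duplicate policies behave as documented", {
  inv <- minimal_inv()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("observation_unit_id\tdate\tv1", "u1\t2000-06-01\tNA",
               "u1\t2000-06-02\t-", "u1\t2000-06-03\t5"), f)
  expect_identical(nrow(read_observation_table(f, inv)), 1L)
  expect_identical(nrow(read_observation_table(f, inv, na_tokens = "")), 3L)

  writeLines(c("observation_unit_id\tdate\tv1", "u1\t2000-06-01\t5",
               "u1\t2000-06-01\t6"), f)
  expect_error(read_observation_table(f, inv), "conflicting duplicate")
  expect_identical(read_observation_table(f, inv, on_duplicate = "last")$value, "6")
  expect_identical(read_observation_table(f, inv, on_duplicate = "first")$value, "5")
})

test_that("observation round trip preserves the record multiset and sparsity", {
  for (seed in c(24, 25)) {
    fx <- generate_fixture(random_spec(seed))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_observation_table(fx$records, f, fx$investigation)
    back <- read_observation_table(f, fx$investigation)
    key <- function(d) sort(paste(d$observation_unit_id, d$date, d$variable_id,
                                  d$value, sep = "\r"))
    expect_identical(key(back), key(fx$records))
  }
})

test_that("weather tables: counts, bounds and conflicting duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "station_id\tlatitude\tlongitude\tdate\tdaily_mean_temperature_C\tphotoperiod_hours"
  writeLines(c(hdr, "w1\t52\t5.6\t2000-06-01\t17.2\t16.5"), f)
  wx <- read_weather_table(f)
  expect_identical(nrow(wx$stations), 1L)
  expect_identical(nrow(wx$observations), 2L)

  days <- sprintf("w1\t52\t5.6\t2000-06-%02d\t%s\t%s", 1:30, "15.0", "16.0")
  writeLines(c(hdr, days), f)
  expect_identical(nrow(read_weather_table(f)$observations), 60L)

  writeLines(c(hdr, "w1\t52\t5.6\t2000-06-01\t17.2\t25.0"), f)
  expect_error(read_weather_table(f), "photoperiod")

  writeLines(c(hdr, "w1\t52\t5.6\t2000-06-01\t17.2\t16.5",
               "w1\t52\t5.6\t2000-06-01\t18.0\t16.5"), f)
  expect_error(read_weather_table(f), "conflicting duplicate")
})

test_that("weather round trip preserves stations and readings", {
  fx <- generate_fixture(tiny_spec(26))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weather_table(fx$stations, fx$weather, f)
  wx <- read_weather_table(f)
  expect_equal(wx$observations, fx$weather)
  expect_equal(wx$stations[c("id", "latitude", "longitude")],
               fx$stations[order(fx$stations$id), c("id", "latitude", "longitude")],
               ignore_attr = TRUE)
})
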