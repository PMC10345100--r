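test_that("a fully consistent investigation validates with zero errors", {
  inv <- minimal_inv()
  rep <- validate_investigation(inv, rec_df("u1", "2000-06-01", "v1", "7"))
  expect_true(is_valid_report(rep))
  expect_identical(nrow(rep$errors), 0L)
})

test_that("date-less events are rejected: undated occurrences are factors, not events", {
  inv <- minimal_inv()
  inv$studies[[1]]$events <- data.frame(
    event_type = "planting", description = "planting", date = NA_character_,
    stringsAsFactors = FALSE)
  rep <- validate_investigation(inv)
  expect_true("EVT_DATE_MISSING" %in% rep$errors$code)
  # ...but the same information is representable as an experimental factor
  inv$studies[[1]]$events <- inv$studies[[1]]$events[0, , drop = FALSE]
  inv$studies[[1]]$experimental_factors <- data.frame(
    factor_type = "fertilization", description = "amount known, date unknown",
    values = "120 kg N/ha", stringsAsFactors = FALSE)
  expect_true(is_valid_report(validate_investigation(inv)))
})

test_that("references that do not resolve are reported with their ids", {
  inv <- minimal_inv()
  recs <- rbind(rec_df("u1", "2000-06-01", "tottub", "3"),
                rec_df("ghost", "2000-06-01", "v1", "3"))
  rep <- validate_investigation(inv, recs)
  expect_true(any(rep$errors$code == "REC_VAR_UNKNOWN" &
                    rep$errors$object_id == "tottub"))
  expect_true(any(rep$errors$code == "REC_UNIT_UNKNOWN" &
                    rep$errors$object_id == "ghost"))

  inv2 <- minimal_inv()
  inv2$data_files <- data.frame(path_or_url = "x.tsv", description = "d",
                                study_id = "nope", stringsAsFactors = FALSE)
  expect_true("DF_STUDY_UNKNOWN" %in% validate_investigation(inv2)$errors$code)

  inv3 <- minimal_inv()
  inv3$studies[[1]]$observation_units$biological_material_id <- "missing"
  expect_true("UNIT_MAT_UNKNOWN" %in% validate_investigation(inv3)$errors$code)
})

test_that("structural rules: duplicates, coordinates, date order, nesting", {
  inv <- minimal_inv()
  inv$studies <- c(inv$studies, inv$studies)  # duplicate study id
  expect_true("STUDY_DUP_ID" %in% validate_investigation(inv)$errors$code)

  inv <- minimal_inv()
  inv$studies[[1]]$latitude <- 95
  expect_true("COORD_RANGE" %in% validate_investigation(inv)$errors$code)

  inv <- minimal_inv()
  inv$studies[[1]]$start_date <- "2001-01-01"
  expect_true("STUDY_DATE_ORDER" %in% validate_investigation(inv)$errors$code)

  inv <- minimal_inv()
  inv$studies[[1]]$observation_units <- rbind(
    units_df("plot1", "plot", "g1"),
    units_df("u1", "plant", "g1", "plot1"),
    units_df("u2", "plant", "g1", "u1"))  # plant under plant: not coarser
  rep <- validate_investigation(inv)
  expect_true(any(rep$errors$code == "UNIT_PARENT_LEVEL" &
                    rep$errors$object_id == "u2"))
})

test_that("undeclared categorical tokens are errors, downgradable to warnings", {
  inv <- minimal_inv()
  inv$observed_variables$categories <- "0|1|2|3|4|5|6|7"
  ok <- rec_df("u1", "2000-06-01", "v1", "5")
  bad <- rec_df("u1", "2000-06-02", "v1", "*")
  expect_true(is_valid_report(validate_investigation(inv, ok)))
  rep <- validate_investigation(inv, rbind(ok, bad))
  expect_true("REC_TOKEN_UNDECLARED" %in% rep$errors$code)
  rep2 <- validate_investigation(inv, rbind(ok, bad), permissive_tokens = TRUE)
  expect_true(is_valid_report(rep2))
  expect_true("REC_TOKEN_UNDECLARED" %in% rep2$warnings$code)
})

test_that("partial dates warn, malformed dates error", {
  inv <- minimal_inv()
  inv$studies[[1]]$end_date <- "2000"
  rep <- validate_investigation(inv)
  expect_true(is_valid_report(rep))
  expect_true("DATE_PARTIAL" %in% rep$warnings$code)
  inv$studies[[1]]$end_date <- "June 2000"
  expect_true("DATE_INVALID" %in% validate_investigation(inv)$errors$code)
})

test_that("validation is deterministic and idempotent", {
  fx <- generate_fixture(tiny_spec(31))
  inv <- fx$investigation
  inv$studies[[1]]$events <- rbind(inv$studies[[1]]$events, data.frame(
    event_type = "watering", description = "w", date = NA_character_,
    stringsAsFactors = FALSE))
  r1 <- validate_investigation(inv, fx$records)
  r2 <- validate_investigation(inv, fx$records)
  expect_identical(r1, r2)
  expect_identical(r1$errors, r1$errors[order(r1$errors$code, r1$errors$object_id), ])
})
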