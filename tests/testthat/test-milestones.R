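test_that("the conversion bundle reloads into the directly serialized graphs", {
  fx <- generate_fixture(tiny_spec(111), dir = withr::local_tempdir())
  out <- withr::local_tempdir()
  files <- cmd_convert(fx$paths$workbook, fx$paths$observations,
                       fx$paths$weather, out)
  pol <- uri_policy()
  direct_meta <- investigation_to_graph(fx$investigation, pol)
  expect_identical(as.data.frame(parse_turtle(files[["metadata"]])),
                   as.data.frame(direct_meta))
  data_graphs <- lapply(names(fx$paths$observations), function(sid)
    parse_turtle(files[[paste0("data_", sid)]]))
  merged <- do.call(graph_union, data_graphs)
  expect_identical(
    as.data.frame(merged),
    as.data.frame(observations_to_graph(fx$records, fx$investigation, pol)))
  # station names are not part of the weather file format, so the bundle is
  # compared against a graph built from the read-back tables
  wx <- read_weather_table(fx$paths$weather)
  expect_identical(
    as.data.frame(parse_turtle(files[["weather"]])),
    as.data.frame(weather_to_graph(wx$stations, wx$observations, pol)))
})

test_that("conversion refuses a corrupted deposit with a validation report", {
  fx <- generate_fixture(tiny_spec(112), dir = withr::local_tempdir())
  p <- perturb_fixture(fx, "dateless_event")
  expect_error(cmd_convert(p$workbook, p$observations, p$weather,
                           withr::local_tempdir()),
               "EVT_DATE_MISSING")
})

test_that("the milestone report directory carries all six outputs and the log", {
  fx <- generate_fixture(tiny_spec(113), dir = withr::local_tempdir())
  out <- withr::local_tempdir()
  res <- cmd_milestones(fx$paths$workbook, fx$paths$observations,
                        fx$paths$weather, "tubweight", out)
  for (f in c("studies.tsv", "common_genotypes.txt", "station_matches.tsv",
              "trait_matrix.tsv", "pbtt.tsv", "stability.tsv",
              "trait_means.png", "stability.png", "summary.log"))
    expect_true(file.exists(file.path(out, f)), info = f)
  expect_identical(readLines(file.path(out, "common_genotypes.txt")),
                   fx$truth$common_genotypes)
  expect_identical(unname(res$counts[["common_genotypes"]]),
                   length(fx$truth$common_genotypes))
  # deterministic reruns: byte-identical tabular outputs
  out2 <- withr::local_tempdir()
  cmd_milestones(fx$paths$workbook, fx$paths$observations, fx$paths$weather,
                 "tubweight", out2)
  for (f in c("studies.tsv", "station_matches.tsv", "trait_matrix.tsv",
              "pbtt.tsv", "stability.tsv"))
    expect_identical(readLines(file.path(out, f)), readLines(file.path(out2, f)),
                     info = f)
})

test_that("a single-study source gives its own genotype set and only flat lines", {
  fx <- generate_fixture(fixture_spec(n_studies = 1, n_genotypes_total = 6,
                                      overlap_count = 6, complete_cases = 6,
                                      genotype_level_study = NA,
                                      plants_per_genotype = 2, seed = 114))
  res <- run_milestones(source_model(fx$investigation, fx$records),
                        source_weather_model(fx$stations, fx$weather),
                        "tubweight")
  sid <- fx$investigation$studies[[1]]$id
  expect_identical(res$common_genotypes, fx$truth$genotype_sets[[sid]])
  expect_identical(unique(res$stability$direction), "flat")
  expect_true(all(res$stability$spread == 0))
})

test_that("stage failures name the failing milestone", {
  fx <- generate_fixture(tiny_spec(115))
  wx <- fx$weather[fx$weather$date != fx$weather$date[5], ]
  expect_error(run_milestones(source_model(fx$investigation, fx$records),
                              source_weather_model(fx$stations, wx),
                              "tubweight"),
               "milestone 'pbtt'")
  expect_error(run_milestones(source_model(fx$investigation, fx$records),
                              source_weather_model(fx$stations, fx$weather),
                              "not_a_trait"),
               "milestone 'trait_aggregation'")
})

test_that("the CLI entry script is valid R", {
  p <- system.file("cli", "fairphen.R", package = "fairphen")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "cli", "fairphen.R")
  expect_no_error(parse(file = p))
})
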