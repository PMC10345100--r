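test_that("study summaries equal the model fields across all three source kinds", {
  fx <- generate_fixture(tiny_spec(71))
  routes <- three_routes(fx, withr::local_tempdir())
  sm <- summarize_studies(routes$pheno$model)
  expect_identical(nrow(sm), length(fx$investigation$studies))
  for (s in fx$investigation$studies) {
    row <- sm[sm$study_id == s$id, ]
    expect_identical(row$country_code, s$country_code)
    expect_identical(row$start_date, s$start_date)
    expect_equal(row$latitude, s$latitude)
    expect_equal(row$altitude, s$altitude)
  }
  expect_equal(summarize_studies(routes$pheno$graph), sm)
  expect_equal(summarize_studies(routes$pheno$sparql), sm)
})

test_that("station matching equals exhaustive pairwise minimization", {
  set.seed(72)
  summaries <- data.frame(study_id = sprintf("s%d", 1:5),
                          latitude = runif(5, -40, 65),
                          longitude = runif(5, -80, 80),
                          stringsAsFactors = FALSE)
  stations <- data.frame(id = sprintf("w%d", 1:5), name = sprintf("w%d", 1:5),
                         latitude = runif(5, -40, 65),
                         longitude = runif(5, -80, 80), stringsAsFactors = FALSE)
  got <- match_weather_stations(summaries, stations)
  for (i in seq_len(nrow(summaries))) {
    best_d <- Inf; best_id <- NULL
    for (j in seq_len(nrow(stations))) {
      d <- (summaries$latitude[i] - stations$latitude[j])^2 +
        (summaries$longitude[i] - stations$longitude[j])^2
      if (d < best_d) { best_d <- d; best_id <- stations$id[j] }
    }
    row <- got[got$study_id == summaries$study_id[i], ]
    expect_identical(row$station_id, best_id)
    expect_equal(row$squared_distance, best_d)
  }
  # colocated station matches at distance zero; ties break lexicographically
  stations2 <- rbind(stations,
                     data.frame(id = c("a_tie", "b_tie"), name = "t",
                                latitude = summaries$latitude[1],
                                longitude = summaries$longitude[1]))
  got2 <- match_weather_stations(summaries, stations2)
  expect_identical(got2$station_id[got2$study_id == "s1"], "a_tie")
  expect_equal(got2$squared_distance[got2$study_id == "s1"], 0)
  # adding a station can only decrease or preserve matched distances
  expect_true(all(got2$squared_distance <= got$squared_distance + 1e-15))
  expect_error(match_weather_stations(summaries, stations[0, ]), "no weather stations")
})

test_that("trait means equal a two-pass arithmetic mean and are order-invariant", {
  fx <- generate_fixture(tiny_spec(73, plants = 3))
  src <- source_model(fx$investigation, fx$records)
  tm <- genotype_trait_means(src, "tubweight")
  # two-pass oracle over plant-level records
  units <- inv_units(fx$investigation)
  rec <- fx$records[fx$records$variable_id == "tubweight", ]
  rec$study <- units$study_id[match(rec$observation_unit_id, units$id)]
  rec$geno <- units$biological_material_id[match(rec$observation_unit_id, units$id)]
  for (i in sample(nrow(tm), min(15, nrow(tm)))) {
    vals <- as.numeric(rec$value[rec$study == tm$study_id[i] &
                                   rec$geno == tm$genotype_id[i]])
    expect_equal(tm$mean_value[i], sum(vals) / length(vals), tolerance = 1e-12)
  }
  # permutation invariance in record order
  perm <- fx$records[sample(nrow(fx$records)), ]
  tm2 <- genotype_trait_means(source_model(fx$investigation, perm), "tubweight")
  expect_equal(tm, tm2)
})

test_that("pre-averaged genotype-level records pass through with unknown counts", {
  fx <- generate_fixture(tiny_spec(74, geno_level = 1))
  tm <- genotype_trait_means(source_model(fx$investigation, fx$records), "tubweight")
  gl_sid <- fx$investigation$studies[[1]]$id  # normalized order; find by level
  units <- inv_units(fx$investigation)
  gl_sid <- unique(units$study_id[units$level == "genotype"])
  gl <- tm[tm$study_id == gl_sid, ]
  expect_true(all(is.na(gl$n_units)))
  expect_true(all(!is.na(tm$n_units[tm$study_id != gl_sid])))
})

test_that("repeated dated measurements reduce by the selected policy", {
  inv <- minimal_inv()
  recs <- rbind(rec_df("u1", "2000-06-01", "v1", "10"),
                rec_df("u1", "2000-07-01", "v1", "30"))
  last <- genotype_trait_means(source_model(inv, recs), "v1")
  expect_equal(last$mean_value, 30)
  expect_equal(genotype_trait_means(source_model(inv, recs), "v1",
                                    repeated = "first")$mean_value, 10)
  expect_equal(genotype_trait_means(source_model(inv, recs), "v1",
                                    repeated = "mean")$mean_value, 20)
  expect_error(genotype_trait_means(source_model(inv, recs), "nope"), "nope")
})

test_that("complete cases equal the set-intersection of genotypes with values", {
  fx <- generate_fixture(tiny_spec(75, total = 12, overlap = 6, complete = 4))
  src <- source_model(fx$investigation, fx$records)
  uni <- genotype_trait_means(src, "tubweight")
  cc <- genotype_trait_means(src, "tubweight", restrict = "complete_cases")
  sids <- vapply(fx$investigation$studies, `[[`, "", "id")
  per_study <- lapply(sids, function(s) unique(uni$genotype_id[uni$study_id == s]))
  oracle <- Reduce(intersect, per_study)
  expect_setequal(unique(cc$genotype_id), oracle)
  expect_lte(length(unique(cc$genotype_id)),
             length(common_genotype_ids(fx$investigation)))
  expect_identical(sort(unique(cc$genotype_id), method = "radix"),
                   fx$truth$complete_case_genotypes)
})

test_that("stability lines agree with a brute-force scan and classify direction", {
  fx <- generate_fixture(tiny_spec(76))
  src <- source_model(fx$investigation, fx$records)
  tm <- genotype_trait_means(src, "tubweight")
  pb <- fx$truth$pbtt
  st <- stability_lines(tm, pb)
  pbv <- setNames(pb$pbtt, pb$study_id)
  for (g in unique(st$genotype_id)) {
    d <- tm[tm$genotype_id == g, ]
    lo <- d[which.min(d$mean_value), ]; hi <- d[which.max(d$mean_value), ]
    row <- st[st$genotype_id == g, ]
    expect_equal(row$value_low, lo$mean_value)
    expect_equal(row$value_high, hi$mean_value)
    expect_lte(row$value_low, row$value_high)
    expect_equal(row$spread, hi$mean_value - lo$mean_value)
    want <- if (nrow(d) == 1 || lo$mean_value == hi$mean_value) "flat"
            else if (pbv[[hi$study_id]] > pbv[[lo$study_id]]) "rising"
            else if (pbv[[hi$study_id]] < pbv[[lo$study_id]]) "falling" else "flat"
    expect_identical(row$direction, want)
  }
})

test_that("a trait rising monotonically with PBTT yields only rising lines", {
  inv <- minimal_inv()
  inv$studies <- list(
    miappe_study("sA", start_date = "2000-05-01", end_date = "2000-06-01",
                 latitude = 10, longitude = 0,
                 observation_units = units_df("a_u1", "plant", "g1")),
    miappe_study("sB", start_date = "2000-05-01", end_date = "2000-06-01",
                 latitude = 50, longitude = 0,
                 observation_units = units_df("b_u1", "plant", "g1")))
  recs <- rbind(rec_df("a_u1", NA, "v1", "10"), rec_df("b_u1", NA, "v1", "50"))
  tm <- genotype_trait_means(source_model(inv, recs), "v1")
  pb <- data.frame(study_id = c("sA", "sB"), pbtt = c(5, 25))
  st <- stability_lines(tm, pb)
  expect_identical(unique(st$direction), "rising")
  # single-environment genotype: flat with zero spread
  one <- stability_lines(tm[tm$study_id == "sA", ], pb)
  expect_identical(one$direction, "flat")
  expect_equal(one$spread, 0)
  expect_error(stability_lines(tm, pb[1, ]), "sB")
})

test_that("degenerate federation equals the in-memory joins", {
  fx <- generate_fixture(tiny_spec(77))
  routes <- three_routes(fx, withr::local_tempdir())
  direct <- match_weather_stations(summarize_studies(routes$pheno$model),
                                   fx$stations)
  fed <- federated_fetch(routes$pheno$model, routes$weather$model,
                         "station_match")
  expect_equal(fed, direct)
  fed_x <- federated_fetch(routes$pheno$graph, routes$weather$sparql,
                           "station_match")
  expect_equal(as.data.frame(fed_x), as.data.frame(direct))
  pb <- federated_fetch(routes$pheno$model, routes$weather$model, "pbtt")
  expect_equal(pb$pbtt, fx$truth$pbtt$pbtt)
  expect_error(
    federated_fetch(routes$pheno$model,
                    source_weather_sparql(file.path(tempdir(), "nope.ttl"))),
    "missing file")
})
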