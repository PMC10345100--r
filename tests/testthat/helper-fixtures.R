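# shared helpers: tiny deposit-shaped specs and a minimal hand-built
# investigation used across test files

tiny_spec <- function(seed, n_studies = 3, total = 10, overlap = 4,
                      complete = 3, plants = 2, geno_level = 2) {
  fixture_spec(n_studies = n_studies, n_genotypes_total = total,
               overlap_count = overlap, complete_cases = complete,
               genotype_level_study = geno_level,
               plants_per_genotype = plants, seed = seed)
}

random_spec <- function(seed) {
  set.seed(seed * 7 + 13)
  ns <- sample(2:4, 1)
  tot <- sample(8:14, 1)
  ov <- sample(2:min(6, tot), 1)
  gl <- if (stats::runif(1) < 0.5) NA_integer_ else sample.int(ns, 1)
  fixture_spec(n_studies = ns, n_genotypes_total = tot, overlap_count = ov,
               complete_cases = sample.int(ov, 1), genotype_level_study = gl,
               plants_per_genotype = sample(1:3, 1), seed = seed)
}

units_df <- function(id, level, mat, parent = NA_character_) {
  data.frame(id = id, level = level, biological_material_id = mat,
             parent_unit_id = parent, stringsAsFactors = FALSE)
}

minimal_inv <- function() {
  miappe_investigation(
    id = "inv1", title = "minimal", miappe_version = "1.1",
    license = "CC BY 4.0",
    studies = list(miappe_study(
      id = "s1", title = "study one", start_date = "2000-05-01",
      end_date = "2000-09-01", country_code = "NL", latitude = 50,
      longitude = 5, altitude = 3,
      observation_units = units_df("u1", "plant", "g1"))),
    biological_materials = data.frame(
      id = "g1", genus_species = "Solanum tuberosum",
      material_source = NA_character_, synonyms = NA_character_,
      stringsAsFactors = FALSE),
    observed_variables = data.frame(
      id = "v1", name = "trait one", trait = "t", method = "m", scale = "s",
      categories = NA_character_, unit = NA_character_,
      stringsAsFactors = FALSE))
}

rec_df <- function(unit, date, var, value) {
  data.frame(observation_unit_id = unit, date = date, variable_id = var,
             value = as.character(value), stringsAsFactors = FALSE)
}

# all observation units of an investigation with their study id
inv_units <- function(inv) {
  do.call(rbind, lapply(inv$studies, function(s) {
    u <- s$observation_units
    if (nrow(u) == 0L) return(NULL)
    u$study_id <- s$id
    u
  }))
}

# serialize fixture graphs to a directory; returns the three source routes
three_routes <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pol <- uri_policy()
  gm <- investigation_to_graph(fx$investigation, pol)
  gd <- observations_to_graph(fx$records, fx$investigation, pol)
  gw <- weather_to_graph(fx$stations, fx$weather, pol)
  fm <- file.path(dir, "meta.ttl"); serialize_turtle(gm, fm)
  fd <- file.path(dir, "data.ttl"); serialize_turtle(gd, fd)
  fw <- file.path(dir, "weather.ttl"); serialize_turtle(gw, fw)
  list(
    pheno = list(model = source_model(fx$investigation, fx$records),
                 graph = source_graph(gm, gd, pol),
                 sparql = source_sparql(c(fm, fd), pol)),
    weather = list(model = source_weather_model(fx$stations, fx$weather),
                   graph = source_weather_graph(gw, pol),
                   sparql = source_weather_sparql(fw, pol)))
}

milestones_equal <- function(a, b, tol = 1e-12) {
  isTRUE(all.equal(a[setdiff(names(a), "counts")],
                   b[setdiff(names(b), "counts")], tolerance = tol)) &&
    identical(a$counts, b$counts)
}
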