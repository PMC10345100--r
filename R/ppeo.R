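#' Vocabularies
#'
#' The phenotyping vocabulary follows PPEO (the ontology implementation of
#' MIAPPE); the weather vocabulary follows the AEMET weather ontology's
#' station / property / timestamped-value shape, with station coordinates
#' in WGS84 terms. Term IRIs are configuration: the shapes are fixed, the
#' namespaces swappable. The bundled defaults cover exactly the MIAPPE
#' subset this package models.
#'
#' @param ns namespace IRI the term names are appended to.
#' @return a named list with `ns`, `type` (class IRIs) and `pred`
#'   (predicate IRIs).
#' @export
ppeo_vocabulary <- function(ns = "http://purl.org/ppeo/PPEO.owl#") {
  t <- function(x) stats::setNames(paste0(ns, x), names(x))
  list(
    ns = ns,
    type = t(c(investigation = "investigation", study = "study",
               person = "person", data_file = "data_file",
               biological_material = "biological_material",
               observed_variable = "observed_variable",
               observation_unit = "observation_unit",
               environment_parameter = "environment_parameter",
               event = "event", experimental_factor = "experimental_factor",
               observation = "observation")),
    pred = t(c(
      identifier = "hasIdentifier", title = "hasTitle",
      description = "hasDescription", miappe_version = "hasMiappeVersion",
      license = "hasLicense", publication = "hasPublication",
      material_source_decl = "declaresMaterialSource",
      has_study = "hasStudy", has_person = "hasPerson",
      has_data_file = "hasDataFile", has_material = "hasBiologicalMaterial",
      has_variable = "hasObservedVariable",
      start_date = "hasStartDate", end_date = "hasEndDate",
      country_code = "hasCountryCode", location_name = "hasLocationName",
      location_address = "hasLocationAddress", latitude = "hasLatitude",
      longitude = "hasLongitude", altitude = "hasAltitude",
      design_description = "hasDesignDescription",
      has_env = "hasEnvironmentParameter", env_name = "hasParameterName",
      env_value = "hasParameterValue", env_unit = "hasParameterUnit",
      has_event = "hasEvent", event_type = "hasEventType",
      event_date = "hasEventDate",
      has_factor = "hasExperimentalFactor", factor_type = "hasFactorType",
      factor_desc = "hasFactorDescription", factor_value = "hasFactorValue",
      has_unit = "hasObservationUnit", level = "hasObservationLevel",
      material_ref = "refersToMaterial", parent_unit = "hasParentUnit",
      person_name = "hasName", email = "hasEmail",
      affiliation = "hasAffiliation", role = "hasRole",
      file_path = "hasFileLocator", file_desc = "hasFileDescription",
      file_study = "describesStudy",
      genus = "hasGenusSpecies", mat_source = "hasMaterialSource",
      synonym = "hasSynonym",
      var_name = "hasVariableName", trait = "hasTrait", method = "hasMethod",
      scale = "hasScale", category = "hasScaleCategory", unit = "hasUnit",
      obs_unit_ref = "onObservationUnit", obs_var_ref = "onObservedVariable",
      obs_value = "hasValue", obs_date = "hasObservationDate")))
}

#' @rdname ppeo_vocabulary
#' @export
aemet_vocabulary <- function(ns = "http://aemet.linkeddata.es/ontology#") {
  geo <- "http://www.w3.org/2003/01/geo/wgs84_pos#"
  list(
    ns = ns,
    type = c(station = paste0(ns, "WeatherStation"),
             observation = paste0(ns, "WeatherObservation")),
    pred = c(identifier = paste0(ns, "stationIdentifier"),
             name = paste0(ns, "stationName"),
             latitude = paste0(geo, "lat"), longitude = paste0(geo, "long"),
             of_station = paste0(ns, "observedAtStation"),
             date = paste0(ns, "observationDate"),
             property = paste0(ns, "observedProperty"),
             value = paste0(ns, "value")),
    prop = c(daily_mean_temperature_C = paste0(ns, "dailyMeanTemperature"),
             photoperiod_hours = paste0(ns, "photoperiod")))
}

xsd_t <- function(x) paste0(XSD, x)

lit_date <- function(s, p, v) {
  if (is.na(v)) return(NULL)
  st_lit(s, p, v, if (is_iso_date(v)) xsd_t("date") else NA_character_)
}
lit_str <- function(s, p, v) {
  if (is.na(v) || !nzchar(v)) return(NULL)
  st_lit(s, p, v)
}
lit_dec <- function(s, p, v) {
  if (is.na(v)) return(NULL)
  st_lit(s, p, fmt_num(v), xsd_t("decimal"))
}
# a measurement value: keep lexical form verbatim, type numerics as decimal
lit_val <- function(s, p, v) {
  st_lit(s, p, v,
         if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", v)) xsd_t("decimal")
         else NA_character_)
}

#' Serialize an investigation to a PPEO-style graph
#'
#' Maps every section of a valid investigation to typed nodes: one
#' investigation node, one study node per study linked from it, and every
#' person, data-file link, material, variable, environment parameter,
#' event, factor and observation unit reachable from the investigation
#' node. Literal fields are typed (dates as `xsd:date`, coordinates as
#' `xsd:decimal`). Refuses investigations with validation errors.
#'
#' @param inv an [miappe_investigation()]; must validate with zero errors.
#' @param policy a [uri_policy()].
#' @param vocab a [ppeo_vocabulary()].
#' @return an `fp_graph`.
#' @export
investigation_to_graph <- function(inv, policy = uri_policy(),
                                   vocab = ppeo_vocabulary()) {
  assert_valid(inv, what = "serialize to RDF")
  inv <- normalize_investigation(inv)
  P <- vocab$pred; TY <- vocab$type
  tr <- list()
  add <- function(x) tr[[length(tr) + 1L]] <<- x

  iu <- mint_uri(policy, "investigation", inv$id)
  add(st_uri(iu, RDF_TYPE, TY[["investigation"]]))
  add(st_lit(iu, P[["identifier"]], inv$id))
  add(lit_str(iu, P[["title"]], inv$title))
  add(lit_str(iu, P[["description"]], inv$description))
  add(st_lit(iu, P[["miappe_version"]], inv$miappe_version))
  add(lit_str(iu, P[["license"]], inv$license))
  for (p in inv$publications) add(st_lit(iu, P[["publication"]], p))
  for (m in inv$material_sources) add(st_lit(iu, P[["material_source_decl"]], m))

  for (i in seq_len(nrow(inv$persons))) {
    pu <- mint_uri(policy, "person", paste0(inv$id, "#", i))
    add(st_uri(iu, P[["has_person"]], pu))
    add(st_uri(pu, RDF_TYPE, TY[["person"]]))
    add(lit_str(pu, P[["person_name"]], inv$persons$name[i]))
    add(lit_str(pu, P[["email"]], inv$persons$email[i]))
    add(lit_str(pu, P[["affiliation"]], inv$persons$affiliation[i]))
    add(lit_str(pu, P[["role"]], inv$persons$role[i]))
  }
  for (i in seq_len(nrow(inv$data_files))) {
    du <- mint_uri(policy, "data_file", paste0(inv$id, "#", i))
    add(st_uri(iu, P[["has_data_file"]], du))
    add(st_uri(du, RDF_TYPE, TY[["data_file"]]))
    add(lit_str(du, P[["file_path"]], inv$data_files$path_or_url[i]))
    add(lit_str(du, P[["file_desc"]], inv$data_files$description[i]))
    add(st_uri(du, P[["file_study"]],
               mint_uri(policy, "study", inv$data_files$study_id[i])))
  }
  bm <- inv$biological_materials
  for (i in seq_len(nrow(bm))) {
    mu <- mint_uri(policy, "material", bm$id[i])
    add(st_uri(iu, P[["has_material"]], mu))
    add(st_uri(mu, RDF_TYPE, TY[["biological_material"]]))
    add(st_lit(mu, P[["identifier"]], bm$id[i]))
    add(lit_str(mu, P[["genus"]], bm$genus_species[i]))
    add(lit_str(mu, P[["mat_source"]], bm$material_source[i]))
    for (s in split_multi(bm$synonyms[i] %||% NA_character_))
      add(st_lit(mu, P[["synonym"]], s))
  }
  ov <- inv$observed_variables
  for (i in seq_len(nrow(ov))) {
    vu <- mint_uri(policy, "variable", ov$id[i])
    add(st_uri(iu, P[["has_variable"]], vu))
    add(st_uri(vu, RDF_TYPE, TY[["observed_variable"]]))
    add(st_lit(vu, P[["identifier"]], ov$id[i]))
    add(lit_str(vu, P[["var_name"]], ov$name[i]))
    add(lit_str(vu, P[["trait"]], ov$trait[i]))
    add(lit_str(vu, P[["method"]], ov$method[i]))
    add(lit_str(vu, P[["scale"]], ov$scale[i]))
    add(lit_str(vu, P[["unit"]], ov$unit[i]))
    if (!is.na(ov$categories[i]))
      for (ct in split_multi(ov$categories[i]))
        add(st_lit(vu, P[["category"]], ct))
  }

  for (s in inv$studies) {
    su <- mint_uri(policy, "study", s$id)
    add(st_uri(iu, P[["has_study"]], su))
    add(st_uri(su, RDF_TYPE, TY[["study"]]))
    add(st_lit(su, P[["identifier"]], s$id))
    add(lit_str(su, P[["title"]], s$title))
    add(lit_date(su, P[["start_date"]], s$start_date))
    add(lit_date(su, P[["end_date"]], s$end_date))
    add(lit_str(su, P[["country_code"]], s$country_code))
    add(lit_str(su, P[["location_name"]], s$location_name))
    add(lit_str(su, P[["location_address"]], s$location_address))
    add(lit_dec(su, P[["latitude"]], s$latitude))
    add(lit_dec(su, P[["longitude"]], s$longitude))
    add(lit_dec(su, P[["altitude"]], s$altitude))
    add(lit_str(su, P[["design_description"]], s$design_description))
    ep <- s$environment_parameters
    for (i in seq_len(nrow(ep))) {
      eu <- mint_uri(policy, "environment", paste0(s$id, "#", i))
      add(st_uri(su, P[["has_env"]], eu))
      add(st_uri(eu, RDF_TYPE, TY[["environment_parameter"]]))
      add(lit_str(eu, P[["env_name"]], ep$name[i]))
      add(lit_str(eu, P[["env_value"]], ep$value[i]))
      add(lit_str(eu, P[["env_unit"]], ep$unit[i]))
    }
    ev <- s$events
    for (i in seq_len(nrow(ev))) {
      eu <- mint_uri(policy, "event", paste0(s$id, "#", i))
      add(st_uri(su, P[["has_event"]], eu))
      add(st_uri(eu, RDF_TYPE, TY[["event"]]))
      add(lit_str(eu, P[["event_type"]], ev$event_type[i]))
      add(lit_str(eu, P[["description"]], ev$description[i]))
      add(lit_date(eu, P[["event_date"]], ev$date[i]))
    }
    fc <- s$experimental_factors
    for (i in seq_len(nrow(fc))) {
      fu <- mint_uri(policy, "factor", paste0(s$id, "#", i))
      add(st_uri(su, P[["has_factor"]], fu))
      add(st_uri(fu, RDF_TYPE, TY[["experimental_factor"]]))
      add(lit_str(fu, P[["factor_type"]], fc$factor_type[i]))
      add(lit_str(fu, P[["factor_desc"]], fc$description[i]))
      for (v in split_multi(fc$values[i] %||% NA_character_))
        add(st_lit(fu, P[["factor_value"]], v))
    }
    u <- s$observation_units
    for (i in seq_len(nrow(u))) {
      uu <- mint_uri(policy, "unit", u$id[i])
      add(st_uri(su, P[["has_unit"]], uu))
      add(st_uri(uu, RDF_TYPE, TY[["observation_unit"]]))
      add(st_lit(uu, P[["identifier"]], u$id[i]))
      add(st_lit(uu, P[["level"]], u$level[i]))
      add(st_uri(uu, P[["material_ref"]],
                 mint_uri(policy, "material", u$biological_material_id[i])))
      if (!is.na(u$parent_unit_id[i]) && nzchar(u$parent_unit_id[i]))
        add(st_uri(uu, P[["parent_unit"]], mint_uri(policy, "unit", u$parent_unit_id[i])))
    }
  }
  triple_graph(rbind_all(tr, triples_proto()))
}

#' Rebuild an investigation from a PPEO-style graph
#'
#' Inverse of [investigation_to_graph()]:
#' `graph_to_investigation(investigation_to_graph(inv))` equals
#' `normalize_investigation(inv)` field for field. Fails naming the first
#' missing mandatory shape element (e.g. an investigation node without a
#' `miappe_version` literal).
#'
#' @param g an `fp_graph` with the PPEO shape.
#' @param policy,vocab as used to produce the graph.
#' @return an [miappe_investigation()].
#' @export
graph_to_investigation <- function(g, policy = uri_policy(),
                                   vocab = ppeo_vocabulary()) {
  P <- vocab$pred; TY <- vocab$type
  inv_nodes <- g_subjects_of_type(g, TY[["investigation"]])
  if (length(inv_nodes) != 1L)
    stop_fp("expected exactly 1 investigation node, found %d", length(inv_nodes))
  iu <- inv_nodes
  ident <- function(node) g_value(g, node, P[["identifier"]], required = TRUE)

  persons <- rbind_all(lapply(c_sort(graph_match(g, s = iu, p = P[["has_person"]])$object),
    function(pu) data.frame(
      name = g_value(g, pu, P[["person_name"]]), email = g_value(g, pu, P[["email"]]),
      affiliation = g_value(g, pu, P[["affiliation"]]), role = g_value(g, pu, P[["role"]]),
      stringsAsFactors = FALSE)), persons_proto())
  dfs <- rbind_all(lapply(c_sort(graph_match(g, s = iu, p = P[["has_data_file"]])$object),
    function(du) data.frame(
      path_or_url = g_value(g, du, P[["file_path"]]),
      description = g_value(g, du, P[["file_desc"]]),
      study_id = uri_decompose(policy, g_value(g, du, P[["file_study"]], required = TRUE))$id,
      stringsAsFactors = FALSE)), data_files_proto())
  mats <- rbind_all(lapply(c_sort(graph_match(g, s = iu, p = P[["has_material"]])$object),
    function(mu) data.frame(
      id = ident(mu), genus_species = g_value(g, mu, P[["genus"]]),
      material_source = g_value(g, mu, P[["mat_source"]]),
      synonyms = {
        syn <- g_values(g, mu, P[["synonym"]])
        if (length(syn)) join_multi(syn) else NA_character_
      }, stringsAsFactors = FALSE)), materials_proto())
  vars <- rbind_all(lapply(c_sort(graph_match(g, s = iu, p = P[["has_variable"]])$object),
    function(vu) data.frame(
      id = ident(vu), name = g_value(g, vu, P[["var_name"]]),
      trait = g_value(g, vu, P[["trait"]]), method = g_value(g, vu, P[["method"]]),
      scale = g_value(g, vu, P[["scale"]]),
      categories = {
        ct <- g_values(g, vu, P[["category"]])
        if (length(ct)) join_multi(ct) else NA_character_
      },
      unit = g_value(g, vu, P[["unit"]]), stringsAsFactors = FALSE)),
    variables_proto())

  read_children <- function(su, link, fields) {
    nodes <- c_sort(graph_match(g, s = su, p = link)$object)
    rbind_all(lapply(nodes, function(nu) {
      vals <- lapply(fields, function(f) f(nu))
      as.data.frame(vals, stringsAsFactors = FALSE)
    }), as.data.frame(lapply(fields, function(f) character(0)),
                      stringsAsFactors = FALSE))
  }

  studies <- lapply(c_sort(graph_match(g, s = iu, p = P[["has_study"]])$object),
    function(su) {
      units <- read_children(su, P[["has_unit"]], list(
        id = function(n) ident(n),
        level = function(n) g_value(g, n, P[["level"]], required = TRUE),
        biological_material_id = function(n)
          uri_decompose(policy, g_value(g, n, P[["material_ref"]], required = TRUE))$id,
        parent_unit_id = function(n) {
          p <- g_value(g, n, P[["parent_unit"]])
          if (is.na(p)) NA_character_ else uri_decompose(policy, p)$id
        }))
      miappe_study(
        id = ident(su), title = g_value(g, su, P[["title"]]),
        start_date = g_value(g, su, P[["start_date"]]),
        end_date = g_value(g, su, P[["end_date"]]),
        country_code = g_value(g, su, P[["country_code"]]),
        location_name = g_value(g, su, P[["location_name"]]),
        location_address = g_value(g, su, P[["location_address"]]),
        latitude = g_num(g, su, P[["latitude"]]),
        longitude = g_num(g, su, P[["longitude"]]),
        altitude = g_num(g, su, P[["altitude"]]),
        design_description = g_value(g, su, P[["design_description"]]),
        environment_parameters = read_children(su, P[["has_env"]], list(
          name = function(n) g_value(g, n, P[["env_name"]]),
          value = function(n) g_value(g, n, P[["env_value"]]),
          unit = function(n) g_value(g, n, P[["env_unit"]]))),
        experimental_factors = read_children(su, P[["has_factor"]], list(
          factor_type = function(n) g_value(g, n, P[["factor_type"]]),
          description = function(n) g_value(g, n, P[["factor_desc"]]),
          values = function(n) {
            v <- g_values(g, n, P[["factor_value"]])
            if (length(v)) join_multi(v) else NA_character_
          })),
        events = read_children(su, P[["has_event"]], list(
          event_type = function(n) g_value(g, n, P[["event_type"]]),
          description = function(n) g_value(g, n, P[["description"]]),
          date = function(n) g_value(g, n, P[["event_date"]]))),
        observation_units = units)
    })

  normalize_investigation(miappe_investigation(
    id = ident(iu), title = g_value(g, iu, P[["title"]]),
    description = g_value(g, iu, P[["description"]]),
    miappe_version = g_value(g, iu, P[["miappe_version"]], required = TRUE),
    license = g_value(g, iu, P[["license"]]),
    publications = g_values(g, iu, P[["publication"]]),
    studies = studies, persons = persons, data_files = dfs,
    biological_materials = mats, observed_variables = vars,
    material_sources = g_values(g, iu, P[["material_source_decl"]])))
}

#' Serialize observation records to a graph
#'
#' One observation node per record, carrying a unit reference, a variable
#' reference, the value literal (typed `xsd:decimal` when numeric, kept in
#' its verbatim lexical form) and an optional date literal. Refuses
#' records whose unit or variable does not resolve against the
#' investigation.
#'
#' @param records observation-record data frame.
#' @param inv the investigation the records belong to.
#' @param policy,vocab as for [investigation_to_graph()].
#' @return an `fp_graph`.
#' @export
observations_to_graph <- function(records, inv, policy = uri_policy(),
                                  vocab = ppeo_vocabulary()) {
  units <- all_units(inv)
  bad_u <- setdiff(records$observation_unit_id, units$id)
  if (length(bad_u) > 0L)
    stop_fp("record(s) reference undeclared unit(s): %s",
            paste(utils::head(bad_u, 5), collapse = ", "))
  bad_v <- setdiff(records$variable_id, inv$observed_variables$id)
  if (length(bad_v) > 0L)
    stop_fp("record(s) reference undeclared variable(s): %s",
            paste(utils::head(bad_v, 5), collapse = ", "))
  P <- vocab$pred
  tr <- vector("list", nrow(records) * 5L)
  k <- 0L
  add <- function(x) { k <<- k + 1L; tr[[k]] <<- x }
  for (i in seq_len(nrow(records))) {
    key <- paste(records$observation_unit_id[i], records$variable_id[i],
                 ifelse(is.na(records$date[i]), "undated", records$date[i]), sep = "/")
    ou <- mint_uri(policy, "observation", key)
    add(st_uri(ou, RDF_TYPE, vocab$type[["observation"]]))
    add(st_uri(ou, P[["obs_unit_ref"]],
               mint_uri(policy, "unit", records$observation_unit_id[i])))
    add(st_uri(ou, P[["obs_var_ref"]],
               mint_uri(policy, "variable", records$variable_id[i])))
    add(lit_val(ou, P[["obs_value"]], records$value[i]))
    if (!is.na(records$date[i])) add(lit_date(ou, P[["obs_date"]], records$date[i]))
  }
  triple_graph(rbind_all(tr[seq_len(k)], triples_proto()))
}

#' Rebuild observation records from a graph
#' @param g graph produced by [observations_to_graph()] (possibly merged
#'   with others).
#' @param policy the minting policy.
#' @param vocab the phenotyping vocabulary.
#' @return observation-record data frame in canonical order.
#' @export
graph_to_observations <- function(g, policy = uri_policy(),
                                  vocab = ppeo_vocabulary()) {
  P <- vocab$pred
  nodes <- g_subjects_of_type(g, vocab$type[["observation"]])
  out <- rbind_all(lapply(nodes, function(ou) data.frame(
    observation_unit_id = uri_decompose(policy, g_value(g, ou, P[["obs_unit_ref"]],
                                                        required = TRUE))$id,
    date = g_value(g, ou, P[["obs_date"]]),
    variable_id = uri_decompose(policy, g_value(g, ou, P[["obs_var_ref"]],
                                                required = TRUE))$id,
    value = g_value(g, ou, P[["obs_value"]], required = TRUE),
    stringsAsFactors = FALSE)), observation_records())
  out <- out[c_order(out$observation_unit_id, out$variable_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize weather data to an AEMET-style graph
#'
#' Station nodes carry identifier, name and WGS84 coordinate literals;
#' each daily observation node links its station, date, weather-property
#' term and decimal value. Observations referencing an undeclared station
#' are refused.
#' @param stations,observations weather data frames
#'   (see [weather_stations()]).
#' @param policy a [uri_policy()].
#' @param vocab an [aemet_vocabulary()].
#' @return an `fp_graph`.
#' @export
weather_to_graph <- function(stations, observations, policy = uri_policy(),
                             vocab = aemet_vocabulary()) {
  bad <- setdiff(observations$station_id, stations$id)
  if (length(bad) > 0L)
    stop_fp("weather observation(s) reference undeclared station(s): %s",
            paste(bad, collapse = ", "))
  bad_v <- setdiff(observations$variable, names(vocab$prop))
  if (length(bad_v) > 0L)
    stop_fp("unknown weather variable(s): %s", paste(bad_v, collapse = ", "))
  P <- vocab$pred
  tr <- list()
  add <- function(x) tr[[length(tr) + 1L]] <<- x
  for (i in seq_len(nrow(stations))) {
    su <- mint_uri(policy, "station", stations$id[i])
    add(st_uri(su, RDF_TYPE, vocab$type[["station"]]))
    add(st_lit(su, P[["identifier"]], stations$id[i]))
    add(lit_str(su, P[["name"]], stations$name[i]))
    add(lit_dec(su, P[["latitude"]], stations$latitude[i]))
    add(lit_dec(su, P[["longitude"]], stations$longitude[i]))
  }
  for (i in seq_len(nrow(observations))) {
    key <- paste(observations$station_id[i], observations$date[i],
                 observations$variable[i], sep = "/")
    ou <- mint_uri(policy, "weather_observation", key)
    add(st_uri(ou, RDF_TYPE, vocab$type[["observation"]]))
    add(st_uri(ou, P[["of_station"]], mint_uri(policy, "station", observations$station_id[i])))
    add(lit_date(ou, P[["date"]], observations$date[i]))
    add(st_uri(ou, P[["property"]], vocab$prop[[observations$variable[i]]]))
    add(lit_dec(ou, P[["value"]], observations$value[i]))
  }
  triple_graph(rbind_all(tr, triples_proto()))
}

#' Rebuild weather tables from a graph
#' @param g graph produced by [weather_to_graph()].
#' @param policy the minting policy.
#' @param vocab the weather vocabulary.
#' @return list with `stations` and `observations`.
#' @export
graph_to_weather <- function(g, policy = uri_policy(), vocab = aemet_vocabulary()) {
  P <- vocab$pred
  st <- rbind_all(lapply(g_subjects_of_type(g, vocab$type[["station"]]),
    function(su) data.frame(
      id = g_value(g, su, P[["identifier"]], required = TRUE),
      name = g_value(g, su, P[["name"]]),
      latitude = g_num(g, su, P[["latitude"]]),
      longitude = g_num(g, su, P[["longitude"]]), stringsAsFactors = FALSE)),
    weather_stations())
  prop_rev <- stats::setNames(names(vocab$prop), unname(vocab$prop))
  obs <- rbind_all(lapply(g_subjects_of_type(g, vocab$type[["observation"]]),
    function(ou) data.frame(
      station_id = uri_decompose(policy, g_value(g, ou, P[["of_station"]],
                                                 required = TRUE))$id,
      date = g_value(g, ou, P[["date"]], required = TRUE),
      variable = prop_rev[[g_value(g, ou, P[["property"]], required = TRUE)]],
      value = as.numeric(g_value(g, ou, P[["value"]], required = TRUE)),
      stringsAsFactors = FALSE)), weather_observations())
  obs <- obs[c_order(obs$station_id, obs$date, obs$variable), , drop = FALSE]
  rownames(obs) <- NULL
  st <- st[c_order(st$id), , drop = FALSE]
  rownames(st) <- NULL
  list(stations = st, observations = obs)
}
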