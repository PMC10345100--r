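#' SPARQL engine route
#'
#' The "endpoint" execution route loads the serialized Turtle into a
#' SPARQL 1.1 engine (python's rdflib, run out of process) and extracts
#' the milestone tables with SELECT queries. It is the independent third
#' leg of the three-way consistency property: the engine parses the
#' Turtle with its own parser and matches the queries with its own
#' algebra, so agreement with the model and graph routes exercises the
#' whole serialization stack.
#'
#' @name sparql-route
NULL

#' Run a batch of SPARQL jobs
#'
#' @param jobs list of jobs, each `list(name =, files =, queries = named
#'   character vector)`.
#' @param python python interpreter with rdflib.
#' @return nested list: job name -> query name -> data frame.
#' @export
run_sparql_jobs <- function(jobs, python = find_python()) {
  runner <- system.file("python", "sparql_runner.py", package = "fairphen")
  if (!nzchar(runner)) stop_fp("sparql_runner.py not found in installed package")
  job_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(job_path, out_path)), add = TRUE)
  payload <- list(jobs = lapply(jobs, function(j) list(
    name = j$name, files = I(as.character(j$files)), queries = as.list(j$queries))))
  jsonlite::write_json(payload, job_path, auto_unbox = TRUE)
  status <- system2(python, c(runner, job_path, out_path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path))
    stop_fp("SPARQL engine failed: %s", paste(status, collapse = "\n"))
  raw <- jsonlite::fromJSON(out_path, simplifyVector = FALSE)
  lapply(raw, function(job) lapply(job, function(q) {
    cols <- unlist(q$cols)
    if (length(q$rows) == 0L)
      return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                           stringsAsFactors = FALSE))
    m <- do.call(rbind, lapply(q$rows, function(r)
      vapply(r, function(x) if (is.null(x)) NA_character_ else as.character(x),
             character(1))))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }))
}

#' Prefetch many SPARQL sources in one engine invocation
#'
#' Loading the engine has a fixed per-process cost; when a property-based
#' run needs hundreds of sources, batching all extraction queries into
#' one invocation keeps the endpoint route tractable. Each source's cache
#' is filled; subsequent milestone calls on it are pure R.
#'
#' @param sources list of [source_sparql()] / [source_weather_sparql()]
#'   objects.
#' @param python interpreter; defaults to the first source's.
#' @return `sources`, invisibly (their caches now populated).
#' @export
sparql_prefetch <- function(sources, python = NULL) {
  todo <- Filter(function(s) inherits(s, "fp_source") && s$kind == "sparql" &&
                   is.null(s$cache$tables), sources)
  if (length(todo) == 0L) return(invisible(sources))
  if (is.null(python)) python <- todo[[1]]$python
  jobs <- lapply(seq_along(todo), function(i) {
    s <- todo[[i]]
    list(name = sprintf("job%04d", i), files = s$files,
         queries = if (s$domain == "phenotypic") sparql_pheno_queries(s$vocab)
                   else sparql_weather_queries(s$vocab))
  })
  res <- run_sparql_jobs(jobs, python)
  for (i in seq_along(todo)) {
    s <- todo[[i]]
    r <- res[[sprintf("job%04d", i)]]
    s$cache$tables <- if (s$domain == "phenotypic")
      sparql_tables_from_results(r, s$policy)
    else sparql_weather_from_results(r, s$vocab)
  }
  invisible(sources)
}

sparql_pheno_queries <- function(vocab) {
  P <- function(x) sprintf("<%s>", vocab$pred[[x]])
  TY <- function(x) sprintf("<%s>", vocab$type[[x]])
  opt <- function(v, p) sprintf("OPTIONAL { ?s %s ?%s . }", p, v)
  c(
    investigation = sprintf(
      "SELECT ?id ?title WHERE { ?s a %s ; %s ?id . %s }",
      TY("investigation"), P("identifier"), opt("title", P("title"))),
    studies = sprintf(paste(
      "SELECT ?id ?title ?start_date ?end_date ?country_code ?location_name",
      "?location_address ?latitude ?longitude ?altitude ?design_description",
      "WHERE { ?s a %s ; %s ?id . %s %s %s %s %s %s %s %s %s %s }"),
      TY("study"), P("identifier"),
      opt("title", P("title")), opt("start_date", P("start_date")),
      opt("end_date", P("end_date")), opt("country_code", P("country_code")),
      opt("location_name", P("location_name")),
      opt("location_address", P("location_address")),
      opt("latitude", P("latitude")), opt("longitude", P("longitude")),
      opt("altitude", P("altitude")),
      opt("design_description", P("design_description"))),
    units = sprintf(paste(
      "SELECT ?study ?id ?level ?mat ?parent WHERE {",
      "?st a %s ; %s ?study ; %s ?u .",
      "?u %s ?id ; %s ?level ; %s ?mat .",
      "OPTIONAL { ?u %s ?parent . } }"),
      TY("study"), P("identifier"), P("has_unit"),
      P("identifier"), P("level"), P("material_ref"), P("parent_unit")),
    materials = sprintf(paste(
      "SELECT ?id ?synonym WHERE { ?i a %s ; %s ?m .",
      "?m %s ?id . OPTIONAL { ?m %s ?synonym . } }"),
      TY("investigation"), P("has_material"), P("identifier"), P("synonym")),
    variables = sprintf(paste(
      "SELECT ?id ?name WHERE { ?i a %s ; %s ?v . ?v %s ?id .",
      "OPTIONAL { ?v %s ?name . } }"),
      TY("investigation"), P("has_variable"), P("identifier"), P("var_name")),
    records = sprintf(paste(
      "SELECT ?unit ?var ?value ?date WHERE { ?o a %s ;",
      "%s ?unit ; %s ?var ; %s ?value . OPTIONAL { ?o %s ?date . } }"),
      TY("observation"), P("obs_unit_ref"), P("obs_var_ref"),
      P("obs_value"), P("obs_date")))
}

sparql_weather_queries <- function(vocab) {
  P <- function(x) sprintf("<%s>", vocab$pred[[x]])
  TY <- function(x) sprintf("<%s>", vocab$type[[x]])
  c(
    stations = sprintf(paste(
      "SELECT ?id ?name ?lat ?lon WHERE { ?s a %s ; %s ?id .",
      "OPTIONAL { ?s %s ?name . } OPTIONAL { ?s %s ?lat . }",
      "OPTIONAL { ?s %s ?lon . } }"),
      TY("station"), P("identifier"), P("name"), P("latitude"), P("longitude")),
    weather = sprintf(paste(
      "SELECT ?station ?date ?prop ?value WHERE { ?o a %s ;",
      "%s ?su ; %s ?date ; %s ?prop ; %s ?value . ?su %s ?station . }"),
      TY("observation"), P("of_station"), P("date"), P("property"),
      P("value"), P("identifier")))
}

sparql_pheno_tables <- function(source, results = NULL) {
  if (is.null(results)) {
    jobs <- list(list(name = "pheno", files = source$files,
                      queries = sparql_pheno_queries(source$vocab)))
    results <- run_sparql_jobs(jobs, source$python)$pheno
  }
  sparql_tables_from_results(results, source$policy)
}

# shared with the batched acceptance path
sparql_tables_from_results <- function(res, policy) {
  it <- res$investigation
  if (nrow(it) != 1L) stop_fp("expected exactly 1 investigation node via SPARQL")
  st <- res$studies
  un <- res$units
  studies <- lapply(seq_len(nrow(st)), function(i) {
    u <- un[un$study == st$id[i], , drop = FALSE]
    units <- data.frame(
      id = u$id, level = u$level,
      biological_material_id = if (nrow(u)) uri_decompose(policy, u$mat)$id else character(0),
      parent_unit_id = ifelse(is.na(u$parent), NA_character_,
                              vapply(u$parent, function(p)
                                if (is.na(p)) NA_character_ else uri_decompose(policy, p)$id,
                                character(1), USE.NAMES = FALSE)),
      stringsAsFactors = FALSE)
    miappe_study(
      id = st$id[i], title = st$title[i], start_date = st$start_date[i],
      end_date = st$end_date[i], country_code = st$country_code[i],
      location_name = st$location_name[i], location_address = st$location_address[i],
      latitude = as.numeric(st$latitude[i]), longitude = as.numeric(st$longitude[i]),
      altitude = as.numeric(st$altitude[i]),
      design_description = st$design_description[i],
      observation_units = units)
  })
  mt <- res$materials
  mats <- materials_proto()
  if (nrow(mt) > 0L) {
    syn <- vapply(split(mt$synonym, mt$id), function(s) {
      s <- s[!is.na(s)]
      if (length(s)) join_multi(c_sort(s)) else NA_character_
    }, character(1))
    mats <- data.frame(id = names(syn), genus_species = NA_character_,
                       material_source = NA_character_, synonyms = unname(syn),
                       stringsAsFactors = FALSE)
  }
  vt <- res$variables
  vars <- variables_proto()
  if (nrow(vt) > 0L)
    vars <- data.frame(id = vt$id, name = vt$name, trait = NA_character_,
                       method = NA_character_, scale = NA_character_,
                       categories = NA_character_, unit = NA_character_,
                       stringsAsFactors = FALSE)
  inv <- normalize_investigation(miappe_investigation(
    id = it$id[1], title = it$title[1], studies = studies,
    biological_materials = mats, observed_variables = vars))
  rc <- res$records
  records <- observation_records()
  if (nrow(rc) > 0L) {
    records <- data.frame(
      observation_unit_id = uri_decompose(policy, rc$unit)$id,
      date = rc$date,
      variable_id = uri_decompose(policy, rc$var)$id,
      value = rc$value, stringsAsFactors = FALSE)
    records <- records[c_order(records$observation_unit_id, records$variable_id,
                               records$date), , drop = FALSE]
    rownames(records) <- NULL
  }
  list(inv = inv, records = records)
}

sparql_weather_tables <- function(source, results = NULL) {
  if (is.null(results)) {
    jobs <- list(list(name = "weather", files = source$files,
                      queries = sparql_weather_queries(source$vocab)))
    results <- run_sparql_jobs(jobs, source$python)$weather
  }
  sparql_weather_from_results(results, source$vocab)
}

sparql_weather_from_results <- function(res, vocab) {
  st <- res$stations
  stations <- weather_stations()
  if (nrow(st) > 0L) {
    stations <- data.frame(id = st$id, name = st$name,
                           latitude = as.numeric(st$lat),
                           longitude = as.numeric(st$lon), stringsAsFactors = FALSE)
    stations <- stations[c_order(stations$id), , drop = FALSE]
    rownames(stations) <- NULL
  }
  wt <- res$weather
  obs <- weather_observations()
  if (nrow(wt) > 0L) {
    prop_rev <- stats::setNames(names(vocab$prop), unname(vocab$prop))
    obs <- data.frame(station_id = wt$station, date = wt$date,
                      variable = unname(prop_rev[wt$prop]),
                      value = as.numeric(wt$value), stringsAsFactors = FALSE)
    obs <- obs[c_order(obs$station_id, obs$date, obs$variable), , drop = FALSE]
    rownames(obs) <- NULL
  }
  list(stations = stations, observations = obs)
}
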