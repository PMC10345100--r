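#' Milestone data sources
#'
#' Every integration milestone runs identically over three kinds of
#' source: the in-memory model, serialized PPEO/AEMET graphs, or a SPARQL
#' engine loaded with the Turtle files. A source object records which; the
#' milestone functions convert it to the common tables first, so the
#' computation downstream is shared and the three routes are comparable
#' statement-for-statement.
#'
#' @param inv investigation; `records` observation records.
#' @return a `fp_source`.
#' @name milestone-sources
NULL

#' @rdname milestone-sources
#' @export
source_model <- function(inv, records = observation_records()) {
  structure(list(kind = "model", inv = inv, records = records,
                 domain = "phenotypic"), class = "fp_source")
}

#' @rdname milestone-sources
#' @param meta_graph,data_graph PPEO graphs (metadata, observations); the
#'   data graph may be a union over per-study files.
#' @param policy,vocab as used during serialization.
#' @export
source_graph <- function(meta_graph, data_graph = triple_graph(),
                         policy = uri_policy(), vocab = ppeo_vocabulary()) {
  structure(list(kind = "graph", meta = meta_graph, data = data_graph,
                 policy = policy, vocab = vocab, domain = "phenotypic"),
            class = "fp_source")
}

#' @rdname milestone-sources
#' @param ttl_files Turtle files to load into the engine.
#' @param python path to a python interpreter with rdflib (the SPARQL 1.1
#'   engine used as the local endpoint).
#' @export
source_sparql <- function(ttl_files, policy = uri_policy(),
                          vocab = ppeo_vocabulary(), python = find_python()) {
  missing <- ttl_files[!file.exists(ttl_files)]
  if (length(missing) > 0L)
    stop_fp("SPARQL source unreachable; missing file(s): %s",
            paste(missing, collapse = ", "))
  structure(list(kind = "sparql", files = ttl_files, policy = policy,
                 vocab = vocab, python = python, domain = "phenotypic",
                 cache = new.env(parent = emptyenv())),
            class = "fp_source")
}

#' @rdname milestone-sources
#' @param stations,observations weather tables.
#' @export
source_weather_model <- function(stations, observations) {
  structure(list(kind = "model", stations = stations,
                 observations = observations, domain = "weather"),
            class = "fp_source")
}

#' @rdname milestone-sources
#' @param graph an AEMET-style weather graph.
#' @export
source_weather_graph <- function(graph, policy = uri_policy(),
                                 vocab = aemet_vocabulary()) {
  structure(list(kind = "graph", meta = graph, policy = policy, vocab = vocab,
                 domain = "weather"), class = "fp_source")
}

#' @rdname milestone-sources
#' @export
source_weather_sparql <- function(ttl_files, policy = uri_policy(),
                                  vocab = aemet_vocabulary(),
                                  python = find_python()) {
  missing <- ttl_files[!file.exists(ttl_files)]
  if (length(missing) > 0L)
    stop_fp("weather SPARQL source unreachable; missing file(s): %s",
            paste(missing, collapse = ", "))
  structure(list(kind = "sparql", files = ttl_files, policy = policy,
                 vocab = vocab, python = python, domain = "weather",
                 cache = new.env(parent = emptyenv())),
            class = "fp_source")
}

#' @export
print.fp_source <- function(x, ...) {
  cat(sprintf("%s milestone source (%s)\n", x$domain, x$kind))
  invisible(x)
}

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop_fp("no python interpreter found for the SPARQL engine")
  unname(p)
}

# --- common-table extraction --------------------------------------------

as_pheno_tables <- function(source) {
  stopifnot(inherits(source, "fp_source"), source$domain == "phenotypic")
  switch(source$kind,
    model = list(inv = normalize_investigation(source$inv),
                 records = source$records),
    graph = list(inv = graph_to_investigation(source$meta, source$policy, source$vocab),
                 records = graph_to_observations(
                   graph_union(source$meta, source$data), source$policy, source$vocab)),
    sparql = {
      if (is.null(source$cache$tables))
        source$cache$tables <- sparql_pheno_tables(source)
      source$cache$tables
    })
}

as_weather_tables <- function(source) {
  stopifnot(inherits(source, "fp_source"), source$domain == "weather")
  switch(source$kind,
    model = list(stations = source$stations, observations = source$observations),
    graph = graph_to_weather(source$meta, source$policy, source$vocab),
    sparql = {
      if (is.null(source$cache$tables))
        source$cache$tables <- sparql_weather_tables(source)
      source$cache$tables
    })
}
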