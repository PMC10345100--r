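test_that("URI minting is injective, including ids needing percent-encoding", {
  pol <- uri_policy("https://example.org/base")
  ids <- c("plain", "a/b", "a b", "a%2Fb", "ü-umlaut", "a.b", "100%", "#frag")
  uris <- c(mint_uri(pol, "study", ids), mint_uri(pol, "unit", ids))
  expect_identical(anyDuplicated(uris), 0L)
  dec <- uri_decompose(pol, mint_uri(pol, "study", ids))
  expect_identical(dec$id, ids)
  expect_identical(unique(dec$type_tag), "study")
  expect_true(all(grepl("^https://example\\.org/base/", uris)))
  expect_error(mint_uri(pol, "study", ""), "empty id")
  expect_error(uri_policy("not-a-uri"), "absolute")
})

test_that("turtle serialization round-trips as a statement set and is deterministic", {
  fx <- generate_fixture(tiny_spec(41))
  g <- investigation_to_graph(fx$investigation)
  t1 <- serialize_turtle(g)
  t2 <- serialize_turtle(g)
  expect_identical(t1, t2)  # byte-identical
  g2 <- parse_turtle(text = t1)
  expect_identical(as.data.frame(g), as.data.frame(g2))
})

test_that("an empty graph serializes to a parseable prefix-only document", {
  txt <- serialize_turtle(triple_graph())
  g <- parse_turtle(text = txt)
  expect_identical(nrow(g), 0L)
})

test_that("the parser handles general turtle conveniences and flags bad input", {
  txt <- paste("@prefix ex: <http://ex.org/> .",
               "# a comment",
               "ex:s a ex:T ; ex:p \"a\\\"b\" , \"c\"@en ;",
               "  ex:q \"1.5\"^^<http://www.w3.org/2001/XMLSchema#decimal> .",
               sep = "\n")
  g <- parse_turtle(text = txt)
  expect_identical(nrow(g), 4L)
  expect_setequal(g$object[g$kind == "literal"], c("a\"b", "c", "1.5"))
  expect_error(parse_turtle(text = "<http://a> <http://b> ."), "line 1")
  expect_error(parse_turtle(text = "ex:s ex:p ex:o ."), "undeclared prefix")
})

test_that("model to graph to model is the identity on valid fixtures", {
  for (seed in c(42, 43, 44)) {
    fx <- generate_fixture(random_spec(seed))
    pol <- uri_policy()
    g <- investigation_to_graph(fx$investigation, pol)
    expect_equal(graph_to_investigation(g, pol),
                 normalize_investigation(fx$investigation))
  }
})

test_that("the full model-turtle-model loop including observations is lossless", {
  fx <- generate_fixture(tiny_spec(45))
  pol <- uri_policy()
  f <- withr::local_tempfile(fileext = ".ttl")
  serialize_turtle(investigation_to_graph(fx$investigation, pol), f)
  expect_equal(graph_to_investigation(parse_turtle(f), pol),
               normalize_investigation(fx$investigation))
  gd <- observations_to_graph(fx$records, fx$investigation, pol)
  serialize_turtle(gd, f)
  back <- graph_to_observations(parse_turtle(f), pol)
  key <- function(d) sort(paste(d$observation_unit_id, d$date, d$variable_id,
                                d$value, sep = "\r"))
  expect_identical(key(back), key(fx$records))
})

test_that("graph node counts follow section cardinalities", {
  fx <- generate_fixture(tiny_spec(46, n_studies = 5, total = 12, overlap = 4))
  inv <- fx$investigation
  g <- investigation_to_graph(inv)
  voc <- ppeo_vocabulary()
  count_type <- function(ty) sum(g$predicate ==
    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" & g$object == voc$type[[ty]])
  expect_identical(count_type("investigation"), 1L)
  expect_identical(count_type("study"), 5L)
  expect_identical(count_type("biological_material"), nrow(inv$biological_materials))
  expect_identical(count_type("observation_unit"), nrow(inv_units(inv)))
  gd <- observations_to_graph(fx$records, inv)
  expect_identical(count_type("observation"), 0L)
  expect_identical(sum(gd$predicate == voc$pred[["obs_value"]]), nrow(fx$records))
})

test_that("materials link to their declared source population", {
  fx <- generate_fixture(tiny_spec(47))
  g <- investigation_to_graph(fx$investigation)
  voc <- ppeo_vocabulary()
  src <- graph_match(g, p = voc$pred[["mat_source"]])
  expect_identical(nrow(src), nrow(fx$investigation$biological_materials))
  expect_identical(unique(src$object), "CxE")
})

test_that("mandatory shape elements are enforced when reading graphs", {
  fx <- generate_fixture(tiny_spec(48))
  g <- investigation_to_graph(fx$investigation)
  voc <- ppeo_vocabulary()
  df <- as.data.frame(g)
  df <- df[df$predicate != voc$pred[["miappe_version"]], , drop = FALSE]
  expect_error(graph_to_investigation(triple_graph(df)), "hasMiappeVersion")
})

test_that("weather graphs carry recoverable station coordinates", {
  fx <- generate_fixture(tiny_spec(49))
  g <- weather_to_graph(fx$stations, fx$weather)
  back <- graph_to_weather(g)
  ord <- order(fx$stations$id, method = "radix")
  expect_equal(back$stations, fx$stations[ord, ], ignore_attr = TRUE)
  expect_equal(back$observations, fx$weather)
  bad <- fx$weather
  bad$station_id[1] <- "WS_ghost"
  expect_error(weather_to_graph(fx$stations, bad), "WS_ghost")
})

test_that("an independent RDF engine parses our turtle to the same statement count", {
  fx <- generate_fixture(tiny_spec(50))
  g <- investigation_to_graph(fx$investigation)
  f <- withr::local_tempfile(fileext = ".ttl")
  serialize_turtle(g, f)
  py <- Sys.which("python")
  out <- system2(py, c("-c", shQuote(sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='turtle'); print(len(g))",
    f))), stdout = TRUE)
  expect_identical(as.integer(out[length(out)]), nrow(g))
})
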