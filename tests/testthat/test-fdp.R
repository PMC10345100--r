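chain_nodes <- function() list(
  fdp_node("fdp", "fdp_root", title = "Root"),
  fdp_node("cat1", "catalog", title = "Cat", theme = "phenotypic", parent = "fdp"),
  fdp_node("ds1", "dataset", title = "Data", parent = "cat1"),
  fdp_node("dist1", "distribution", title = "TTL", parent = "ds1",
           media_type = "text/turtle", access_url = "file:///x.ttl"))

test_that("a root-catalog-dataset-distribution chain builds and navigates", {
  tree <- build_fdp(chain_nodes())
  expect_identical(tree$root, "fdp")
  expect_identical(tree$nodes[["fdp"]]$children, "cat1")
  expect_identical(tree$nodes[["dist1"]]$parent, "ds1")
})

test_that("orphans, level skips, cycles and double roots are refused by name", {
  n <- chain_nodes()
  expect_error(build_fdp(n[c(1, 2, 4)]), "dist1")      # skip: distribution under catalog? missing parent
  bad <- c(n, list(fdp_node("lost", "dataset", parent = NA)))
  expect_error(build_fdp(bad), "orphan node 'lost'")
  skip_lvl <- list(n[[1]], fdp_node("d", "dataset", parent = "fdp"))
  expect_error(build_fdp(skip_lvl), "skips a level")
  expect_error(build_fdp(c(n, list(fdp_node("fdp2", "fdp_root")))),
               "exactly one fdp_root")
  expect_error(build_fdp(c(n, n[3])), "duplicate")
})

test_that("MIAPPE embedding is restricted to the dataset level", {
  expect_error(fdp_node("c", "catalog", embedded_investigation = minimal_inv()),
               "dataset level")
  nd <- fdp_node("ds", "dataset", embedded_investigation = minimal_inv())
  g <- embed_investigation(nd)
  expect_gt(nrow(g), 0)
  nd2 <- fdp_node("dist", "distribution")
  expect_error(embed_investigation(nd2), "dataset-level only")
})

test_that("the dataset document holds both generic and MIAPPE parts", {
  fx <- generate_fixture(tiny_spec(61))
  d <- withr::local_tempdir()
  out <- cmd_fdp(list(fx$investigation), d)
  doc <- parse_turtle(file.path(d, "dataset-1.ttl"))
  # generic DCAT2-compatible block
  expect_true(any(doc$predicate == "http://purl.org/dc/terms/title"))
  expect_true(any(doc$predicate == "http://www.w3.org/ns/dcat#distribution"))
  # MIAPPE block: study summaries present, count matching the investigation
  voc <- ppeo_vocabulary()
  study_nodes <- doc$subject[doc$predicate ==
    "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" & doc$object == voc$type[["study"]]]
  expect_identical(length(study_nodes), length(fx$investigation$studies))
})

test_that("the paper-shaped FDP has three catalogs and a SPARQL distribution", {
  fx <- generate_fixture(tiny_spec(62))
  d <- withr::local_tempdir()
  out <- cmd_fdp(list(fx$investigation), d,
                 endpoint_url = "http://localhost:3030/pheno/sparql")
  cats <- Filter(function(n) n$level == "catalog", out$tree$nodes)
  expect_setequal(vapply(cats, `[[`, "", "theme"),
                  c("phenotypic", "genotypic", "genomic"))
  doc <- parse_turtle(file.path(d, "dataset-1-sparql.ttl"))
  expect_true("http://localhost:3030/pheno/sparql" %in% doc$object)
})

test_that("crawling the emitted documents reconstructs the tree", {
  fx <- generate_fixture(tiny_spec(63))
  d <- withr::local_tempdir()
  out <- cmd_fdp(list(fx$investigation), d)
  cr <- cmd_fdp_crawl(d)
  expect_equal(fdp_skeleton(cr$tree), fdp_skeleton(out$tree))
  expect_length(cr$warnings, 0)
})

test_that("crawl(emit(tree)) is the identity on random synthetic trees", {
  for (seed in c(64, 65, 66)) {
    set.seed(seed)
    nodes <- list(fdp_node("fdp", "fdp_root", title = "R"))
    for (ci in seq_len(sample(1:3, 1))) {
      cid <- paste0("c", ci)
      nodes <- c(nodes, list(fdp_node(cid, "catalog", title = cid,
                                      theme = sample(c("phenotypic", "genomic"), 1),
                                      parent = "fdp")))
      for (di in seq_len(sample(0:3, 1))) {
        did <- paste0(cid, "d", di)
        nodes <- c(nodes, list(fdp_node(did, "dataset", title = did, parent = cid)))
        for (xi in seq_len(sample(0:2, 1)))
          nodes <- c(nodes, list(fdp_node(paste0(did, "x", xi), "distribution",
                                          parent = did, media_type = "text/turtle")))
      }
    }
    tree <- build_fdp(nodes)
    d <- withr::local_tempdir()
    emit_fdp_documents(tree, d)
    cr <- cmd_fdp_crawl(d)
    expect_equal(fdp_skeleton(cr$tree), fdp_skeleton(tree))
    # every leaf reachable from root (closure holds by construction of crawl)
    expect_setequal(names(cr$tree$nodes), names(tree$nodes))
  }
})

test_that("crawl tolerates unreachable children and fails on unreachable root", {
  tree <- build_fdp(chain_nodes())
  d <- withr::local_tempdir()
  emit_fdp_documents(tree, d)
  unlink(file.path(d, "ds1.ttl"))
  cr <- cmd_fdp_crawl(d)
  expect_true(any(grepl("ds1", cr$warnings)))
  expect_error(crawl_fdp("fdp", fetch = function(id) stop("down")), "unreachable")
})

test_that("datasets are selectable from embedded descriptors alone", {
  fx <- generate_fixture(tiny_spec(67))
  other <- minimal_inv()
  d <- withr::local_tempdir()
  out <- cmd_fdp(list(other, fx$investigation), d)
  cr <- cmd_fdp_crawl(d)
  hit <- discover_datasets(cr, function(s) "tubweight" %in% s$variable_ids)
  expect_identical(hit, "dataset-2")
  s <- cr$summaries[[hit]]
  expect_identical(s$title, fx$investigation$title)
  expect_identical(s$study_ids,
                   sort(vapply(fx$investigation$studies, `[[`, "", "id"),
                        method = "radix"))
  expect_identical(s$variable_ids,
                   sort(fx$investigation$observed_variables$id, method = "radix"))
  expect_identical(s$material_count, nrow(fx$investigation$biological_materials))
})
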