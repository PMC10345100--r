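#' FAIR Data Point hierarchy
#'
#' A FAIR Data Point (FDP) publishes metadata as a four-level tree — FDP
#' root, catalogs, datasets, distributions — each level a linked-data
#' document that names both its parent and its children, so humans and
#' machine agents can navigate in either direction, progressively
#' harvesting metadata without touching the data itself.
#'
#' The generic per-level predicates are DCAT2-compatible (title,
#' description, theme, license, dataset/distribution links, access URL,
#' media type), so non-MIAPPE-aware harvesters degrade gracefully. The
#' extension this package implements is dataset-level embedding of a
#' MIAPPE investigation summary: enough content metadata (investigation,
#' studies, variables, materials) to decide whether a dataset is relevant
#' without opening any distribution.
#'
#' @name fdp-layer
NULL

FDP_NS <- "https://w3id.org/fairphen/fdp#"
DCT <- "http://purl.org/dc/terms/"
DCAT <- "http://www.w3.org/ns/dcat#"

fdp_levels <- function() c("fdp_root", "catalog", "dataset", "distribution")

#' Construct one FDP node
#' @param id node identifier (unique within the tree; used in locators).
#' @param level one of `"fdp_root"`, `"catalog"`, `"dataset"`,
#'   `"distribution"`.
#' @param title,description free text.
#' @param theme free-text tag (e.g. `"phenotypic"`).
#' @param parent parent node id (`NA` for the root).
#' @param license license identifier.
#' @param media_type,access_url distribution access pair: media type plus
#'   file or SPARQL-endpoint locator (distributions only).
#' @param embedded_investigation an [miappe_investigation()] whose summary
#'   is embedded in the node document (datasets only).
#' @return an `fp_fdp_node`.
#' @export
fdp_node <- function(id, level, title = "", description = "", theme = NA,
                     parent = NA, license = NA, media_type = NA,
                     access_url = NA, embedded_investigation = NULL) {
  if (!(level %in% fdp_levels()))
    stop_fp("unknown FDP level '%s'", level)
  if (!is.null(embedded_investigation) && level != "dataset")
    stop_fp("node '%s': MIAPPE metadata can only be embedded at the dataset level", id)
  structure(list(id = chr1(id), level = level, title = chr1(title),
                 description = chr1(description), theme = chr1(theme),
                 parent = chr1(parent), license = chr1(license),
                 media_type = chr1(media_type), access_url = chr1(access_url),
                 embedded_investigation = embedded_investigation),
            class = "fp_fdp_node")
}

#' Assemble and validate an FDP tree
#'
#' Checks the navigation closure: exactly one root with no parent, every
#' non-root with exactly one existing parent whose level is one step
#' coarser (no level skips), no cycles, no orphans. Children lists are
#' derived from the parent links and sorted.
#'
#' @param nodes list of [fdp_node()] objects.
#' @return an `fp_fdp_tree`: named list of nodes (by id) with a `children`
#'   field added, plus the root id.
#' @export
build_fdp <- function(nodes) {
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_fp("duplicate FDP node id(s): %s",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(nodes) <- ids
  lev <- vapply(nodes, `[[`, "", "level")
  roots <- ids[lev == "fdp_root"]
  if (length(roots) != 1L)
    stop_fp("an FDP tree needs exactly one fdp_root node, found %d", length(roots))
  rank <- stats::setNames(seq_along(fdp_levels()), fdp_levels())
  for (n in nodes) {
    if (n$level == "fdp_root") {
      if (!is.na(n$parent)) stop_fp("root node '%s' must not have a parent", n$id)
      next
    }
    if (is.na(n$parent)) stop_fp("orphan node '%s': non-root nodes need a parent", n$id)
    p <- nodes[[n$parent]]
    if (is.null(p)) stop_fp("node '%s' references missing parent '%s'", n$id, n$parent)
    if (rank[[n$level]] != rank[[p$level]] + 1L)
      stop_fp("node '%s' (%s) skips a level under parent '%s' (%s)",
              n$id, n$level, p$id, p$level)
  }
  # cycle check: walk each node to the root
  for (n in nodes) {
    seen <- character(0); cur <- n$id
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) stop_fp("cycle in FDP tree at node '%s'", cur)
      seen <- c(seen, cur)
      cur <- nodes[[cur]]$parent
    }
  }
  for (i in seq_along(nodes)) nodes[[i]]$children <- character(0)
  for (n in nodes) if (!is.na(n$parent))
    nodes[[n$parent]]$children <- c_sort(c(nodes[[n$parent]]$children, n$id))
  structure(list(nodes = nodes, root = roots), class = "fp_fdp_tree")
}

#' @export
print.fp_fdp_tree <- function(x, ...) {
  lev <- vapply(x$nodes, `[[`, "", "level")
  cat(sprintf("FDP tree: %d node(s) (%s)\n", length(x$nodes),
              paste(sprintf("%d %s", table(lev)[fdp_levels()][!is.na(table(lev)[fdp_levels()])],
                            names(table(lev)[fdp_levels()])[!is.na(table(lev)[fdp_levels()])]),
                    collapse = ", ")))
  invisible(x)
}

fdp_uri <- function(policy, id) mint_uri(policy, "fdp", id)

#' Embed a MIAPPE summary into a dataset document
#'
#' Produces the dataset-level metadata graph with its two distinguishable
#' parts: (a) the generic DCAT2-compatible resource metadata of the FDP
#' dataset specification, and (b) the embedded MIAPPE content summary —
#' investigation id/title/description, one summary node per study (id,
#' title, country, dates), the observed-variable id list and the
#' biological-material count. The only cross link between the two parts is
#' Dataset ↔ Investigation; no other alignment (distribution–study and
#' the like) carries meaning, so none is emitted.
#'
#' @param node a dataset-level [fdp_node()] with an
#'   `embedded_investigation`.
#' @param policy a [uri_policy()].
#' @param vocab a [ppeo_vocabulary()].
#' @return an `fp_graph` (the MIAPPE block plus the cross link).
#' @export
embed_investigation <- function(node, policy = uri_policy(),
                                vocab = ppeo_vocabulary()) {
  if (node$level != "dataset")
    stop_fp("node '%s' is a %s: MIAPPE embedding is dataset-level only",
            node$id, node$level)
  inv <- node$embedded_investigation
  if (is.null(inv)) stop_fp("node '%s' has no embedded investigation", node$id)
  inv <- normalize_investigation(inv)
  P <- vocab$pred
  du <- fdp_uri(policy, node$id)
  iu <- mint_uri(policy, "investigation", inv$id)
  tr <- list(
    st_uri(du, paste0(FDP_NS, "hasMiappeInvestigation"), iu),
    st_uri(iu, RDF_TYPE, vocab$type[["investigation"]]),
    st_lit(iu, P[["identifier"]], inv$id),
    lit_str(iu, P[["title"]], inv$title),
    lit_str(iu, P[["description"]], inv$description),
    st_lit(iu, P[["miappe_version"]], inv$miappe_version),
    st_lit(iu, paste0(FDP_NS, "materialCount"),
           fmt_num(nrow(inv$biological_materials)), xsd_t("integer")))
  for (s in inv$studies) {
    su <- mint_uri(policy, "study", s$id)
    tr <- c(tr, list(
      st_uri(iu, P[["has_study"]], su),
      st_uri(su, RDF_TYPE, vocab$type[["study"]]),
      st_lit(su, P[["identifier"]], s$id),
      lit_str(su, P[["title"]], s$title),
      lit_str(su, P[["country_code"]], s$country_code),
      lit_date(su, P[["start_date"]], s$start_date),
      lit_date(su, P[["end_date"]], s$end_date)))
  }
  for (i in seq_len(nrow(inv$observed_variables))) {
    vu <- mint_uri(policy, "variable", inv$observed_variables$id[i])
    tr <- c(tr, list(
      st_uri(iu, P[["has_variable"]], vu),
      st_uri(vu, RDF_TYPE, vocab$type[["observed_variable"]]),
      st_lit(vu, P[["identifier"]], inv$observed_variables$id[i]),
      lit_str(vu, P[["var_name"]], inv$observed_variables$name[i])))
  }
  triple_graph(rbind_all(tr, triples_proto()))
}

#' Emit the Turtle document for one FDP node
#'
#' Deterministic Turtle holding the node's own metadata, a link to its
#' parent (if any) and to every child, the distribution access pair where
#' applicable, and — for datasets with an embedded investigation — the
#' MIAPPE summary block of [embed_investigation()].
#' @param tree an `fp_fdp_tree`.
#' @param id node id.
#' @param policy a [uri_policy()].
#' @param vocab a [ppeo_vocabulary()] for the embedded block.
#' @return Turtle text.
#' @export
emit_level_document <- function(tree, id, policy = uri_policy(),
                                vocab = ppeo_vocabulary()) {
  node <- tree$nodes[[id]]
  if (is.null(node)) stop_fp("unknown FDP node '%s'", id)
  nu <- fdp_uri(policy, node$id)
  type_uri <- c(fdp_root = paste0(FDP_NS, "FairDataPoint"),
                catalog = paste0(DCAT, "Catalog"),
                dataset = paste0(DCAT, "Dataset"),
                distribution = paste0(DCAT, "Distribution"))[[node$level]]
  child_pred <- c(fdp_root = paste0(DCAT, "catalog"),
                  catalog = paste0(DCAT, "dataset"),
                  dataset = paste0(DCAT, "distribution"))
  tr <- list(
    st_uri(nu, RDF_TYPE, type_uri),
    st_lit(nu, paste0(FDP_NS, "nodeId"), node$id),
    lit_str(nu, paste0(DCT, "title"), node$title),
    lit_str(nu, paste0(DCT, "description"), node$description),
    lit_str(nu, paste0(DCAT, "theme"), node$theme),
    lit_str(nu, paste0(DCT, "license"), node$license))
  if (!is.na(node$parent))
    tr <- c(tr, list(st_uri(nu, paste0(DCT, "isPartOf"), fdp_uri(policy, node$parent))))
  for (ch in node$children)
    tr <- c(tr, list(st_uri(nu, child_pred[[node$level]], fdp_uri(policy, ch))))
  if (node$level == "distribution") {
    tr <- c(tr, list(lit_str(nu, paste0(DCAT, "mediaType"), node$media_type)))
    if (!is.na(node$access_url))
      tr <- c(tr, list(st_uri(nu, paste0(DCAT, "accessURL"), node$access_url)))
  }
  g <- triple_graph(rbind_all(tr, triples_proto()))
  if (node$level == "dataset" && !is.null(node$embedded_investigation))
    g <- graph_union(g, embed_investigation(node, policy, vocab))
  serialize_turtle(g)
}

#' Write every node document of an FDP tree
#' @param tree an `fp_fdp_tree`.
#' @param dir target directory; one `<node id>.ttl` per node.
#' @param policy,vocab as for [emit_level_document()].
#' @return named character vector of file paths.
#' @export
emit_fdp_documents <- function(tree, dir, policy = uri_policy(),
                               vocab = ppeo_vocabulary()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(tree$nodes)
  paths <- stats::setNames(file.path(dir, paste0(pct_encode(ids), ".ttl")), ids)
  for (id in ids) {
    con <- file(paths[[id]], open = "wb")
    writeLines(emit_level_document(tree, id, policy, vocab), con, sep = "",
               useBytes = TRUE)
    close(con)
  }
  paths
}

#' Crawl an FDP from its root document
#'
#' Breadth-first navigation from the root, fetching each node's Turtle
#' document with `fetch(locator)` and following child links — exactly what
#' a harvesting agent does. Unreachable children are tolerated and
#' recorded as warnings; an unreachable root is an error. Dataset nodes
#' contribute a MIAPPE summary (investigation id/title, study ids,
#' variable ids, material count) harvested purely from the embedded
#' metadata, never from distributions.
#'
#' @param root_id id of the root node.
#' @param fetch function(node id) -> Turtle text (e.g. reading
#'   `<id>.ttl` from a directory, or an HTTP GET).
#' @param policy a [uri_policy()].
#' @param vocab a [ppeo_vocabulary()].
#' @return list with `tree` (an `fp_fdp_tree` re-assembled from the
#'   documents), `summaries` (per-dataset MIAPPE summaries) and
#'   `warnings` (unreachable children).
#' @export
crawl_fdp <- function(root_id, fetch, policy = uri_policy(),
                      vocab = ppeo_vocabulary()) {
  P <- vocab$pred
  get_doc <- function(id) {
    txt <- tryCatch(fetch(id), error = function(e) NULL)
    if (is.null(txt)) return(NULL)
    parse_turtle(text = txt)
  }
  root_doc <- get_doc(root_id)
  if (is.null(root_doc)) stop_fp("FDP root '%s' is unreachable", root_id)
  type_rev <- c(stats::setNames("fdp_root", paste0(FDP_NS, "FairDataPoint")),
                stats::setNames("catalog", paste0(DCAT, "Catalog")),
                stats::setNames("dataset", paste0(DCAT, "Dataset")),
                stats::setNames("distribution", paste0(DCAT, "Distribution")))
  child_preds <- paste0(DCAT, c("catalog", "dataset", "distribution"))
  nodes <- list(); summaries <- list(); warns <- character(0)
  queue <- root_id; seen <- character(0)
  while (length(queue) > 0L) {
    id <- queue[1]; queue <- queue[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    doc <- if (id == root_id) root_doc else get_doc(id)
    if (is.null(doc)) { warns <- c(warns, sprintf("unreachable node '%s'", id)); next }
    nu <- fdp_uri(policy, id)
    type <- graph_match(doc, s = nu, p = RDF_TYPE)$object
    level <- type_rev[type[type %in% names(type_rev)]][1]
    if (is.na(level)) stop_fp("document for '%s' has no recognizable FDP level", id)
    parent_uri <- g_value(doc, nu, paste0(DCT, "isPartOf"))
    kids <- unlist(lapply(child_preds, function(p) graph_match(doc, s = nu, p = p)$object))
    kid_ids <- if (length(kids)) uri_decompose(policy, kids)$id else character(0)
    nodes[[id]] <- fdp_node(
      id = id, level = level,
      title = g_value(doc, nu, paste0(DCT, "title")) %|NA|% "",
      description = g_value(doc, nu, paste0(DCT, "description")) %|NA|% "",
      theme = g_value(doc, nu, paste0(DCAT, "theme")),
      parent = if (is.na(parent_uri)) NA else uri_decompose(policy, parent_uri)$id,
      license = g_value(doc, nu, paste0(DCT, "license")),
      media_type = g_value(doc, nu, paste0(DCAT, "mediaType")),
      access_url = g_value(doc, nu, paste0(DCAT, "accessURL")))
    if (level == "dataset") {
      iu <- g_value(doc, nu, paste0(FDP_NS, "hasMiappeInvestigation"))
      if (!is.na(iu)) {
        studies <- c_sort(graph_match(doc, s = iu, p = P[["has_study"]])$object)
        vars <- c_sort(graph_match(doc, s = iu, p = P[["has_variable"]])$object)
        summaries[[id]] <- list(
          investigation_id = g_value(doc, iu, P[["identifier"]], required = TRUE),
          title = g_value(doc, iu, P[["title"]]),
          description = g_value(doc, iu, P[["description"]]),
          miappe_version = g_value(doc, iu, P[["miappe_version"]]),
          study_ids = c_sort(unname(vapply(studies, function(su)
            g_value(doc, su, P[["identifier"]], required = TRUE), ""))),
          variable_ids = c_sort(unname(vapply(vars, function(vu)
            g_value(doc, vu, P[["identifier"]], required = TRUE), ""))),
          material_count = as.integer(g_value(doc, iu, paste0(FDP_NS, "materialCount"))))
      }
    }
    queue <- c(queue, setdiff(kid_ids, seen))
  }
  list(tree = build_fdp(unname(nodes)), summaries = summaries, warnings = warns)
}

`%|NA|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

#' Select datasets by their embedded MIAPPE summary
#'
#' The discovery milestone: filter a crawl's dataset summaries with a
#' predicate over content descriptors only (title, study ids, variable
#' ids) — never by opening distributions.
#' @param crawl a [crawl_fdp()] result.
#' @param predicate function(summary) -> logical.
#' @return character vector of matching dataset node ids.
#' @export
discover_datasets <- function(crawl, predicate) {
  hits <- vapply(crawl$summaries, function(s) isTRUE(predicate(s)), logical(1))
  c_sort(names(crawl$summaries)[hits])
}

#' Canonical comparable form of an FDP tree
#'
#' Reduces each node to its structural and descriptive fields (dropping
#' the full embedded investigation, which the documents carry only as a
#' summary), so that `crawl(emit(tree))` can be compared to `tree`.
#' @param tree an `fp_fdp_tree`.
#' @return data frame, one row per node, sorted by id.
#' @export
fdp_skeleton <- function(tree) {
  rows <- lapply(tree$nodes, function(n) data.frame(
    id = n$id, level = n$level,
    title = if (is.na(n$title)) "" else n$title,
    description = if (is.na(n$description)) "" else n$description,
    theme = n$theme, parent = n$parent, license = n$license,
    media_type = n$media_type, access_url = n$access_url,
    children = join_multi(n$children), stringsAsFactors = FALSE))
  out <- rbind_all(unname(rows), empty_df(id = "character"))
  out <- out[c_order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
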