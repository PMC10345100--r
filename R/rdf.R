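#' Triple graphs and Turtle
#'
#' A triple graph is a set of (subject, predicate, object) statements held
#' as a data frame with columns `subject`, `predicate`, `object`, `kind`
#' (`"uri"` or `"literal"`) and `dtype` (datatype IRI for typed literals,
#' `NA` for URIs and plain strings). Set semantics: duplicate statements
#' collapse and the row order is canonical, so two graphs are equal exactly
#' when their data frames are identical.
#'
#' Serialization uses Turtle restricted to one statement per line with
#' full or prefixed IRIs — deterministic (sorted) for diff-ability, and
#' valid Turtle for any conformant parser. Blank nodes are never emitted:
#' every node carries a minted URI, as stable references are what makes a
#' graph harvestable.
#'
#' @name triple-graph
NULL

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

triples_proto <- function() empty_df(subject = "character", predicate = "character",
                                     object = "character", kind = "character",
                                     dtype = "character")

#' Construct a triple graph
#' @param df data frame with columns `subject`, `predicate`, `object`,
#'   `kind`, `dtype`; defaults to empty.
#' @return an `fp_graph`.
#' @export
triple_graph <- function(df = triples_proto()) {
  df <- df[, names(triples_proto()), drop = FALSE]
  df <- unique(df)
  df <- df[c_order(df$subject, df$predicate, df$kind, df$object, df$dtype), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("fp_graph", "data.frame"))
}

#' @export
print.fp_graph <- function(x, ...) {
  cat(sprintf("triple graph: %d statement(s), %d subject(s)\n",
              nrow(x), length(unique(x$subject))))
  invisible(x)
}

#' Merge triple graphs
#' @param ... `fp_graph` objects.
#' @return their union as an `fp_graph`.
#' @export
graph_union <- function(...) {
  gs <- list(...)
  triple_graph(do.call(rbind, c(lapply(gs, as.data.frame), list(make.row.names = FALSE))))
}

# statement builders -----------------------------------------------------
st_uri <- function(s, p, o) data.frame(subject = s, predicate = p, object = o,
                                       kind = "uri", dtype = NA_character_,
                                       stringsAsFactors = FALSE)
st_lit <- function(s, p, o, dtype = NA_character_)
  data.frame(subject = s, predicate = p, object = as.character(o),
             kind = "literal", dtype = dtype, stringsAsFactors = FALSE)

#' Match statements by pattern
#'
#' `NULL` components are wildcards. The workhorse behind every graph-backed
#' milestone computation.
#' @param g an `fp_graph`.
#' @param s,p,o subject / predicate / object to match (`o` matches the
#'   lexical value for literals and the IRI for URIs).
#' @return the matching rows as a data frame.
#' @export
graph_match <- function(g, s = NULL, p = NULL, o = NULL) {
  keep <- rep(TRUE, nrow(g))
  if (!is.null(s)) keep <- keep & g$subject %in% s
  if (!is.null(p)) keep <- keep & g$predicate %in% p
  if (!is.null(o)) keep <- keep & g$object %in% o
  out <- as.data.frame(g)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# single literal value (NA when absent); errors on multiplicity
g_value <- function(g, s, p, required = FALSE) {
  m <- graph_match(g, s = s, p = p)
  if (nrow(m) == 0L) {
    if (required) stop_fp("missing mandatory predicate <%s> on <%s>", p, s)
    return(NA_character_)
  }
  if (nrow(m) > 1L) stop_fp("predicate <%s> on <%s> is not single-valued", p, s)
  m$object
}
g_values <- function(g, s, p) c_sort(graph_match(g, s = s, p = p)$object)
g_num <- function(g, s, p) {
  v <- g_value(g, s, p)
  if (is.na(v)) NA_real_ else as.numeric(v)
}
g_subjects_of_type <- function(g, type_uri) {
  c_sort(unique(graph_match(g, p = RDF_TYPE, o = type_uri)$subject))
}

# Turtle ------------------------------------------------------------------

default_prefixes <- function() c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  xsd = XSD,
  ppeo = "http://purl.org/ppeo/PPEO.owl#",
  aemet = "http://aemet.linkeddata.es/ontology#",
  geo = "http://www.w3.org/2003/01/geo/wgs84_pos#",
  dct = "http://purl.org/dc/terms/",
  dcat = "http://www.w3.org/ns/dcat#")

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}
unescape_lit <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    buf <- character(0); j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", "\\" = "\\",
                             "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch); j <- j + 1L
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

shorten <- function(iri, prefixes) {
  for (pf in names(prefixes)) {
    ns <- prefixes[[pf]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local) && !endsWith(local, "."))
        return(paste0(pf, ":", local))
    }
  }
  paste0("<", iri, ">")
}

#' Serialize a triple graph to Turtle
#'
#' Deterministic: prefixes in fixed order, statements sorted; serializing
#' the same graph twice yields byte-identical files.
#' @param g an `fp_graph`.
#' @param path target file; `NULL` returns the text instead.
#' @param prefixes named character vector of prefix -> namespace.
#' @return `path` invisibly, or the Turtle text when `path` is `NULL`.
#' @export
serialize_turtle <- function(g, path = NULL, prefixes = default_prefixes()) {
  term <- function(iri) shorten(iri, prefixes)
  obj <- ifelse(g$kind == "uri", vapply(g$object, term, ""),
                paste0("\"", escape_lit(g$object), "\"",
                       ifelse(is.na(g$dtype), "",
                              paste0("^^", vapply(ifelse(is.na(g$dtype), XSD, g$dtype),
                                                  term, "")))))
  lines <- c(paste0("@prefix ", names(prefixes), ": <", prefixes, "> ."), "",
             if (nrow(g)) paste0("<", g$subject, "> ",
                                 vapply(g$predicate, term, ""), " ", obj, " ."))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "", useBytes = TRUE)
  invisible(path)
}

# scan one RDF term at the head of `s`; returns list(kind, value, dtype, rest)
scan_term <- function(s, prefixes, lineno) {
  s <- sub("^\\s+", "", s)
  if (startsWith(s, "<")) {
    end <- regexpr(">", s, fixed = TRUE)
    if (end < 0) stop_fp("line %d: unterminated IRI", lineno)
    return(list(kind = "uri", value = substr(s, 2L, end - 1L), dtype = NA_character_,
                rest = substring(s, end + 1L)))
  }
  if (startsWith(s, "\"")) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    j <- 2L
    while (j <= length(chars)) {
      if (chars[j] == "\\") { j <- j + 2L; next }
      if (chars[j] == "\"") break
      j <- j + 1L
    }
    if (j > length(chars)) stop_fp("line %d: unterminated literal", lineno)
    lex <- unescape_lit(substr(s, 2L, j - 1L))
    rest <- substring(s, j + 1L)
    dtype <- NA_character_
    if (startsWith(rest, "^^")) {
      t <- scan_term(substring(rest, 3L), prefixes, lineno)
      dtype <- t$value; rest <- t$rest
    } else if (grepl("^@[A-Za-z-]+", rest)) {
      rest <- sub("^@[A-Za-z-]+", "", rest)
    }
    return(list(kind = "literal", value = lex, dtype = dtype, rest = rest))
  }
  m <- regmatches(s, regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z_][A-Za-z0-9_.-]*", s))
  if (length(m) == 1L) {
    parts <- strsplit(m, ":", fixed = TRUE)[[1]]
    ns <- prefixes[[parts[1]]]
    if (is.null(ns)) stop_fp("line %d: undeclared prefix '%s'", lineno, parts[1])
    return(list(kind = "uri", value = paste0(ns, parts[2]), dtype = NA_character_,
                rest = substring(s, nchar(m) + 1L)))
  }
  if (startsWith(s, "a ") || s == "a")
    return(list(kind = "uri", value = RDF_TYPE, dtype = NA_character_,
                rest = substring(s, 2L)))
  stop_fp("line %d: cannot parse term near '%s'", lineno, substr(s, 1, 30))
}

#' Parse a Turtle file
#'
#' Accepts the line-oriented Turtle this package emits plus the common
#' conveniences: `@prefix` declarations, prefixed names, `a` for
#' `rdf:type`, comments, language tags, and `;` / `,` continuation lists.
#' Malformed input fails with the offending line number.
#' @param path file path, or `text =` a character scalar.
#' @param text Turtle text (alternative to `path`).
#' @return an `fp_graph`.
#' @export
parse_turtle <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, encoding = "UTF-8")
           else strsplit(text, "\n", fixed = TRUE)[[1]]
  prefixes <- list()
  rows <- list()
  subj <- NULL; pred <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^@prefix", ln)) {
      m <- regmatches(ln, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_.-]*)?:\\s*<([^>]*)>\\s*\\.$", ln))[[1]]
      if (length(m) == 0L) stop_fp("line %d: malformed @prefix", i)
      prefixes[[m[2]]] <- m[3]
      next
    }
    repeat {
      if (is.null(subj)) {
        t <- scan_term(ln, prefixes, i); subj <- t$value; ln <- t$rest
        if (t$kind != "uri") stop_fp("line %d: subject must be an IRI", i)
        t <- scan_term(ln, prefixes, i); pred <- t$value; ln <- t$rest
      } else if (is.null(pred)) {
        t <- scan_term(ln, prefixes, i); pred <- t$value; ln <- t$rest
      }
      t <- scan_term(ln, prefixes, i); ln <- sub("^\\s+", "", t$rest)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, predicate = pred, object = t$value, kind = t$kind,
        dtype = t$dtype, stringsAsFactors = FALSE)
      if (startsWith(ln, ",")) { ln <- substring(ln, 2L); next }
      if (startsWith(ln, ";")) { pred <- NULL; ln <- sub("^;\\s*", "", ln)
        if (!nzchar(ln)) break else next }
      if (startsWith(ln, ".")) { subj <- NULL; pred <- NULL
        ln <- sub("^\\.\\s*", "", ln)
        if (!nzchar(ln)) break else next }
      if (!nzchar(ln)) break
      stop_fp("line %d: unexpected trailing content '%s'", i, substr(ln, 1, 30))
    }
  }
  if (!is.null(subj)) stop_fp("unterminated statement at end of input")
  triple_graph(rbind_all(rows, triples_proto()))
}

# URI policy ---------------------------------------------------------------

#' URI minting policy
#'
#' Every model object gets a minted absolute URI
#' `base/{type-tag}/{percent-encoded id}`. Minting is injective on
#' (type-tag, id) because the id is percent-encoded (no unescaped `/` can
#' collide) and type tags are distinct path segments.
#' @param base_uri absolute URI prefix ending in `/` (added if missing).
#' @return a `fp_uri_policy`.
#' @export
uri_policy <- function(base_uri = "https://fairphen.example.org/id/") {
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", base_uri))
    stop_fp("base_uri must be an absolute URI: %s", base_uri)
  if (!endsWith(base_uri, "/")) base_uri <- paste0(base_uri, "/")
  structure(list(base_uri = base_uri), class = "fp_uri_policy")
}

# RFC 3986 percent-encoding over UTF-8 bytes; unreserved characters only
# (utils::URLencode leaves '%' alone, which would break injectivity)
pct_encode <- function(x) vapply(x, function(v) {
  b <- as.integer(charToRaw(enc2utf8(v)))
  unres <- (b >= 0x30 & b <= 0x39) | (b >= 0x41 & b <= 0x5A) |
    (b >= 0x61 & b <= 0x7A) | b %in% c(0x2D, 0x2E, 0x5F, 0x7E)
  paste(ifelse(unres, vapply(b, function(i) rawToChar(as.raw(i)), ""),
               sprintf("%%%02X", b)), collapse = "")
}, character(1), USE.NAMES = FALSE)
pct_decode <- function(x) vapply(x, function(v) {
  out <- utils::URLdecode(v)
  Encoding(out) <- "UTF-8"
  out
}, character(1), USE.NAMES = FALSE)

#' Mint a URI for a model object
#' @param policy a [uri_policy()].
#' @param type_tag short object-kind tag (e.g. `"study"`).
#' @param id object identifier (any string; percent-encoded).
#' @return absolute URI string (vectorized over `id`).
#' @export
mint_uri <- function(policy, type_tag, id) {
  if (any(is.na(id) | !nzchar(id))) stop_fp("cannot mint a URI for an empty id")
  paste0(policy$base_uri, type_tag, "/", pct_encode(id))
}

#' Invert a minted URI
#' @param policy the [uri_policy()] that minted it.
#' @param uri minted URI (vectorized).
#' @return data frame with columns `type_tag`, `id`.
#' @export
uri_decompose <- function(policy, uri) {
  if (!all(startsWith(uri, policy$base_uri)))
    stop_fp("URI(s) not under policy base <%s>", policy$base_uri)
  rest <- substring(uri, nchar(policy$base_uri) + 1L)
  slash <- regexpr("/", rest, fixed = TRUE)
  if (any(slash < 0)) stop_fp("URI lacks a type-tag segment")
  data.frame(type_tag = substr(rest, 1L, slash - 1L),
             id = pct_decode(substring(rest, slash + 1L)),
             stringsAsFactors = FALSE)
}
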