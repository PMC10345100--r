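`%||%` <- function(a, b) if (is.null(a)) b else a

chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_character_)
  as.character(x)[1L]
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

#' Format a number for serialization
#'
#' Canonical, locale-independent decimal rendering used everywhere a numeric
#' value crosses a text boundary (TSV cells, Turtle literals). Up to 15
#' significant digits, plain notation, decimal point only.
#' @param x numeric vector
#' @return character vector
#' @keywords internal
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    formatC(v, format = "fg", digits = 15, flag = "#", drop0trailing = TRUE)
  }, character(1))
  sub("\\.$", "", out)
}

# ISO 8601 calendar date "YYYY-MM-DD"; also recognizes year-only partial dates.
is_iso_date <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y-%m-%d", optional = TRUE))
  ok
}
is_partial_date <- function(x) grepl("^\\d{4}$", x)

# pipe-joined multi-valued cell <-> character vector
join_multi <- function(x) paste(x, collapse = "|")
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

# stable C-locale ordering for deterministic output
c_order <- function(...) order(..., method = "radix")
c_sort <- function(x) sort(x, method = "radix")

stop_fp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

empty_df <- function(...) {
  cols <- c(...)
  out <- lapply(cols, function(cl) vector(cl, 0L))
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

# row-bind a list of one-row data.frames / NULLs
rbind_all <- function(lst, proto) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(proto)
  out <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
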