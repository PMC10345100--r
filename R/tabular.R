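#' Tabular I/O: MIAPPE workbook and sparse data tables
#'
#' The MIAPPE workbook is laid out as one tab per checklist section. This
#' package reads and writes the workbook as a directory of per-section TSV
#' files (one file per tab, UTF-8, tab-separated, decimal point only), the
#' plain-text form of the spreadsheet layout. The eleven recognized
#' sections and their file names are given by [miappe_sections()].
#'
#' @name tabular-io
NULL

#' MIAPPE workbook sections
#' @return named character vector: section name -> file name inside a
#'   workbook directory.
#' @export
miappe_sections <- function() {
  c("Investigation" = "investigation.tsv",
    "Study" = "study.tsv",
    "Person" = "person.tsv",
    "Data file" = "data_file.tsv",
    "Biological material" = "biological_material.tsv",
    "Environment" = "environment.tsv",
    "Experimental factor" = "experimental_factor.tsv",
    "Event" = "event.tsv",
    "Observation unit" = "observation_unit.tsv",
    "Sample" = "sample.tsv",
    "Observed variable" = "observed_variable.tsv")
}

read_tsv_raw <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_fp("empty table: %s", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  n <- length(header)
  rows <- lapply(seq_along(cells)[-1], function(i) {
    r <- cells[[i]]
    length(r) <- n  # trailing empty cells are dropped by strsplit
    r
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (length(rows) == 0L) df <- as.data.frame(matrix(character(0), 0, n), stringsAsFactors = FALSE)
  names(df) <- header
  for (cl in names(df)) df[[cl]][!is.na(df[[cl]]) & !nzchar(df[[cl]])] <- NA_character_
  df
}

write_tsv_raw <- function(df, path) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
    df[[cl]][is.na(df[[cl]])] <- ""
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t"))),
             con, useBytes = TRUE)
  invisible(path)
}

num_col <- function(df, cl) suppressWarnings(as.numeric(df[[cl]]))

#' Read a MIAPPE workbook
#'
#' Reads a workbook directory (one TSV per section). Section files may
#' appear in any order; a missing `Investigation` section is a hard
#' failure, any other missing section yields a `SECTION_MISSING` warning
#' and an empty section, and unrecognized `.tsv` files are reported as
#' `SECTION_UNKNOWN` warnings, never silently ignored.
#'
#' @param path workbook directory.
#' @return list with `investigation` (an [miappe_investigation()]) and
#'   `report` (an `fp_report`: parse findings merged with
#'   [validate_investigation()] output).
#' @export
read_miappe_workbook <- function(path) {
  if (!dir.exists(path)) stop_fp("workbook directory does not exist: %s", path)
  secs <- miappe_sections()
  present <- list.files(path, pattern = "\\.tsv$")
  extra <- setdiff(present, unname(secs))
  wrns <- list()
  wrn <- function(code, oid, msg) wrns[[length(wrns) + 1L]] <<-
      data.frame(code = code, object_id = oid, message = msg, stringsAsFactors = FALSE)
  for (e in extra) wrn("SECTION_UNKNOWN", e, "unrecognized workbook tab")
  missing <- names(secs)[!(unname(secs) %in% present)]
  if ("Investigation" %in% missing)
    stop_fp("workbook has no Investigation section (%s)", secs[["Investigation"]])
  for (m in missing) wrn("SECTION_MISSING", m, "workbook tab absent; section left empty")

  tab <- function(section, proto) {
    f <- file.path(path, secs[[section]])
    if (!file.exists(f)) return(proto)
    df <- read_tsv_raw(f)
    unknown <- setdiff(names(df), names(proto))
    for (uc in unknown) wrn("COLUMN_UNKNOWN", paste0(section, ":", uc),
                            "unrecognized column in workbook tab")
    for (cl in names(proto)) if (!(cl %in% names(df))) df[[cl]] <- NA_character_
    df <- df[, names(proto), drop = FALSE]
    df
  }

  it <- read_tsv_raw(file.path(path, secs[["Investigation"]]))
  get1 <- function(cl) if (cl %in% names(it) && nrow(it) > 0L) it[[cl]][1] else NA_character_

  st <- tab("Study", cbind(data.frame(id = character(0)), empty_df(
    title = "character", start_date = "character", end_date = "character",
    country_code = "character", location_name = "character",
    location_address = "character", latitude = "character",
    longitude = "character", altitude = "character",
    design_description = "character")))
  with_sid <- function(proto) cbind(data.frame(study_id = character(0)), proto)
  ep <- tab("Environment", with_sid(envparams_proto()))
  fc <- tab("Experimental factor", with_sid(factors_proto()))
  ev <- tab("Event", with_sid(events_proto()))
  ou <- tab("Observation unit", with_sid(units_proto()))
  tab("Sample", empty_df(id = "character", description = "character"))

  studies <- lapply(seq_len(nrow(st)), function(i) {
    sid <- st$id[i]
    pick <- function(df) {
      out <- df[!is.na(df$study_id) & df$study_id == sid, setdiff(names(df), "study_id"),
                drop = FALSE]
      rownames(out) <- NULL
      out
    }
    miappe_study(
      id = sid, title = st$title[i], start_date = st$start_date[i],
      end_date = st$end_date[i], country_code = st$country_code[i],
      location_name = st$location_name[i], location_address = st$location_address[i],
      latitude = num_col(st, "latitude")[i], longitude = num_col(st, "longitude")[i],
      altitude = num_col(st, "altitude")[i],
      design_description = st$design_description[i],
      environment_parameters = pick(ep), experimental_factors = pick(fc),
      events = pick(ev), observation_units = pick(ou))
  })

  inv <- miappe_investigation(
    id = get1("id"), title = get1("title"), description = get1("description"),
    miappe_version = get1("miappe_version"), license = get1("license"),
    publications = split_multi(get1("publications") %||% NA_character_),
    studies = studies,
    persons = tab("Person", persons_proto()),
    data_files = tab("Data file", data_files_proto()),
    biological_materials = tab("Biological material", materials_proto()),
    observed_variables = tab("Observed variable", variables_proto()),
    material_sources = split_multi(get1("material_sources") %||% NA_character_))
  inv <- normalize_investigation(inv)

  rep <- validate_investigation(inv)
  proto <- empty_df(code = "character", object_id = "character", message = "character")
  rep$warnings <- rbind_all(c(list(rep$warnings), wrns), proto)
  rep$warnings <- rep$warnings[c_order(rep$warnings$code, rep$warnings$object_id), ,
                               drop = FALSE]
  rownames(rep$warnings) <- NULL
  list(investigation = inv, report = rep)
}

#' Write a MIAPPE workbook
#'
#' Emits all eleven section tabs as TSV files with deterministic row order
#' (the canonical order of [normalize_investigation()]). Refuses to write an
#' investigation that fails validation — e.g. one carrying a date-less
#' event — and surfaces the report in the error.
#'
#' @param inv investigation; must validate with zero errors.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_miappe_workbook <- function(inv, path) {
  assert_valid(inv, what = "write workbook")
  inv <- normalize_investigation(inv)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  secs <- miappe_sections()
  w <- function(section, df) write_tsv_raw(df, file.path(path, secs[[section]]))

  w("Investigation", data.frame(
    id = inv$id, title = inv$title, description = inv$description,
    miappe_version = inv$miappe_version, license = inv$license,
    publications = join_multi(inv$publications),
    material_sources = join_multi(inv$material_sources),
    stringsAsFactors = FALSE))
  st <- rbind_all(lapply(inv$studies, function(s) data.frame(
    id = s$id, title = s$title, start_date = s$start_date, end_date = s$end_date,
    country_code = s$country_code, location_name = s$location_name,
    location_address = s$location_address, latitude = fmt_num(s$latitude),
    longitude = fmt_num(s$longitude), altitude = fmt_num(s$altitude),
    design_description = s$design_description, stringsAsFactors = FALSE)),
    empty_df(id = "character"))
  w("Study", st)
  w("Person", inv$persons)
  w("Data file", inv$data_files)
  w("Biological material", inv$biological_materials)
  per_study <- function(field) rbind_all(lapply(inv$studies, function(s) {
    df <- s[[field]]
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(study_id = s$id, stringsAsFactors = FALSE), df)
  }), cbind(data.frame(study_id = character(0)),
            switch(field, environment_parameters = envparams_proto(),
                   experimental_factors = factors_proto(),
                   events = events_proto(), observation_units = units_proto())))
  w("Environment", per_study("environment_parameters"))
  w("Experimental factor", per_study("experimental_factors"))
  w("Event", per_study("events"))
  w("Observation unit", per_study("observation_units"))
  w("Sample", empty_df(id = "character", description = "character"))
  w("Observed variable", inv$observed_variables)
  invisible(path)
}

#' Read a sparse observation table
#'
#' The convention: tab-delimited text whose header is
#' `observation_unit_id`, `date`, then one column per observed-variable id.
#' Every non-empty cell yields one record; empty cells yield nothing, so
#' time-series files stay sparse. Records preserve file order (row-major).
#'
#' @param path file path.
#' @param inv investigation whose observed variables declare the legal
#'   column ids.
#' @param na_tokens cell values treated as missing (files from many hands
#'   use different conventions).
#' @param on_duplicate what to do when the same (unit, date, variable) cell
#'   is measured twice with conflicting values: `"error"` (default),
#'   `"last"`, or `"first"`.
#' @return observation-record data frame (see [observation_records()]).
#' @export
read_observation_table <- function(path, inv, na_tokens = c("", "NA", "-"),
                                   on_duplicate = c("error", "last", "first")) {
  on_duplicate <- match.arg(on_duplicate)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_fp("empty observation table: %s", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2L || header[1] != "observation_unit_id" || header[2] != "date")
    stop_fp("observation table %s must start with columns observation_unit_id, date", path)
  var_cols <- header[-(1:2)]
  undeclared <- setdiff(var_cols, inv$observed_variables$id)
  if (length(undeclared) > 0L)
    stop_fp("observation table %s has undeclared variable column(s): %s",
            path, paste(undeclared, collapse = ", "))
  n <- length(header)
  recs <- vector("list", length(cells) - 1L)
  for (i in seq_along(cells)[-1]) {
    r <- cells[[i]]
    if (length(r) > n)
      stop_fp("line %d of %s has %d fields, expected %d", i, path, length(r), n)
    length(r) <- n
    r[is.na(r)] <- ""
    vals <- r[-(1:2)]
    keep <- !(vals %in% na_tokens)
    if (!any(keep)) next
    recs[[i - 1L]] <- data.frame(
      observation_unit_id = r[1],
      date = if (r[2] %in% na_tokens) NA_character_ else r[2],
      variable_id = var_cols[keep], value = vals[keep],
      stringsAsFactors = FALSE)
  }
  out <- rbind_all(recs, observation_records())
  key <- paste(out$observation_unit_id, out$date, out$variable_id, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conflict <- vapply(split(out$value[dup], key[dup]),
                       function(v) length(unique(v)) > 1L, logical(1))
    if (any(conflict)) {
      if (on_duplicate == "error")
        stop_fp("conflicting duplicate measurement(s) in %s for: %s", path,
                paste(gsub("\r", "/", names(conflict)[conflict]), collapse = "; "))
      out <- if (on_duplicate == "last") out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
             else out[!duplicated(key), , drop = FALSE]
    } else {
      out <- out[!duplicated(key), , drop = FALSE]
    }
    rownames(out) <- NULL
  }
  out
}

#' Write a sparse observation table
#'
#' Inverse of [read_observation_table()]: pivots records to the wide sparse
#' layout, rows sorted by (unit id, date), variable columns in declared
#' order restricted to variables that occur.
#' @param records observation-record data frame.
#' @param path target file.
#' @param inv investigation (declares variable column order).
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(records, path, inv) {
  vars <- inv$observed_variables$id[inv$observed_variables$id %in% records$variable_id]
  stray <- setdiff(records$variable_id, vars)
  if (length(stray) > 0L)
    stop_fp("records reference undeclared variable(s): %s", paste(stray, collapse = ", "))
  dkey <- ifelse(is.na(records$date), "", records$date)
  rkey <- paste(records$observation_unit_id, dkey, sep = "\t")
  ukeys <- c_sort(unique(rkey))
  wide <- matrix("", nrow = length(ukeys), ncol = length(vars),
                 dimnames = list(ukeys, vars))
  ri <- match(rkey, ukeys)
  ci <- match(records$variable_id, vars)
  dup <- duplicated(cbind(ri, ci))
  if (any(dup)) stop_fp("duplicate (unit, date, variable) records cannot be written wide")
  wide[cbind(ri, ci)] <- records$value
  df <- data.frame(do.call(rbind, strsplit(ukeys, "\t", fixed = TRUE)),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) df <- data.frame(a = character(0), b = character(0))
  names(df) <- c("observation_unit_id", "date")
  df <- cbind(df, as.data.frame(wide, stringsAsFactors = FALSE, optional = TRUE))
  names(df) <- c("observation_unit_id", "date", vars)
  write_tsv_raw(df, path)
}

#' Read a daily weather table
#'
#' Tab-delimited with columns `station_id`, `latitude`, `longitude`,
#' `date`, `daily_mean_temperature_C`, `photoperiod_hours`. Stations are
#' deduplicated by id; empty measurement cells are preserved as gaps.
#' Photoperiods outside `[0, 24]` and conflicting duplicate readings are
#' errors.
#'
#' @param path file path.
#' @return list with `stations` and `observations` data frames (see
#'   [weather_stations()]).
#' @export
read_weather_table <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("station_id", "latitude", "longitude", "date",
            "daily_mean_temperature_C", "photoperiod_hours")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_fp("weather table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  st <- df[!duplicated(df$station_id),
           c("station_id", "latitude", "longitude"), drop = FALSE]
  coord_chk <- unique(df[c("station_id", "latitude", "longitude")])
  if (anyDuplicated(coord_chk$station_id))
    stop_fp("station(s) with conflicting coordinates in %s", path)
  stations <- data.frame(id = st$station_id, name = st$station_id,
                         latitude = num_col(st, "latitude"),
                         longitude = num_col(st, "longitude"),
                         stringsAsFactors = FALSE)
  long <- list()
  for (v in c("daily_mean_temperature_C", "photoperiod_hours")) {
    vn <- if (v == "daily_mean_temperature_C") "daily_mean_temperature_C" else "photoperiod_hours"
    keep <- !is.na(df[[v]]) & nzchar(df[[v]])
    if (!any(keep)) next
    long[[v]] <- data.frame(station_id = df$station_id[keep], date = df$date[keep],
                            variable = vn, value = as.numeric(df[[v]][keep]),
                            stringsAsFactors = FALSE)
  }
  obs <- rbind_all(unname(long), weather_observations())
  bad_p <- obs$variable == "photoperiod_hours" & (obs$value < 0 | obs$value > 24)
  if (any(bad_p))
    stop_fp("photoperiod value(s) outside [0, 24] in %s: %s", path,
            paste(fmt_num(obs$value[bad_p]), collapse = ", "))
  key <- paste(obs$station_id, obs$date, obs$variable, sep = "\r")
  if (anyDuplicated(key)) {
    conflict <- vapply(split(obs$value, key), function(v) length(unique(v)) > 1L, logical(1))
    if (any(conflict))
      stop_fp("conflicting duplicate weather reading(s) in %s for: %s", path,
              paste(gsub("\r", "/", names(conflict)[conflict]), collapse = "; "))
    obs <- obs[!duplicated(key), , drop = FALSE]
  }
  obs <- obs[c_order(obs$station_id, obs$date, obs$variable), , drop = FALSE]
  rownames(obs) <- NULL
  list(stations = stations, observations = obs)
}

#' Write a daily weather table
#' @param stations,observations weather data frames.
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(stations, observations, path) {
  key <- unique(observations[c("station_id", "date")])
  key <- key[c_order(key$station_id, key$date), , drop = FALSE]
  get_val <- function(var) {
    m <- observations[observations$variable == var, , drop = FALSE]
    i <- match(paste(key$station_id, key$date), paste(m$station_id, m$date))
    fmt_num(m$value[i])
  }
  si <- match(key$station_id, stations$id)
  if (anyNA(si)) stop_fp("observation references undeclared station")
  df <- data.frame(station_id = key$station_id,
                   latitude = fmt_num(stations$latitude[si]),
                   longitude = fmt_num(stations$longitude[si]),
                   date = key$date,
                   daily_mean_temperature_C = get_val("daily_mean_temperature_C"),
                   photoperiod_hours = get_val("photoperiod_hours"),
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
}
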