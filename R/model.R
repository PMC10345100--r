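#' MIAPPE 1.1 in-memory model
#'
#' The model mirrors the eleven sections of the MIAPPE 1.1 checklist. An
#' investigation is the root object: it owns studies, persons, data-file
#' links, biological materials (genotypes) and observed variables.
#' Study-scoped sections (environment parameters, experimental factors,
#' events, observation units) live on each study. Record-like sections are
#' held as data frames so that thousands of observation units stay cheap;
#' scalar sections are plain fields.
#'
#' Dates are ISO 8601 strings (`"YYYY-MM-DD"`); a year-only partial date is
#' accepted and flagged as a warning by [validate_investigation()]. Missing
#' optional values are `NA`.
#'
#' @name miappe-model
NULL

#' Construct a MIAPPE investigation
#'
#' @param id unique investigation identifier.
#' @param title,description free text.
#' @param miappe_version MIAPPE version string; `"1.1"` is what this package
#'   models.
#' @param license license identifier (e.g. `"CC BY 4.0"`).
#' @param publications character vector of DOIs.
#' @param studies list of [miappe_study()] objects.
#' @param persons data frame with columns `name`, `email`, `affiliation`,
#'   `role` (see [miappe_person()]).
#' @param data_files data frame with columns `path_or_url`, `description`,
#'   `study_id`.
#' @param biological_materials data frame with columns `id`, `genus_species`,
#'   `material_source`, `synonyms` (pipe-joined).
#' @param observed_variables data frame with columns `id`, `name`, `trait`,
#'   `method`, `scale`, `categories` (pipe-joined declared tokens for
#'   categorical scales, else `NA`), `unit`.
#' @param material_sources character vector of declared material sources
#'   (crosses/populations, e.g. the CxE backcross) that
#'   `biological_materials$material_source` may reference.
#' @return An object of class `fp_investigation`.
#' @export
miappe_investigation <- function(id, title = "", description = "",
                                 miappe_version = "1.1", license = "",
                                 publications = character(0),
                                 studies = list(),
                                 persons = persons_proto(),
                                 data_files = data_files_proto(),
                                 biological_materials = materials_proto(),
                                 observed_variables = variables_proto(),
                                 material_sources = character(0)) {
  structure(list(
    id = chr1(id), title = chr1(title), description = chr1(description),
    miappe_version = chr1(miappe_version), license = chr1(license),
    publications = as.character(publications),
    studies = studies,
    persons = persons, data_files = data_files,
    biological_materials = biological_materials,
    observed_variables = observed_variables,
    material_sources = as.character(material_sources)
  ), class = "fp_investigation")
}

#' Construct a MIAPPE study
#'
#' @param id study identifier (e.g. `"1999NL"`).
#' @param title,design_description free text.
#' @param start_date,end_date ISO dates; `end_date` may be `NA` for
#'   under-documented trials (the study is then treated as still open when
#'   windowing weather data).
#' @param country_code ISO-like country abbreviation.
#' @param location_name,location_address free text.
#' @param latitude,longitude decimal degrees.
#' @param altitude metres.
#' @param environment_parameters data frame `name`, `value`, `unit`.
#' @param experimental_factors data frame `factor_type`, `description`,
#'   `values` (pipe-joined levels). Un-dated occurrences (e.g. fertilizer
#'   amounts without application dates) belong here, not in `events`.
#' @param events data frame `event_type`, `description`, `date`. A date is
#'   mandatory for every event.
#' @param observation_units data frame `id`, `level`, `biological_material_id`,
#'   `parent_unit_id`. Levels come from [miappe_levels()]; level `"genotype"`
#'   marks pre-averaged records.
#' @return An object of class `fp_study`.
#' @export
miappe_study <- function(id, title = "", start_date = NA, end_date = NA,
                         country_code = "", location_name = "",
                         location_address = "", latitude = NA_real_,
                         longitude = NA_real_, altitude = NA_real_,
                         design_description = "",
                         environment_parameters = envparams_proto(),
                         experimental_factors = factors_proto(),
                         events = events_proto(),
                         observation_units = units_proto()) {
  structure(list(
    id = chr1(id), title = chr1(title),
    start_date = chr1(start_date), end_date = chr1(end_date),
    country_code = chr1(country_code), location_name = chr1(location_name),
    location_address = chr1(location_address),
    latitude = as.numeric(latitude)[1], longitude = as.numeric(longitude)[1],
    altitude = as.numeric(altitude)[1],
    design_description = chr1(design_description),
    environment_parameters = environment_parameters,
    experimental_factors = experimental_factors,
    events = events,
    observation_units = observation_units
  ), class = "fp_study")
}

#' One person row
#' @param name person name (mandatory).
#' @param email,affiliation,role optional descriptors.
#' @export
miappe_person <- function(name, email = NA, affiliation = NA, role = NA) {
  data.frame(name = chr1(name), email = chr1(email),
             affiliation = chr1(affiliation), role = chr1(role),
             stringsAsFactors = FALSE)
}

#' Observation-unit level vocabulary
#'
#' The levels used in the five-trial potato scenario, ordered coarse to
#' fine. `"genotype"` marks records that were averaged per genotype before
#' deposit (the Venezuelan trial) and sits outside the nesting hierarchy.
#' @param extra additional level names to allow (appended, finest last).
#' @return character vector, coarse to fine.
#' @export
miappe_levels <- function(extra = character(0)) {
  c("block", "plot", "plant", "genotype", extra)
}

persons_proto <- function() empty_df(name = "character", email = "character",
                                     affiliation = "character", role = "character")
data_files_proto <- function() empty_df(path_or_url = "character",
                                        description = "character",
                                        study_id = "character")
materials_proto <- function() empty_df(id = "character", genus_species = "character",
                                       material_source = "character",
                                       synonyms = "character")
variables_proto <- function() empty_df(id = "character", name = "character",
                                       trait = "character", method = "character",
                                       scale = "character", categories = "character",
                                       unit = "character")
envparams_proto <- function() empty_df(name = "character", value = "character",
                                       unit = "character")
factors_proto <- function() empty_df(factor_type = "character",
                                     description = "character",
                                     values = "character")
events_proto <- function() empty_df(event_type = "character",
                                    description = "character", date = "character")
units_proto <- function() empty_df(id = "character", level = "character",
                                   biological_material_id = "character",
                                   parent_unit_id = "character")

#' Empty observation-record table
#'
#' Observation records are rows of a data frame: one row per measured cell
#' (`observation_unit_id`, `date`, `variable_id`, `value`). Missing cells in
#' the source table produce no row — the representation is sparse. `value`
#' is character so numeric measurements and categorical tokens coexist.
#' @return zero-row data frame with the four record columns.
#' @export
observation_records <- function() {
  empty_df(observation_unit_id = "character", date = "character",
           variable_id = "character", value = "character")
}

#' Empty weather tables
#'
#' Stations: `id`, `name`, `latitude`, `longitude`. Observations: one row per
#' (station, date, variable) with `variable` one of
#' `"daily_mean_temperature_C"` or `"photoperiod_hours"`.
#' @return zero-row data frame.
#' @export
weather_stations <- function() {
  empty_df(id = "character", name = "character",
           latitude = "numeric", longitude = "numeric")
}

#' @rdname weather_stations
#' @export
weather_observations <- function() {
  empty_df(station_id = "character", date = "character",
           variable = "character", value = "numeric")
}

weather_variables <- function() c("daily_mean_temperature_C", "photoperiod_hours")

#' @export
print.fp_investigation <- function(x, ...) {
  cat(sprintf("MIAPPE %s investigation '%s': %s\n", x$miappe_version, x$id, x$title))
  cat(sprintf("  %d studies, %d persons, %d materials, %d variables, %d data files\n",
              length(x$studies), nrow(x$persons), nrow(x$biological_materials),
              nrow(x$observed_variables), nrow(x$data_files)))
  for (s in x$studies)
    cat(sprintf("  study %s (%s): %d observation units\n", s$id,
                s$country_code, nrow(s$observation_units)))
  invisible(x)
}

#' @export
print.fp_study <- function(x, ...) {
  cat(sprintf("MIAPPE study '%s' (%s, %s to %s): %d units\n", x$id,
              x$country_code, x$start_date,
              ifelse(is.na(x$end_date), "open", x$end_date),
              nrow(x$observation_units)))
  invisible(x)
}

#' Canonical form of an investigation
#'
#' Sorts every record-like section deterministically (by id, then remaining
#' columns) and normalizes empty strings to `NA` in optional columns, so that
#' two investigations that differ only in row order or `NA` spelling compare
#' equal. All serializers emit the canonical form; round-trip tests compare
#' canonical forms.
#' @param inv an `fp_investigation`.
#' @return the canonicalized investigation.
#' @export
normalize_investigation <- function(inv) {
  sort_tokens <- function(x) vapply(x, function(v) {
    if (is.na(v)) NA_character_ else join_multi(c_sort(split_multi(v)))
  }, character(1), USE.NAMES = FALSE)
  norm_df <- function(df) {
    for (cl in names(df)) {
      if (is.character(df[[cl]])) df[[cl]][!is.na(df[[cl]]) & !nzchar(df[[cl]])] <- NA_character_
    }
    # multi-valued cells (pipe-joined) are sets: canonicalize token order
    for (cl in intersect(names(df), c("synonyms", "categories", "values")))
      df[[cl]] <- sort_tokens(df[[cl]])
    if (nrow(df) > 1L) df <- df[do.call(c_order, unname(as.list(df))), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  inv$persons <- norm_df(inv$persons)
  inv$data_files <- norm_df(inv$data_files)
  inv$biological_materials <- norm_df(inv$biological_materials)
  inv$observed_variables <- norm_df(inv$observed_variables)
  inv$publications <- c_sort(inv$publications)
  inv$material_sources <- c_sort(inv$material_sources)
  for (fld in c("title", "description", "license"))
    if (!is.na(inv[[fld]]) && !nzchar(inv[[fld]])) inv[[fld]] <- NA_character_
  sids <- vapply(inv$studies, `[[`, "", "id")
  inv$studies <- inv$studies[c_order(sids)]
  inv$studies <- lapply(inv$studies, function(s) {
    s$environment_parameters <- norm_df(s$environment_parameters)
    s$experimental_factors <- norm_df(s$experimental_factors)
    s$events <- norm_df(s$events)
    s$observation_units <- norm_df(s$observation_units)
    for (fld in c("title", "end_date", "country_code", "location_name",
                  "location_address", "design_description"))
      if (!is.na(s[[fld]]) && !nzchar(s[[fld]])) s[[fld]] <- NA_character_
    s
  })
  names(inv$studies) <- NULL
  inv
}

# --- internal lookups ---------------------------------------------------

study_ids <- function(inv) vapply(inv$studies, `[[`, "", "id")

get_study <- function(inv, study_id) {
  i <- match(study_id, study_ids(inv))
  if (is.na(i)) stop_fp("unknown study id: '%s'", study_id)
  inv$studies[[i]]
}

# all observation units across studies, with study_id column
all_units <- function(inv) {
  lst <- lapply(inv$studies, function(s) {
    u <- s$observation_units
    if (nrow(u) == 0L) return(NULL)
    u$study_id <- s$id
    u
  })
  out <- rbind_all(lst, cbind(units_proto(), study_id = character(0)))
  out
}
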