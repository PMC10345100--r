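#' Validate an investigation against the MIAPPE structural rules
#'
#' Checks the rules that the data-archaeology experience behind this package
#' motivates: mandatory fields, duplicate identifiers, unresolvable
#' references (unit to material, record to unit, record to variable,
#' data-file to study, parent-unit nesting), date-less events, out-of-range
#' coordinates, `start_date` after `end_date`, malformed dates, and — for
#' variables whose scale declares categories — measurement tokens outside
#' the declared set (undocumented dots or asterisks on a 0–7 flowering
#' scale being the archetype).
#'
#' Every problem is reported, never raised: the report separates `errors`
#' (the investigation is not serializable) from `warnings` (partial dates,
#' empty optional sections). Reports are deterministic: rows are ordered by
#' `(code, object_id)` and repeated validation of the same input yields an
#' identical report.
#'
#' @param inv an [miappe_investigation()].
#' @param records observation-record data frame (see
#'   [observation_records()]); may be empty.
#' @param permissive_tokens if `TRUE`, undeclared categorical tokens are
#'   downgraded from errors to warnings.
#' @param levels allowed observation-unit levels, coarse to fine
#'   ([miappe_levels()]).
#' @return An object of class `fp_report` with data-frame components
#'   `errors` and `warnings`, each with columns `code`, `object_id`,
#'   `message`.
#' @export
validate_investigation <- function(inv, records = observation_records(),
                                   permissive_tokens = FALSE,
                                   levels = miappe_levels()) {
  errs <- list(); wrns <- list()
  err <- function(code, oid, msg) errs[[length(errs) + 1L]] <<-
      data.frame(code = code, object_id = as.character(oid), message = msg,
                 stringsAsFactors = FALSE)
  wrn <- function(code, oid, msg) wrns[[length(wrns) + 1L]] <<-
      data.frame(code = code, object_id = as.character(oid), message = msg,
                 stringsAsFactors = FALSE)

  if (is_blank(inv$id))
    err("INV_ID_MISSING", "investigation", "investigation id is empty")
  if (is_blank(inv$miappe_version))
    err("INV_VERSION_MISSING", inv$id %||% "investigation",
        "miappe_version is mandatory")

  sids <- study_ids(inv)
  for (d in unique(sids[duplicated(sids)]))
    err("STUDY_DUP_ID", d, "duplicate study id within the investigation")

  check_date <- function(x, oid, what) {
    if (is.na(x)) return(invisible())
    if (is_partial_date(x)) {
      wrn("DATE_PARTIAL", oid, sprintf("%s '%s' is a year-only partial date", what, x))
    } else if (!is_iso_date(x)) {
      err("DATE_INVALID", oid, sprintf("%s '%s' is not an ISO 8601 calendar date", what, x))
    }
  }

  mat_ids <- inv$biological_materials$id
  for (d in unique(mat_ids[duplicated(mat_ids)]))
    err("MAT_DUP_ID", d, "duplicate biological material id")
  declared_sources <- unique(c(inv$material_sources, mat_ids))
  bad_src <- inv$biological_materials[
    !is_blank(inv$biological_materials$material_source) &
      !(inv$biological_materials$material_source %in% declared_sources), ,
    drop = FALSE]
  for (i in seq_len(nrow(bad_src)))
    err("MAT_SOURCE_UNDECLARED", bad_src$id[i],
        sprintf("material source '%s' is not declared", bad_src$material_source[i]))

  var_ids <- inv$observed_variables$id
  for (d in unique(var_ids[duplicated(var_ids)]))
    err("VAR_DUP_ID", d, "duplicate observed variable id")

  if (nrow(inv$persons) > 0L)
    for (i in which(is_blank(inv$persons$name)))
      err("PERSON_NAME_MISSING", sprintf("person#%d", i), "person name is empty")

  for (i in seq_len(nrow(inv$data_files)))
    if (!(inv$data_files$study_id[i] %in% sids))
      err("DF_STUDY_UNKNOWN", inv$data_files$study_id[i],
          sprintf("data file '%s' references an unknown study",
                  inv$data_files$path_or_url[i]))

  lev_rank <- stats::setNames(seq_along(levels), levels)

  for (s in inv$studies) {
    check_date(s$start_date, s$id, "start_date")
    check_date(s$end_date, s$id, "end_date")
    if (!is.na(s$start_date) && !is.na(s$end_date) &&
        is_iso_date(s$start_date) && is_iso_date(s$end_date) &&
        as.Date(s$start_date) > as.Date(s$end_date))
      err("STUDY_DATE_ORDER", s$id, "start_date is after end_date")
    if (!is.na(s$latitude) && abs(s$latitude) > 90)
      err("COORD_RANGE", s$id, sprintf("latitude %s out of [-90, 90]", fmt_num(s$latitude)))
    if (!is.na(s$longitude) && abs(s$longitude) > 180)
      err("COORD_RANGE", s$id, sprintf("longitude %s out of [-180, 180]", fmt_num(s$longitude)))

    ev <- s$events
    for (i in which(is_blank(ev$date)))
      err("EVT_DATE_MISSING", sprintf("%s/event#%d", s$id, i),
          sprintf("event '%s' has no date; a date is mandatory for events (date-less occurrences belong in experimental factors)",
                  ev$event_type[i]))
    for (i in which(!is_blank(ev$date))) check_date(ev$date[i], sprintf("%s/event#%d", s$id, i), "event date")

    ep <- s$environment_parameters
    for (i in which(is_blank(ep$name)))
      err("ENV_NAME_MISSING", sprintf("%s/environment#%d", s$id, i),
          "environment parameter has no name")

    u <- s$observation_units
    for (d in unique(u$id[duplicated(u$id)]))
      err("UNIT_DUP_ID", d, sprintf("duplicate observation unit id in study %s", s$id))
    for (i in which(!(u$level %in% levels)))
      err("UNIT_LEVEL_UNKNOWN", u$id[i],
          sprintf("level '%s' is not in the allowed vocabulary", u$level[i]))
    for (i in which(!(u$biological_material_id %in% mat_ids)))
      err("UNIT_MAT_UNKNOWN", u$id[i],
          sprintf("biological material '%s' is not declared", u$biological_material_id[i]))
    has_parent <- which(!is_blank(u$parent_unit_id))
    for (i in has_parent) {
      j <- match(u$parent_unit_id[i], u$id)
      if (is.na(j)) {
        err("UNIT_PARENT_UNKNOWN", u$id[i],
            sprintf("parent unit '%s' not found in study %s", u$parent_unit_id[i], s$id))
      } else if (u$level[i] %in% names(lev_rank) && u$level[j] %in% names(lev_rank) &&
                 lev_rank[[u$level[j]]] >= lev_rank[[u$level[i]]]) {
        err("UNIT_PARENT_LEVEL", u$id[i],
            sprintf("parent '%s' (level %s) is not coarser than %s",
                    u$parent_unit_id[i], u$level[j], u$level[i]))
      }
    }
  }

  units <- all_units(inv)
  if (nrow(records) > 0L) {
    unknown_u <- unique(records$observation_unit_id[
      !(records$observation_unit_id %in% units$id)])
    for (uu in unknown_u)
      err("REC_UNIT_UNKNOWN", uu, "record references an undeclared observation unit")
    unknown_v <- unique(records$variable_id[!(records$variable_id %in% var_ids)])
    for (vv in unknown_v)
      err("REC_VAR_UNKNOWN", vv, "record references an undeclared observed variable")

    cat_vars <- inv$observed_variables[!is_blank(inv$observed_variables$categories), ,
                                       drop = FALSE]
    for (i in seq_len(nrow(cat_vars))) {
      toks <- split_multi(cat_vars$categories[i])
      rel <- records$value[records$variable_id == cat_vars$id[i]]
      bad <- unique(rel[!is.na(rel) & !(rel %in% toks)])
      for (b in bad) {
        msg <- sprintf("token '%s' is outside the declared categories of variable '%s'",
                       b, cat_vars$id[i])
        if (permissive_tokens) wrn("REC_TOKEN_UNDECLARED", cat_vars$id[i], msg)
        else err("REC_TOKEN_UNDECLARED", cat_vars$id[i], msg)
      }
    }
  }

  report_proto <- function() empty_df(code = "character", object_id = "character",
                                      message = "character")
  errors <- rbind_all(errs, report_proto())
  warnings <- rbind_all(wrns, report_proto())
  errors <- errors[c_order(errors$code, errors$object_id, errors$message), , drop = FALSE]
  warnings <- warnings[c_order(warnings$code, warnings$object_id, warnings$message), , drop = FALSE]
  rownames(errors) <- rownames(warnings) <- NULL
  structure(list(errors = errors, warnings = warnings), class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("validation report: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  show <- function(df, tag) {
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %s %s [%s]: %s\n", tag, df$code[i], df$object_id[i], df$message[i]))
  }
  show(x$errors, "E"); show(x$warnings, "W")
  invisible(x)
}

#' Does a validation report allow serialization?
#' @param report an `fp_report`.
#' @return `TRUE` when the report has no errors.
#' @export
is_valid_report <- function(report) nrow(report$errors) == 0L

assert_valid <- function(inv, records = observation_records(), what = "serialize") {
  rep <- validate_investigation(inv, records)
  if (!is_valid_report(rep)) {
    msgs <- sprintf("%s [%s]", rep$errors$code, rep$errors$object_id)
    stop_fp("refusing to %s: investigation has %d validation error(s): %s",
            what, nrow(rep$errors), paste(utils::head(msgs, 5L), collapse = "; "))
  }
  invisible(rep)
}
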