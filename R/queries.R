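#' Study summaries
#'
#' Milestone "explore the investigation and study metadata": one row per
#' study with the descriptors a re-user needs to judge temporal and
#' spatial compatibility — id, country abbreviation, location name and
#' address, start and end dates, GPS coordinates and altitude. Values
#' equal the underlying study fields exactly; rows are sorted by study id.
#'
#' @param source a phenotypic [source_model()], [source_graph()] or
#'   [source_sparql()].
#' @return data frame of study summaries.
#' @export
summarize_studies <- function(source) {
  inv <- as_pheno_tables(source)$inv
  out <- rbind_all(lapply(inv$studies, function(s) data.frame(
    study_id = s$id, country_code = s$country_code,
    location_name = s$location_name, location_address = s$location_address,
    start_date = s$start_date, end_date = s$end_date,
    latitude = s$latitude, longitude = s$longitude, altitude = s$altitude,
    stringsAsFactors = FALSE)),
    empty_df(study_id = "character", country_code = "character",
             location_name = "character", location_address = "character",
             start_date = "character", end_date = "character",
             latitude = "numeric", longitude = "numeric", altitude = "numeric"))
  out <- out[c_order(out$study_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype overlap across studies (source version)
#'
#' Milestone "verify that the experiments have overlapping genotypes" for
#' any source kind; delegates to [common_genotype_ids()] on the extracted
#' model.
#' @param source phenotypic source.
#' @param study_ids studies to intersect; default all.
#' @return sorted character vector of common genotype ids.
#' @export
overlap_genotypes <- function(source, study_ids = NULL) {
  common_genotype_ids(as_pheno_tables(source)$inv, study_ids)
}

#' Match each study to its nearest weather station
#'
#' Milestone "find weather data for the location and time period of
#' interest": for every study, the station minimizing the sum of squared
#' coordinate differences \eqn{(\Delta lat)^2 + (\Delta lon)^2} in raw
#' decimal degrees — the deliberately simple metric the reuse scenario
#' computes (sorting it ascending reveals the matches). A great-circle
#' (haversine, km) mode exists behind `metric` but squared degrees is the
#' default for fidelity to that scenario. Ties break by lexicographic
#' station id. The full sorted study-by-station distance table is
#' attached as attribute `"distance_table"` for inspection.
#'
#' @param summaries study summaries ([summarize_studies()] output or any
#'   data frame with `study_id`, `latitude`, `longitude`).
#' @param stations weather-station data frame.
#' @param metric `"squared_degrees"` (default) or `"haversine_km"`.
#' @return data frame `study_id`, `station_id`, `squared_distance`.
#' @export
match_weather_stations <- function(summaries, stations,
                                   metric = c("squared_degrees", "haversine_km")) {
  metric <- match.arg(metric)
  if (nrow(stations) == 0L) stop_fp("no weather stations to match against")
  pairs <- expand.grid(si = seq_len(nrow(summaries)), wi = seq_len(nrow(stations)))
  d <- if (metric == "squared_degrees") {
    (summaries$latitude[pairs$si] - stations$latitude[pairs$wi])^2 +
      (summaries$longitude[pairs$si] - stations$longitude[pairs$wi])^2
  } else {
    hav <- function(lat1, lon1, lat2, lon2) {
      r <- pi / 180
      a <- sin((lat2 - lat1) * r / 2)^2 +
        cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
      2 * 6371 * asin(pmin(1, sqrt(a)))
    }
    hav(summaries$latitude[pairs$si], summaries$longitude[pairs$si],
        stations$latitude[pairs$wi], stations$longitude[pairs$wi])
  }
  tab <- data.frame(study_id = summaries$study_id[pairs$si],
                    station_id = stations$id[pairs$wi],
                    squared_distance = d, stringsAsFactors = FALSE)
  tab <- tab[c_order(tab$study_id, tab$squared_distance, tab$station_id), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab[!duplicated(tab$study_id), , drop = FALSE]
  rownames(best) <- NULL
  attr(best, "distance_table") <- tab
  best
}

#' Per-genotype, per-study trait means
#'
#' Milestone "focus on a trait and plot it for all experiments": for each
#' (genotype, study) cell, collect the records of `variable_id` on that
#' genotype's units, reduce repeated dated measurements per unit
#' (`repeated`, default the last dated record), and average arithmetically
#' over the study's contributing units — "averaged by plant" when units
#' are plants. Pre-averaged genotype-level records pass through as the
#' cell value with an unknown (NA) contributing count. A cell exists only
#' where at least one record contributed.
#'
#' @param source phenotypic source.
#' @param variable_id observed-variable id; must be declared.
#' @param study_ids studies to include (default all).
#' @param restrict `"all_genotypes"` (union) or `"complete_cases"`
#'   (genotypes with a value in every listed study).
#' @param repeated how to reduce repeated dated measurements of one unit:
#'   `"last"`, `"mean"`, or `"first"`.
#' @return an `fp_trait_summary`: data frame `genotype_id`, `study_id`,
#'   `mean_value`, `n_units`, with the variable id as attribute
#'   `"variable_id"`.
#' @export
genotype_trait_means <- function(source, variable_id, study_ids = NULL,
                                 restrict = c("all_genotypes", "complete_cases"),
                                 repeated = c("last", "mean", "first")) {
  restrict <- match.arg(restrict)
  repeated <- match.arg(repeated)
  tb <- as_pheno_tables(source)
  inv <- tb$inv
  if (!(variable_id %in% inv$observed_variables$id))
    stop_fp("variable '%s' is not declared in the investigation", variable_id)
  if (is.null(study_ids)) study_ids <- study_ids(inv)
  units <- all_units(inv)
  units <- units[units$study_id %in% study_ids, , drop = FALSE]
  rec <- tb$records[tb$records$variable_id == variable_id, , drop = FALSE]
  ui <- match(rec$observation_unit_id, units$id)
  rec <- rec[!is.na(ui), , drop = FALSE]
  ui <- ui[!is.na(ui)]
  rec$study_id <- units$study_id[ui]
  rec$level <- units$level[ui]
  rec$genotype <- resolve_synonyms(inv, units$biological_material_id[ui])
  rec$num <- suppressWarnings(as.numeric(rec$value))
  rec <- rec[!is.na(rec$num), , drop = FALSE]

  # one value per unit
  per_unit <- lapply(split(rec, paste(rec$observation_unit_id, rec$study_id, sep = "\r")),
    function(d) {
      v <- switch(repeated,
        mean = mean(d$num),
        last = d$num[order(ifelse(is.na(d$date), "", d$date))][nrow(d)],
        first = d$num[order(ifelse(is.na(d$date), "~", d$date))][1])
      data.frame(study_id = d$study_id[1], genotype = d$genotype[1],
                 level = d$level[1], num = v, stringsAsFactors = FALSE)
    })
  pu <- rbind_all(per_unit, empty_df(study_id = "character", genotype = "character",
                                     level = "character", num = "numeric"))
  cells <- lapply(split(pu, paste(pu$genotype, pu$study_id, sep = "\r")), function(d) {
    pre <- d$level == "genotype"
    if (any(pre)) {
      # pre-averaged deposit records are the cell value; plant records, if
      # any coexist, are folded in as weight-1 means alongside them
      data.frame(genotype_id = d$genotype[1], study_id = d$study_id[1],
                 mean_value = mean(d$num), n_units = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(genotype_id = d$genotype[1], study_id = d$study_id[1],
                 mean_value = mean(d$num), n_units = nrow(d),
                 stringsAsFactors = FALSE)
    }
  })
  out <- rbind_all(cells, empty_df(genotype_id = "character", study_id = "character",
                                   mean_value = "numeric", n_units = "integer"))
  if (restrict == "complete_cases" && nrow(out) > 0L) {
    per_g <- split(out$study_id, out$genotype_id)
    keep <- names(per_g)[vapply(per_g, function(s) all(study_ids %in% s), logical(1))]
    out <- out[out$genotype_id %in% keep, , drop = FALSE]
  }
  out <- out[c_order(out$genotype_id, out$study_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variable_id") <- variable_id
  class(out) <- c("fp_trait_summary", "data.frame")
  out
}

#' Genotype stability lines
#'
#' Milestone "combine the trait with the weather information": for every
#' genotype, take the environments (studies) of its lowest and highest
#' mean value, pair each with that study's cumulative PBTT, and classify
#' the line joining them: rising when the best performance sits at the
#' higher PBTT (the genotype did worse where days were short and cool),
#' falling for the opposite, flat for a single environment or exact ties.
#' The spread (max minus min) is the stability indicator. Ties on value or
#' PBTT resolve to the lexicographically smallest study id. Genotypes with
#' zero cells are excluded and counted in attribute `"n_excluded"`.
#'
#' @param summary an `fp_trait_summary` ([genotype_trait_means()]).
#' @param pbtt_per_study data frame `study_id`, `pbtt` covering every
#'   study present in `summary`.
#' @param all_genotypes optional genotype universe; members without any
#'   cell are excluded from the output and counted in `"n_excluded"`.
#' @return data frame `genotype_id`, `study_low`, `pbtt_low`, `value_low`,
#'   `study_high`, `pbtt_high`, `value_high`, `spread`, `direction`.
#' @export
stability_lines <- function(summary, pbtt_per_study, all_genotypes = NULL) {
  miss <- setdiff(unique(summary$study_id), pbtt_per_study$study_id)
  if (length(miss) > 0L)
    stop_fp("no PBTT value for study(ies): %s", paste(miss, collapse = ", "))
  pb <- stats::setNames(pbtt_per_study$pbtt, pbtt_per_study$study_id)
  rows <- lapply(split(seq_len(nrow(summary)), summary$genotype_id), function(ix) {
    d <- summary[ix, , drop = FALSE]
    d <- d[c_order(d$study_id), , drop = FALSE]
    lo <- which(d$mean_value == min(d$mean_value))[1]
    hi <- which(d$mean_value == max(d$mean_value))[1]
    p_lo <- unname(pb[[d$study_id[lo]]]); p_hi <- unname(pb[[d$study_id[hi]]])
    dir <- if (nrow(d) == 1L || p_lo == p_hi || d$mean_value[lo] == d$mean_value[hi])
      "flat" else if (p_hi > p_lo) "rising" else "falling"
    data.frame(genotype_id = d$genotype_id[1],
               study_low = d$study_id[lo], pbtt_low = p_lo,
               value_low = d$mean_value[lo],
               study_high = d$study_id[hi], pbtt_high = p_hi,
               value_high = d$mean_value[hi],
               spread = d$mean_value[hi] - d$mean_value[lo],
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- rbind_all(rows, empty_df(
    genotype_id = "character", study_low = "character", pbtt_low = "numeric",
    value_low = "numeric", study_high = "character", pbtt_high = "numeric",
    value_high = "numeric", spread = "numeric", direction = "character"))
  out <- out[c_order(out$genotype_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- if (is.null(all_genotypes)) 0L
    else length(setdiff(all_genotypes, out$genotype_id))
  out
}

#' Federated fetch across the phenotypic and weather sources
#'
#' The cross-source joins the milestones need, with identical results
#' whether each side is an in-memory model, a parsed graph, or a SPARQL
#' engine: `"station_match"` joins study coordinates against station
#' coordinates; `"pbtt"` joins study windows against the matched weather
#' series. Either source being unreachable fails naming it.
#'
#' @param pheno_source phenotypic source.
#' @param weather_source weather source.
#' @param request `"station_match"` or `"pbtt"`.
#' @param params [pbtt_params()] (for `"pbtt"`).
#' @return the joined table.
#' @export
federated_fetch <- function(pheno_source, weather_source,
                            request = c("station_match", "pbtt"),
                            params = pbtt_params()) {
  request <- match.arg(request)
  ph <- tryCatch(as_pheno_tables(pheno_source),
                 error = function(e) stop_fp("phenotypic source failed: %s",
                                             conditionMessage(e)))
  wt <- tryCatch(as_weather_tables(weather_source),
                 error = function(e) stop_fp("weather source failed: %s",
                                             conditionMessage(e)))
  summaries <- summarize_studies(source_model(ph$inv, ph$records))
  matches <- match_weather_stations(summaries, wt$stations)
  if (request == "station_match") return(matches)
  study_pbtt(ph$inv, matches, wt$observations, params)
}

#' Export milestone tables as TSV
#' @param df data frame.
#' @param path target file.
#' @return `path`, invisibly.
#' @export
write_milestone_tsv <- function(df, path) {
  write_tsv_raw(as.data.frame(df), path)
}
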