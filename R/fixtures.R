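#' Synthetic fixture specification
#'
#' The generator emulates the archived five-trial potato deposit: partially
#' overlapping genotype subsets of one mapping population (the CxE
#' backcross) grown across latitudes, plant/plot/block observation levels
#' with one trial deposited only as per-genotype averages, sparse
#' time-series traits, and one weather station per trial location. Every
#' draw is a deterministic function of `seed`, and the generator records a
#' ground-truth ledger (computed by its own simple loops, independent of
#' the package's query code) for every quantity the milestones later
#' recompute.
#'
#' Defaults are the deposit's documented shape: 5 studies with the ids
#' `1999NL, 2003VE, 2004Fin, 2005Fin, 2010ET`, 292 genotypes in total of
#' which 101 occur in all five trials, the Venezuelan trial pre-averaged
#' at genotype level, and 80 of the common genotypes carrying a
#' tuber-weight value in every trial.
#'
#' @param n_studies number of studies.
#' @param n_genotypes_total union size of the genotype sets.
#' @param overlap_count genotypes present in every study.
#' @param complete_cases genotypes (of the overlap) with a tuber-weight
#'   value in every study; the remainder lose their values in one study.
#' @param genotype_level_study index of the study deposited as
#'   per-genotype averages (`NA` for none).
#' @param plants_per_genotype plants grown per genotype per study.
#' @param trait_baseline_mean,trait_baseline_sd genotype baselines for
#'   tuber weight, g per plant.
#' @param study_effect_sd between-environment effect scale, g.
#' @param noise_sd residual plant-to-plant noise, g.
#' @param seed integer seed; fully determines all output.
#' @return a `fp_fixture_spec`.
#' @export
fixture_spec <- function(n_studies = 5, n_genotypes_total = 292,
                         overlap_count = 101, complete_cases = 80,
                         genotype_level_study = 2, plants_per_genotype = 10,
                         trait_baseline_mean = 350, trait_baseline_sd = 120,
                         study_effect_sd = 150, noise_sd = 40, seed = 1) {
  if (overlap_count > n_genotypes_total)
    stop_fp("overlap_count (%d) exceeds n_genotypes_total (%d)",
            overlap_count, n_genotypes_total)
  if (complete_cases > overlap_count)
    stop_fp("complete_cases (%d) exceeds overlap_count (%d)",
            complete_cases, overlap_count)
  if (!is.na(genotype_level_study) &&
      (genotype_level_study < 1 || genotype_level_study > n_studies))
    stop_fp("genotype_level_study out of range")
  structure(as.list(environment()), class = "fp_fixture_spec")
}

# deposit-shaped study metadata for the default 5-trial layout
deposit_studies <- function(n) {
  meta <- data.frame(
    id = c("1999NL", "2003VE", "2004Fin", "2005Fin", "2010ET"),
    country_code = c("NL", "VE", "FI", "FI", "ET"),
    location_name = c("Wageningen", "Merida highlands", "Jokioinen",
                      "Ylistaro", "Holetta"),
    location_address = c("Wageningen, The Netherlands",
                         "Merida, Venezuela", "Jokioinen, Finland",
                         "Ylistaro, Finland", "Holetta, Ethiopia"),
    latitude = c(51.97, 8.6, 60.81, 62.94, 9.05),
    longitude = c(5.66, -71.15, 23.5, 22.51, 38.5),
    altitude = c(10, 1950, 104, 104, 2400),
    start_date = c("1999-04-15", "2003-01-20", "2004-05-20", "2005-05-18",
                   "2010-06-25"),
    end_date = c("1999-09-10", "2003-04-25", "2004-09-15", "2005-09-12",
                 "2010-10-30"),
    stringsAsFactors = FALSE)
  if (n <= 5L) return(meta[seq_len(n), , drop = FALSE])
  extra <- data.frame(
    id = sprintf("20%02dSYN", 10 + seq_len(n - 5L)),
    country_code = "XX", location_name = "Synthetic site",
    location_address = "Synthetic site",
    latitude = 30 + 2 * seq_len(n - 5L), longitude = 4 * seq_len(n - 5L),
    altitude = 100, start_date = "2011-05-01", end_date = "2011-08-31",
    stringsAsFactors = FALSE)
  rbind(meta, extra)
}

# day length (hours) from latitude and day of year: standard solar
# declination geometry with polar clamping
day_length_hours <- function(lat_deg, doy) {
  phi <- lat_deg * pi / 180
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
  x <- -tan(phi) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  24 - (24 / pi) * acos(-x)
}

#' Generate a deposit-shaped synthetic fixture
#'
#' Builds the full scenario under one seed: MIAPPE investigation,
#' per-study sparse observation tables (tuber weight per plant, a sparse
#' plant-height time series, a categorical 0–7 flowering score), one
#' weather station per study within half a degree of the trial, daily
#' temperature and photoperiod series covering each window, and the
#' ground-truth ledger. When `dir` is given, everything is written to
#' disk in the package's interchange formats (workbook directory,
#' observation TSV per study, one weather TSV).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @param params [pbtt_params()] used for the ledger's PBTT values.
#' @return list with `investigation`, `records` (all studies),
#'   `stations`, `weather`, `truth` (the ledger), and `paths` when `dir`
#'   was given.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL,
                             params = pbtt_params()) {
  stopifnot(inherits(spec, "fp_fixture_spec"))
  set.seed(spec$seed)
  ns <- spec$n_studies
  meta <- deposit_studies(ns)
  gids <- sprintf("CE%03d", seq_len(spec$n_genotypes_total))
  common <- gids[seq_len(spec$overlap_count)]
  extras <- setdiff(gids, common)

  # membership: common everywhere; extras in a proper, non-empty subset
  membership <- matrix(FALSE, nrow = length(gids), ncol = ns,
                       dimnames = list(gids, meta$id))
  membership[common, ] <- TRUE
  for (g in extras) {
    k <- if (ns == 1L) 1L else sample(seq_len(ns - 1L), 1L)
    membership[g, sample(ns, k)] <- TRUE
  }

  # trait model: genotype baseline + study effect + plant noise
  baseline <- stats::setNames(
    stats::rnorm(length(gids), spec$trait_baseline_mean, spec$trait_baseline_sd),
    gids)
  baseline <- pmax(baseline, 20)
  study_eff <- stats::setNames(stats::rnorm(ns, 0, spec$study_effect_sd), meta$id)

  # which common genotypes lose their tuber-weight values in one study
  dropped <- character(0)
  drop_at <- character(0)
  if (ns > 1L) {
    dropped <- common[seq_len(spec$overlap_count - spec$complete_cases)]
    drop_at <- meta$id[(seq_along(dropped) - 1L) %% ns + 1L]
    names(drop_at) <- dropped
  }

  materials <- data.frame(
    id = gids, genus_species = "Solanum tuberosum", material_source = "CxE",
    synonyms = ifelse(seq_along(gids) <= 3L, paste0("alt_", gids), NA_character_),
    stringsAsFactors = FALSE)
  variables <- data.frame(
    id = c("tubweight", "plantheight", "flw"),
    name = c("total tuber weight", "plant height", "flowering score"),
    trait = c("tuber weight per plant", "plant height", "flowering"),
    method = c("harvest weighing", "ruler measurement", "visual scoring"),
    scale = c("gram scale", "centimetre scale", "ordinal 0-7"),
    categories = c(NA, NA, join_multi(as.character(0:7))),
    unit = c("g", "cm", NA), stringsAsFactors = FALSE)

  studies <- list()
  rec_rows <- list()
  truth_cells <- list()
  for (si in seq_len(ns)) {
    sid <- meta$id[si]
    here <- gids[membership[, si]]
    geno_level <- !is.na(spec$genotype_level_study) && si == spec$genotype_level_study
    units <- list(); k <- 0L
    push <- function(id, level, mat, parent) {
      k <<- k + 1L
      units[[k]] <<- data.frame(id = id, level = level,
                                biological_material_id = mat,
                                parent_unit_id = parent, stringsAsFactors = FALSE)
    }
    for (gi in seq_along(here)) {
      g <- here[gi]
      mu <- baseline[[g]] + study_eff[[sid]]
      dropped_here <- g %in% dropped && identical(unname(drop_at[g]), sid)
      if (geno_level) {
        uid <- paste(sid, "g", g, sep = "_")
        push(uid, "genotype", g, NA_character_)
        if (!dropped_here) {
          vals <- pmax(round(mu + stats::rnorm(spec$plants_per_genotype, 0, spec$noise_sd), 1), 0)
          avg <- round(mean(vals), 1)
          rec_rows[[length(rec_rows) + 1L]] <- data.frame(
            observation_unit_id = uid, date = meta$end_date[si],
            variable_id = "tubweight", value = fmt_num(avg),
            study_id = sid, stringsAsFactors = FALSE)
          truth_cells[[length(truth_cells) + 1L]] <- data.frame(
            genotype_id = g, study_id = sid, mean_value = avg,
            n_units = NA_integer_, stringsAsFactors = FALSE)
        }
      } else {
        bid <- paste(sid, "b", (gi - 1L) %% 2L + 1L, sep = "_")
        pid <- paste(sid, "plot", g, sep = "_")
        push(pid, "plot", g, bid)
        plant_vals <- numeric(0)
        for (pi in seq_len(spec$plants_per_genotype)) {
          uid <- paste(sid, g, sprintf("pl%02d", pi), sep = "_")
          push(uid, "plant", g, pid)
          v <- max(round(mu + stats::rnorm(1, 0, spec$noise_sd), 1), 0)
          if (!dropped_here) {
            plant_vals <- c(plant_vals, v)
            rec_rows[[length(rec_rows) + 1L]] <- data.frame(
              observation_unit_id = uid, date = meta$end_date[si],
              variable_id = "tubweight", value = fmt_num(v),
              study_id = sid, stringsAsFactors = FALSE)
          }
          # sparse extras on the first plant of the first few genotypes
          if (pi == 1L && gi <= 3L) {
            d0 <- as.Date(meta$start_date[si])
            for (w in c(30L, 60L)) {
              rec_rows[[length(rec_rows) + 1L]] <- data.frame(
                observation_unit_id = uid,
                date = format(d0 + w, "%Y-%m-%d"),
                variable_id = "plantheight",
                value = fmt_num(round(10 + w * 0.8 + stats::rnorm(1, 0, 3), 1)),
                study_id = sid, stringsAsFactors = FALSE)
            }
            rec_rows[[length(rec_rows) + 1L]] <- data.frame(
              observation_unit_id = uid,
              date = format(d0 + 45L, "%Y-%m-%d"),
              variable_id = "flw", value = as.character(sample(0:7, 1)),
              study_id = sid, stringsAsFactors = FALSE)
          }
        }
        if (!dropped_here)
          truth_cells[[length(truth_cells) + 1L]] <- data.frame(
            genotype_id = g, study_id = sid, mean_value = mean(plant_vals),
            n_units = length(plant_vals), stringsAsFactors = FALSE)
      }
    }
    udf <- rbind_all(units, units_proto())
    blocks <- unique(udf$parent_unit_id[udf$level == "plot"])
    blocks <- blocks[!is.na(blocks)]
    for (b in blocks) {
      # blocks are design carriers: they reference a representative material
      first_plot <- udf$id[which(udf$parent_unit_id == b & udf$level == "plot")[1]]
      mat <- udf$biological_material_id[udf$id == first_plot]
      udf <- rbind(udf, data.frame(id = b, level = "block",
                                   biological_material_id = mat,
                                   parent_unit_id = NA_character_,
                                   stringsAsFactors = FALSE))
    }
    studies[[si]] <- miappe_study(
      id = sid, title = sprintf("Field trial %s", sid),
      start_date = meta$start_date[si], end_date = meta$end_date[si],
      country_code = meta$country_code[si],
      location_name = meta$location_name[si],
      location_address = meta$location_address[si],
      latitude = meta$latitude[si], longitude = meta$longitude[si],
      altitude = meta$altitude[si],
      design_description = if (geno_level)
        "Deposited as per-genotype averages" else "Two randomized blocks",
      environment_parameters = data.frame(
        name = c("type of soil", "average temperature"),
        value = c("sandy loam", fmt_num(round(12 + abs(stats::rnorm(1, 4, 2)), 1))),
        unit = c(NA, "degrees C"), stringsAsFactors = FALSE),
      experimental_factors = data.frame(
        factor_type = "fertilization", description = "fertilizer amount, date unrecorded",
        values = "120 kg N/ha", stringsAsFactors = FALSE),
      events = data.frame(event_type = "planting", description = "planting date",
                          date = meta$start_date[si], stringsAsFactors = FALSE),
      observation_units = udf)
  }

  inv <- miappe_investigation(
    id = "CxE_potato_trials",
    title = "Multi-environment potato trials of the CxE population",
    description = paste("Synthetic emulation of five potato field trials with",
                        "partially overlapping subsets of the CxE backcross population"),
    license = "CC BY 4.0",
    publications = c("10.0000/synthetic.deposit"),
    studies = studies,
    persons = data.frame(name = c("Trial Coordinator", "Data Steward"),
                         email = c(NA, "steward@example.org"),
                         affiliation = "Synthetic University",
                         role = c("coordinator", "curator"), stringsAsFactors = FALSE),
    data_files = data.frame(path_or_url = paste0("data_", meta$id, ".tsv"),
                            description = paste("Observations for study", meta$id),
                            study_id = meta$id, stringsAsFactors = FALSE),
    biological_materials = materials,
    observed_variables = variables,
    material_sources = "CxE")
  inv <- normalize_investigation(inv)

  records <- rbind_all(rec_rows, cbind(observation_records(),
                                       study_id = character(0)))

  # one station per trial, within half a degree
  stations <- data.frame(
    id = paste0("WS_", meta$id),
    name = paste("Weather station", meta$location_name),
    latitude = round(meta$latitude + stats::runif(ns, -0.15, 0.15), 4),
    longitude = round(meta$longitude + stats::runif(ns, -0.15, 0.15), 4),
    stringsAsFactors = FALSE)
  wx_rows <- list()
  for (si in seq_len(ns)) {
    days <- seq(as.Date(meta$start_date[si]), as.Date(meta$end_date[si]), by = "day")
    doy <- as.integer(format(days, "%j"))
    lat <- stations$latitude[si]
    seasonal <- if (lat >= 0) -cos(2 * pi * (doy - 15) / 365.25)
                else cos(2 * pi * (doy - 15) / 365.25)
    base_t <- 26 - 0.25 * abs(lat) - 0.004 * meta$altitude[si]
    temps <- round(base_t + 8 * seasonal * (abs(lat) / 60) +
                     stats::rnorm(length(days), 0, 1.5), 1)
    photo <- round(day_length_hours(lat, doy), 2)
    wx_rows[[si]] <- data.frame(
      station_id = stations$id[si],
      date = rep(format(days, "%Y-%m-%d"), 2L),
      variable = rep(c("daily_mean_temperature_C", "photoperiod_hours"),
                     each = length(days)),
      value = c(temps, photo), stringsAsFactors = FALSE)
  }
  weather <- rbind_all(wx_rows, weather_observations())
  weather <- weather[c_order(weather$station_id, weather$date, weather$variable), ,
                     drop = FALSE]
  rownames(weather) <- NULL

  truth <- fixture_truth(spec, meta, membership, truth_cells, stations, weather,
                         params, inv)

  out <- list(spec = spec, investigation = inv,
              records = records[, names(observation_records()), drop = FALSE],
              records_by_study = split(records[, names(observation_records()),
                                               drop = FALSE], records$study_id),
              stations = stations, weather = weather, truth = truth, dir = dir)
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

# ground truth by independent simple loops (no package query code)
fixture_truth <- function(spec, meta, membership, truth_cells, stations,
                          weather, params, inv) {
  sets <- lapply(seq_len(nrow(meta)), function(si) rownames(membership)[membership[, si]])
  common <- sets[[1]]
  for (s in sets[-1]) common <- common[common %in% s]

  cells <- rbind_all(truth_cells, empty_df(genotype_id = "character",
                                           study_id = "character",
                                           mean_value = "numeric",
                                           n_units = "integer"))
  cells <- cells[c_order(cells$genotype_id, cells$study_id), , drop = FALSE]
  rownames(cells) <- NULL
  per_g <- split(cells$study_id, cells$genotype_id)
  complete <- names(per_g)[vapply(per_g, function(s)
    all(meta$id %in% s), logical(1))]

  # nearest station: exhaustive pairwise loop
  match_rows <- list()
  for (si in seq_len(nrow(meta))) {
    best <- NULL
    for (wi in seq_len(nrow(stations))) {
      d <- (meta$latitude[si] - stations$latitude[wi])^2 +
        (meta$longitude[si] - stations$longitude[wi])^2
      if (is.null(best) || d < best$d ||
          (d == best$d && stations$id[wi] < best$id))
        best <- list(id = stations$id[wi], d = d)
    }
    match_rows[[si]] <- data.frame(study_id = meta$id[si], station_id = best$id,
                                   squared_distance = best$d, stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, match_rows)

  # PBTT: plain day-by-day loop, formulas re-stated inline
  pbtt <- numeric(nrow(meta))
  for (si in seq_len(nrow(meta))) {
    st <- matches$station_id[si]
    days <- format(seq(as.Date(meta$start_date[si]), as.Date(meta$end_date[si]),
                       by = "day"), "%Y-%m-%d")
    tot <- 0
    for (d in days) {
      tt <- weather$value[weather$station_id == st & weather$date == d &
                            weather$variable == "daily_mean_temperature_C"]
      pp <- weather$value[weather$station_id == st & weather$date == d &
                            weather$variable == "photoperiod_hours"]
      fb <- 0
      if (tt > params$t_base && tt < params$t_ceil) {
        ex <- (params$t_ceil - params$t_opt) / (params$t_opt - params$t_base)
        fb <- (((tt - params$t_base) / (params$t_opt - params$t_base)) *
                 ((params$t_ceil - tt) / (params$t_ceil - params$t_opt))^ex)^params$curvature
      }
      fp <- 1 - params$p_sens * (params$p_crit - pp)
      fp <- min(1, max(0, fp))
      tot <- tot + fp * fb
    }
    pbtt[si] <- tot
  }

  units <- all_units(inv)
  list(study_ids = c_sort(meta$id),
       genotype_sets = stats::setNames(lapply(sets, c_sort), meta$id),
       common_genotypes = c_sort(common),
       union_genotypes = c_sort(rownames(membership)[rowSums(membership) > 0]),
       trait_cells = cells,
       union_trait_genotypes = c_sort(unique(cells$genotype_id)),
       complete_case_genotypes = c_sort(complete),
       station_matches = matches[c_order(matches$study_id), , drop = FALSE],
       pbtt = data.frame(study_id = meta$id, pbtt = pbtt,
                         stringsAsFactors = FALSE)[c_order(meta$id), , drop = FALSE],
       unit_genotype = stats::setNames(units$biological_material_id, units$id))
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wb <- file.path(dir, "miappe_workbook")
  write_miappe_workbook(fx$investigation, wb)
  obs_paths <- character(0)
  for (sid in names(fx$records_by_study)) {
    p <- file.path(dir, paste0("data_", sid, ".tsv"))
    write_observation_table(fx$records_by_study[[sid]], p, fx$investigation)
    obs_paths[sid] <- p
  }
  wx <- file.path(dir, "weather.tsv")
  write_weather_table(fx$stations, fx$weather, wx)
  list(workbook = wb, observations = obs_paths, weather = wx)
}

#' Inject a named defect into a written fixture
#'
#' Reproduces, one at a time, the data-archaeology defects the validation
#' layer exists for: a date-less event, an undeclared variable column, an
#' undeclared categorical token, a conflicting duplicate measurement, and
#' a missing weather day. The corrupted copy lands in a sibling directory
#' so the clean fixture is untouched.
#'
#' @param fixture a [generate_fixture()] result written with `dir`.
#' @param defect one of `"dateless_event"`, `"unknown_variable_column"`,
#'   `"undeclared_token"`, `"conflicting_duplicate"`,
#'   `"missing_weather_day"`.
#' @param dir output directory for the corrupted copy (default: sibling
#'   `<fixture dir>_<defect>`).
#' @return the corrupted fixture's `paths` list.
#' @export
perturb_fixture <- function(fixture,
                            defect = c("dateless_event", "unknown_variable_column",
                                       "undeclared_token", "conflicting_duplicate",
                                       "missing_weather_day"),
                            dir = NULL) {
  defect <- match.arg(defect)
  if (is.null(fixture$paths)) stop_fp("fixture was not written to disk")
  if (is.null(dir)) dir <- paste0(fixture$dir, "_", defect)
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE)
  file.copy(file.path(fixture$dir, list.files(fixture$dir)), dir,
            recursive = TRUE)
  paths <- list(workbook = file.path(dir, "miappe_workbook"),
                observations = file.path(dir, basename(fixture$paths$observations)),
                weather = file.path(dir, "weather.tsv"))
  names(paths$observations) <- names(fixture$paths$observations)

  edit <- function(path, f) {
    lines <- readLines(path, encoding = "UTF-8")
    writeLines(f(lines), path, useBytes = TRUE)
  }
  first_sid <- names(paths$observations)[1]
  if (defect == "dateless_event") {
    edit(file.path(paths$workbook, "event.tsv"), function(l)
      c(l, paste(first_sid, "fungicide application", "undated application", "",
                 sep = "\t")))
  } else if (defect == "unknown_variable_column") {
    edit(paths$observations[[1]], function(l) {
      h <- strsplit(l[1], "\t", fixed = TRUE)[[1]]
      h[length(h)] <- "tottub"
      l[1] <- paste(h, collapse = "\t")
      l
    })
  } else if (defect == "undeclared_token") {
    # overwrite one flowering cell with an undocumented asterisk
    target <- NULL
    for (p in paths$observations) {
      h <- strsplit(readLines(p, n = 1L), "\t", fixed = TRUE)[[1]]
      if ("flw" %in% h) { target <- p; break }
    }
    if (is.null(target)) stop_fp("no observation file carries the flw column")
    edit(target, function(l) {
      h <- strsplit(l[1], "\t", fixed = TRUE)[[1]]
      ci <- match("flw", h)
      for (i in seq_along(l)[-1]) {
        r <- strsplit(l[i], "\t", fixed = TRUE)[[1]]
        length(r) <- length(h)
        r[is.na(r)] <- ""
        if (nzchar(r[ci])) { r[ci] <- "*"; l[i] <- paste(r, collapse = "\t"); break }
      }
      l
    })
  } else if (defect == "conflicting_duplicate") {
    edit(paths$observations[[1]], function(l) {
      r <- strsplit(l[2], "\t", fixed = TRUE)[[1]]
      h <- strsplit(l[1], "\t", fixed = TRUE)[[1]]
      length(r) <- length(h)
      r[is.na(r)] <- ""
      vi <- which(nzchar(r[-(1:2)]))[1] + 2L
      r[vi] <- fmt_num(suppressWarnings(as.numeric(r[vi])) + 99.9)
      c(l, paste(r, collapse = "\t"))
    })
  } else if (defect == "missing_weather_day") {
    st <- paste0("WS_", first_sid)
    edit(paths$weather, function(l) {
      rows <- which(grepl(paste0("^", st, "\t"), l))
      mid <- rows[ceiling(length(rows) / 2)]
      l[-mid]
    })
  }
  paths
}
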