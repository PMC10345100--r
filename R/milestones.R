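#' Run the six integration milestones
#'
#' Executes, in order, the reuse workflow a researcher follows over a
#' discovered phenotyping dataset and a weather dataset: (a) discovery —
#' when an FDP crawl is supplied, select the relevant dataset from its
#' embedded MIAPPE summary alone; (b) study summaries; (c) genotype
#' overlap across studies; (d) nearest-weather-station matching;
#' (e) per-genotype trait means across environments (union and
#' complete-case restrictions); (f) cumulative PBTT per environment and
#' genotype stability lines. Any stage failure halts with the stage name.
#'
#' @param pheno_source phenotypic source ([source_model()] and friends).
#' @param weather_source weather source.
#' @param variable_id trait to aggregate (e.g. `"tubweight"`).
#' @param params [pbtt_params()].
#' @param out_dir when given, writes `studies.tsv`,
#'   `common_genotypes.txt`, `station_matches.tsv`, `trait_matrix.tsv`,
#'   `pbtt.tsv`, `stability.tsv`, the two charts and `summary.log` there.
#' @param crawl optional [crawl_fdp()] result for the discovery stage.
#' @return list of milestone results plus a `counts` log.
#' @export
run_milestones <- function(pheno_source, weather_source, variable_id,
                           params = pbtt_params(), out_dir = NULL,
                           crawl = NULL) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop_fp("milestone '%s' failed: %s", name, conditionMessage(e)))

  discovered <- NULL
  if (!is.null(crawl))
    discovered <- stage("discovery", discover_datasets(crawl, function(s)
      variable_id %in% s$variable_ids))
  studies <- stage("study_summaries", summarize_studies(pheno_source))
  common <- stage("genotype_overlap", overlap_genotypes(pheno_source))
  wt <- stage("weather_acquisition", as_weather_tables(weather_source))
  matches <- stage("station_matching",
                   match_weather_stations(studies, wt$stations))
  traits_union <- stage("trait_aggregation",
                        genotype_trait_means(pheno_source, variable_id))
  traits_complete <- stage("trait_aggregation",
                           genotype_trait_means(pheno_source, variable_id,
                                                restrict = "complete_cases"))
  inv <- as_pheno_tables(pheno_source)$inv
  pbtt <- stage("pbtt", study_pbtt(inv, matches, wt$observations, params))
  stability <- stage("stability", stability_lines(
    traits_union, pbtt, all_genotypes = unique(unlist(study_genotype_sets(inv)))))

  counts <- c(datasets_discovered = length(discovered),
              studies = nrow(studies),
              common_genotypes = length(common),
              stations = nrow(wt$stations),
              union_trait_genotypes = length(unique(traits_union$genotype_id)),
              complete_case_genotypes = length(unique(traits_complete$genotype_id)),
              stability_rising = sum(stability$direction == "rising"),
              stability_falling = sum(stability$direction == "falling"),
              stability_flat = sum(stability$direction == "flat"))

  out <- list(discovered = discovered, studies = studies, common_genotypes = common,
              station_matches = matches, traits_union = traits_union,
              traits_complete = traits_complete, pbtt = pbtt,
              stability = stability, counts = counts)
  if (!is.null(out_dir)) write_milestone_reports(out, out_dir)
  out
}

#' Trait summary as a genotype-by-study matrix table
#' @param summary an `fp_trait_summary`.
#' @return data frame: `genotype_id` plus one mean-value column per study.
#' @export
trait_matrix <- function(summary) {
  g <- c_sort(unique(summary$genotype_id))
  s <- c_sort(unique(summary$study_id))
  m <- matrix(NA_real_, length(g), length(s), dimnames = list(g, s))
  m[cbind(match(summary$genotype_id, g), match(summary$study_id, s))] <-
    summary$mean_value
  cbind(data.frame(genotype_id = g, stringsAsFactors = FALSE),
        as.data.frame(m, optional = TRUE))
}

write_milestone_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_milestone_tsv(res$studies, file.path(out_dir, "studies.tsv"))
  writeLines(res$common_genotypes, file.path(out_dir, "common_genotypes.txt"),
             useBytes = TRUE)
  write_milestone_tsv(res$station_matches, file.path(out_dir, "station_matches.tsv"))
  write_milestone_tsv(trait_matrix(res$traits_union),
                      file.path(out_dir, "trait_matrix.tsv"))
  write_milestone_tsv(res$pbtt, file.path(out_dir, "pbtt.tsv"))
  write_milestone_tsv(res$stability, file.path(out_dir, "stability.tsv"))
  for (pl in c("trait_means", "stability")) {
    p <- switch(pl, trait_means = plot_trait_means(res$traits_union),
                stability = plot_stability(res$stability))
    suppressMessages(ggplot2::ggsave(file.path(out_dir, paste0(pl, ".png")), p,
                                     width = 8, height = 5, dpi = 120))
  }
  log_lines <- c(sprintf("fairphen milestone run, %d studies", res$counts[["studies"]]),
                 sprintf("%s: %d", names(res$counts), res$counts))
  writeLines(log_lines, file.path(out_dir, "summary.log"), useBytes = TRUE)
  invisible(out_dir)
}
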