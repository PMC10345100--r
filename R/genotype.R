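#' Genotype of an observation unit
#'
#' The genotype of a unit is its biological material after synonym
#' resolution; for pre-averaged `"genotype"`-level units this is the unit's
#' own identity mapping.
#'
#' @param inv an [miappe_investigation()].
#' @param unit_id observation-unit identifier (unique within its study; this
#'   helper searches all studies).
#' @return the biological material (genotype) id, a length-1 character.
#' @export
genotype_of_unit <- function(inv, unit_id) {
  units <- all_units(inv)
  i <- match(unit_id, units$id)
  if (is.na(i)) stop_fp("unknown observation unit: '%s'", unit_id)
  resolve_synonyms(inv, units$biological_material_id[i])
}

#' Resolve genotype synonyms to canonical material ids
#'
#' Trials relayed through several hands carry genotype-name translation
#' files; the model stores alternative names in
#' `biological_materials$synonyms` and maps them onto the canonical id.
#' Unknown names pass through unchanged.
#' @param inv investigation.
#' @param ids character vector of genotype names.
#' @return character vector of canonical ids.
#' @export
resolve_synonyms <- function(inv, ids) {
  bm <- inv$biological_materials
  syn_map <- list()
  for (i in seq_len(nrow(bm))) {
    for (s in split_multi(bm$synonyms[i])) syn_map[[s]] <- bm$id[i]
  }
  vapply(ids, function(x) {
    if (!is.null(syn_map[[x]]) && !(x %in% bm$id)) syn_map[[x]] else x
  }, character(1), USE.NAMES = FALSE)
}

#' Genotypes common to a set of studies
#'
#' Intersects, over the named studies, the sets of biological materials
#' attached to each study's observation units — the multi-environment
#' prerequisite check ("do these trials share genotypes?").
#'
#' @param inv an [miappe_investigation()].
#' @param study_ids studies to intersect; defaults to all.
#' @return sorted character vector of genotype ids present in every named
#'   study.
#' @export
common_genotype_ids <- function(inv, study_ids = NULL) {
  sids <- vapply(inv$studies, `[[`, "", "id")
  if (is.null(study_ids)) study_ids <- sids
  missing <- setdiff(study_ids, sids)
  if (length(missing) > 0L)
    stop_fp("unknown study id(s): %s", paste(missing, collapse = ", "))
  sets <- lapply(study_ids, function(id) {
    s <- get_study(inv, id)
    unique(resolve_synonyms(inv, s$observation_units$biological_material_id))
  })
  c_sort(Reduce(intersect, sets))
}

#' Per-study genotype sets
#' @param inv investigation.
#' @return named list (by study id) of sorted genotype-id vectors.
#' @export
study_genotype_sets <- function(inv) {
  out <- lapply(inv$studies, function(s)
    c_sort(unique(resolve_synonyms(inv, s$observation_units$biological_material_id))))
  stats::setNames(out, study_ids(inv))
}
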