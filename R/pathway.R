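#' KO sets for the methanogenesis pathways
#'
#' Returns the KEGG orthology identifiers used to quantify the
#' methanogenic pathways: KOs unique to acetoclastic methanogenesis
#' (module M00357), unique to hydrogenotrophic methanogenesis (M00567),
#' shared between the two (the mtr complex), common to all routes
#' (mcr/hdr/mvh/fdh) and specific to methylotrophic methanogenesis
#' (M00356). Only the two unique sets enter factor F; the rest are
#' reported for context.
#'
#' @param override_path optional TSV with columns `ko`, `set` (set names as
#'   in the return value) replacing the packaged definitions.
#' @return named list of character vectors: `acetoclastic_unique`,
#'   `hydrogenotrophic_unique`, `shared_aceto_hydro`, `common`,
#'   `methylotrophic`. The five sets are pairwise disjoint.
#' @export
methanogenesis_ko_sets <- function(override_path = NULL) {
  sets <- list(
    acetoclastic_unique = c("K00925", "K00625", "K01895", "K00193",
                            "K00197", "K00194"),
    hydrogenotrophic_unique = c("K00200", "K00201", "K00202", "K00203",
                                "K11261", "K00205", "K00672", "K01499",
                                "K00319", "K13942", "K00320"),
    shared_aceto_hydro = sprintf("K%05d", 577:584),
    common = c("K00399", "K00401", "K00402", "K03388", "K03389", "K03390",
               "K08264", "K08265", "K14126", "K14127", "K22516", "K00125"),
    methylotrophic = c("K14080", "K04480", "K14081"))
  if (!is.null(override_path)) {
    tab <- utils::read.delim(override_path, stringsAsFactors = FALSE)
    if (!all(c("ko", "set") %in% names(tab)))
      stop("KO-set override needs columns 'ko' and 'set'")
    sets <- split(tab$ko, tab$set)
  }
  all_ko <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ko))
    stop("KO sets overlap: ", paste(unique(all_ko[duplicated(all_ko)]),
                                    collapse = ", "))
  if (!length(sets$acetoclastic_unique) || !length(sets$hydrogenotrophic_unique))
    stop("acetoclastic_unique and hydrogenotrophic_unique must be nonempty")
  sets
}

#' Pathway abundance sums for one KO-level profile
#'
#' @param profile named numeric vector of relative abundances indexed by KO
#'   id (a single sample or plant column at KO level). KOs absent from the
#'   profile contribute 0.
#' @param sets KO sets from [methanogenesis_ko_sets()].
#' @return named numeric vector with `aceto_sum`, `hydro_sum`,
#'   `methylo_sum`, `shared_sum`, `common_sum`.
#' @export
pathway_sums <- function(profile, sets = methanogenesis_ko_sets()) {
  take <- function(kos) sum(profile[names(profile) %in% kos])
  c(aceto_sum = take(sets$acetoclastic_unique),
    hydro_sum = take(sets$hydrogenotrophic_unique),
    methylo_sum = take(sets$methylotrophic),
    shared_sum = take(sets$shared_aceto_hydro),
    common_sum = take(sets$common))
}

#' Factor F: acetoclastic over hydrogenotrophic abundance
#'
#' F is the ratio of the summed abundances of KOs unique to acetoclastic
#' methanogenesis over those unique to hydrogenotrophic methanogenesis.
#' `hydro_sum = 0` with positive `aceto_sum` yields `Inf`; both zero
#' yields `NaN` (no methanogenesis signal).
#'
#' @param aceto_sum,hydro_sum nonnegative abundance sums (percent).
#' @return the ratio F.
#' @export
compute_F <- function(aceto_sum, hydro_sum) {
  if (any(aceto_sum < 0) || any(hydro_sum < 0))
    stop("pathway sums must be nonnegative")
  ifelse(hydro_sum == 0,
         ifelse(aceto_sum > 0, Inf, NaN),
         aceto_sum / hydro_sum)
}

#' Classify factor F into a pathway label
#'
#' `F >= hi` is called acetoclastic, `F <= lo` hydrogenotrophic, values in
#' between indicate that both pathways contribute substantially
#' (thresholds inclusive).
#'
#' @param F factor F value(s); nonnegative or `Inf`.
#' @param lo,hi classification thresholds (defaults 0.4 and 2.5).
#' @return character vector of labels in
#'   `c("acetoclastic", "hydrogenotrophic", "both")`.
#' @export
classify_F <- function(F, lo = 0.4, hi = 2.5) {
  stopifnot(lo < hi)
  if (any(is.nan(F)))
    stop("no methanogenesis signal: both pathway sums are zero")
  if (any(F < 0)) stop("F must be nonnegative")
  ifelse(F >= hi, "acetoclastic",
         ifelse(F <= lo, "hydrogenotrophic", "both"))
}

#' Classify samples or plants by dominant methanogenic pathway
#'
#' Computes pathway sums, factor F and a label per unit. In
#' `mode = "per_plant"` the matrix is first averaged per plant with
#' [plant_means()]; in `mode = "per_replicate"` every sample column is
#' classified on its own (the mode used to partition replicates for
#' network inference). Units for which F is undefined (no methanogenesis
#' protein at all) get an `NA` label and a warning; remaining units are
#' still classified.
#'
#' @param m an [abundance_matrix()] at KO level (rows keyed by KO id),
#'   normalized per sample.
#' @param sets KO sets from [methanogenesis_ko_sets()].
#' @param mode `"per_plant"` or `"per_replicate"`.
#' @param lo,hi thresholds passed to [classify_F()].
#' @return data.frame with columns `unit_id`, `aceto_sum`, `hydro_sum`,
#'   `methylo_sum`, `shared_sum`, `common_sum`, `F`, `label`; in
#'   `per_plant` mode an additional `majority_label` column gives the
#'   majority vote of the plant's per-replicate labels (`NA` on a tie),
#'   so plants whose replicates disagree with the plant-mean call are
#'   visible rather than silently reconciled.
#' @export
classify_units <- function(m, sets = methanogenesis_ko_sets(),
                           mode = c("per_plant", "per_replicate"),
                           lo = 0.4, hi = 2.5) {
  mode <- match.arg(mode)
  majority <- NULL
  if (mode == "per_plant") {
    if (length(unique(m$plant)) < ncol(m$values)) {
      per_rep <- classify_units(m, sets, "per_replicate", lo, hi)
      majority <- vapply(unique(m$plant), function(p) {
        tab <- sort(table(per_rep$label[m$plant == p]), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_character_
        else names(tab)[1]
      }, character(1))
    }
    m <- plant_means(m, renormalize = TRUE)
  }
  units <- colnames(m$values)
  sums <- t(apply(m$values, 2, function(col) {
    names(col) <- rownames(m$values)
    pathway_sums(col, sets)
  }))
  F <- compute_F(sums[, "aceto_sum"], sums[, "hydro_sum"])
  label <- rep(NA_character_, length(F))
  ok <- !is.nan(F)
  if (any(!ok))
    warning("no methanogenesis signal in unit(s): ",
            paste(units[!ok], collapse = ", "))
  label[ok] <- classify_F(F[ok], lo = lo, hi = hi)
  out <- data.frame(unit_id = units, sums, F = F, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(majority)) out$majority_label <- majority[out$unit_id]
  out
}

#' Load the packaged per-plant methanogenesis KO abundance table
#'
#' Mean relative abundances (percent of total protein abundance) of every
#' methanogenesis-associated KO for the 16 biogas plants of the study
#' design this package targets, together with the published per-plant
#' pathway labels.
#'
#' @return list with `ko_table` (data.frame: ko, pathway_group, enzyme,
#'   one column per plant) and `plant_labels` (data.frame: plant_id,
#'   printed_label).
#' @export
load_reference_ko_table <- function() {
  f1 <- system.file("extdata", "table1_methanogenesis_ko.tsv",
                    package = "biogasnet", mustWork = TRUE)
  f2 <- system.file("extdata", "table1_plant_labels.tsv",
                    package = "biogasnet", mustWork = TRUE)
  list(ko_table = utils::read.delim(f1, check.names = FALSE,
                                    stringsAsFactors = FALSE),
       plant_labels = utils::read.delim(f2, stringsAsFactors = FALSE))
}
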