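#' Recompute published-style network summary statistics from a link table
#'
#' Given a unique virus-host pair table (and optionally per-sample
#' microscopy counts), recomputes the headline network statistics a
#' field-study report of this design prints: normalized Barber modularity
#' and module count, NODF, nestedness temperature score, the specialist
#' fraction of viruses, pair/virus/host counts, and the median bacterial
#' density. Intended for re-analysis of a study's released link tables.
#'
#' @param linksPath TSV with `virus_pop_id` and `host_species_id` columns
#'   (`virus`/`host` are accepted as synonyms).
#' @param microscopyPath Optional CSV of microscopy counts
#'   ([readMicroscopy()] format).
#' @param nRestarts Modularity restarts.
#' @param nPermutations Null-model permutations for the NODF p-value.
#' @param seed Integer seed.
#' @return Named list of summary statistics.
#' @export
surveySummaryStats <- function(linksPath, microscopyPath = NULL,
                               nRestarts = 50, nPermutations = 999, seed = 1) {
  links <- readTsv(linksPath)
  if (!"virus_pop_id" %in% names(links) && "virus" %in% names(links)) {
    links$virus_pop_id <- links$virus
  }
  if (!"host_species_id" %in% names(links) && "host" %in% names(links)) {
    links$host_species_id <- links$host
  }
  .requireCols(links, c("virus_pop_id", "host_species_id"), "link table")
  bm <- buildIncidenceMatrix(links)
  mod <- barberModularity(bm, nRestarts = nRestarts, seed = seed)
  temp <- nestednessTemperature(bm)
  deg <- degreeStats(bm)
  p_nodf <- nullModelSS(bm, nodf, nPermutations, seed)
  out <- list(
    n_pairs = sum(incidence(bm)),
    n_viruses = ncol(incidence(bm)),
    n_hosts = nrow(incidence(bm)),
    q_normalized = mod$q_normalized,
    n_modules = mod$n_modules,
    nodf = nodf(bm),
    nodf_p_value = p_nodf$p_value,
    nestedness_score = temp$score,
    specialist_percent = deg$specialist_percent)
  if (!is.null(microscopyPath)) {
    micro <- readMicroscopy(microscopyPath)
    out$median_cells_per_ml <- stats::median(micro$cells_per_ml)
    out$median_vlp_per_ml <- stats::median(micro$vlp_per_ml)
    out$median_vmr <- stats::median(micro$vmr)
  }
  out
}
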