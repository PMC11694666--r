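#' Length-normalized relative abundances
#'
#' Computes, per sample, the genome-length-normalized relative abundance of
#' every entity in a count table: `weight = reads / genome_length`,
#' `relative = weight / sum(weight)` (sums to 1 per sample), plus the
#' fractional abundance `reads / total reads`. Length normalization inverts
#' the reads-scale-with-DNA-mass sampling model, so at high depth the
#' relative abundances converge to the underlying genome frequencies.
#'
#' @param counts data.frame with columns `entity_id`, `sample_id`, `reads`,
#'   `genome_length` (non-negative reads, lengths >= 1); extra columns such
#'   as `fraction` and `kind` are carried through.
#' @return The input with `weight`, `relative` and `fractional` columns
#'   appended.
#' @export
relativeAbundance <- function(counts) {
  .requireCols(counts, c("entity_id", "sample_id", "reads", "genome_length"),
               "count table")
  if (any(counts$genome_length < 1)) stop("genome lengths must be >= 1", call. = FALSE)
  if (any(counts$reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  totals <- tapply(counts$reads, counts$sample_id, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with all-zero counts: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  counts$weight <- counts$reads / counts$genome_length
  wsum <- stats::ave(counts$weight, counts$sample_id, FUN = sum)
  rsum <- stats::ave(counts$reads, counts$sample_id, FUN = sum)
  counts$relative <- counts$weight / wsum
  counts$fractional <- counts$reads / rsum
  counts
}

#' Scale relative abundances to genomes per ml with microscopy counts
#'
#' Converts relative abundances to absolute genome densities by multiplying
#' with direct epifluorescence microscopy counts: viral entities are scaled
#' by the virus-like-particle density (`vlp_per_ml`) and bacterial entities
#' by the cell density (`cells_per_ml`). Relative abundances are
#' renormalized within each entity class per sample first, so the scaled
#' densities of each class sum exactly to its microscopy total and ratios
#' between entities of the same class are preserved.
#'
#' @param relative Output of [relativeAbundance()]; must carry a `kind`
#'   column with values `"virus"` and/or `"host"`.
#' @param micro data.frame with `sample_id`, `vlp_per_ml`, `cells_per_ml`
#'   covering every sample in `relative`.
#' @return The input with a `genomes_per_ml` column appended.
#' @export
scaleByMicroscopy <- function(relative, micro) {
  .requireCols(relative, c("entity_id", "sample_id", "relative", "kind"),
               "relative abundance table")
  .requireCols(micro, c("sample_id", "vlp_per_ml", "cells_per_ml"),
               "microscopy table")
  missing <- setdiff(unique(relative$sample_id), micro$sample_id)
  if (length(missing)) {
    stop("microscopy counts missing for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(relative$sample_id, micro$sample_id)
  total <- ifelse(relative$kind == "virus", micro$vlp_per_ml[idx],
                  micro$cells_per_ml[idx])
  class_sum <- stats::ave(relative$relative,
                          relative$sample_id, relative$kind, FUN = sum)
  relative$genomes_per_ml <- relative$relative / class_sum * total
  relative
}

#' Virus-to-host ratios for linked pairs
#'
#' For every unique virus-host pair and sample, computes the cell-associated
#' VHR (cell-associated viral genomes/ml over host genomes/ml; a proxy for
#' ongoing viral production) and the free VHR (free viral genomes/ml over
#' the same host genomes/ml denominator). Pairs whose host density is zero
#' in a sample get `NA` VHRs and are excluded from downstream quartiles; a
#' virus undetected in a fraction gets VHR 0 there.
#'
#' @param pairs data.frame with `virus_pop_id`, `host_species_id`.
#' @param virusGpm Scaled abundance table ([scaleByMicroscopy()]) for
#'   viruses, carrying a `fraction` column with `"free"` and/or
#'   `"cell_associated"` rows.
#' @param hostGpm Scaled abundance table for hosts (cell fraction).
#' @return data.frame: one row per pair and sample with `vhr_cell`,
#'   `vhr_free`.
#' @export
computeVHR <- function(pairs, virusGpm, hostGpm) {
  .requireCols(pairs, c("virus_pop_id", "host_species_id"), "pair table")
  .requireCols(virusGpm, c("entity_id", "sample_id", "fraction", "genomes_per_ml"),
               "virus abundance table")
  .requireCols(hostGpm, c("entity_id", "sample_id", "genomes_per_ml"),
               "host abundance table")
  samples <- sort(unique(hostGpm$sample_id))
  lookup <- function(tab, ids, s) {
    v <- tab$genomes_per_ml[match(paste(ids, s), paste(tab$entity_id, tab$sample_id))]
    ifelse(is.na(v), 0, v)
  }
  v_cell <- virusGpm[virusGpm$fraction == "cell_associated", , drop = FALSE]
  v_free <- virusGpm[virusGpm$fraction == "free", , drop = FALSE]
  out <- do.call(rbind, lapply(samples, function(s) {
    h <- lookup(hostGpm, pairs$host_species_id, s)
    vc <- lookup(v_cell, pairs$virus_pop_id, s)
    vf <- lookup(v_free, pairs$virus_pop_id, s)
    data.frame(virus_pop_id = pairs$virus_pop_id,
               host_species_id = pairs$host_species_id,
               sample_id = s,
               vhr_cell = ifelse(h > 0, vc / h, NA_real_),
               vhr_free = ifelse(h > 0, vf / h, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Abundance rank statistics across samples
#'
#' Ranks entities within each sample (rank 1 = most abundant; ties share
#' the average rank) and summarizes each entity's median rank, rank standard
#' deviation, and abundance standard deviation across samples. When a pair
#' table is supplied, also reports the two-sided Spearman rank correlation
#' between the median ranks of linked viruses and hosts (viruses and hosts
#' are ranked within their own class).
#'
#' @param gpm Abundance table with `entity_id`, `sample_id`,
#'   `genomes_per_ml`, and a `kind` column when both classes are present.
#' @param pairs Optional pair table (`virus_pop_id`, `host_species_id`).
#' @return A list: `stats` (per-entity data.frame with `median_rank`,
#'   `rank_sd`, `abundance_sd`) and, when `pairs` is given, `spearman`
#'   (list with `rho`, `p_value`, `n`).
#' @export
rankStatistics <- function(gpm, pairs = NULL) {
  .requireCols(gpm, c("entity_id", "sample_id", "genomes_per_ml"),
               "abundance table")
  if (!"kind" %in% names(gpm)) gpm$kind <- "entity"
  grp <- interaction(gpm$sample_id, gpm$kind, drop = TRUE)
  gpm$rank <- stats::ave(-gpm$genomes_per_ml, grp,
                         FUN = function(x) rank(x, ties.method = "average"))
  per_entity <- lapply(split(gpm, gpm$entity_id), function(sub) {
    data.frame(entity_id = sub$entity_id[1], kind = sub$kind[1],
               median_rank = stats::median(sub$rank),
               rank_sd = stats::sd(sub$rank),
               abundance_sd = stats::sd(sub$genomes_per_ml),
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, per_entity)
  rownames(stats_df) <- NULL
  out <- list(stats = stats_df)
  if (!is.null(pairs)) {
    .requireCols(pairs, c("virus_pop_id", "host_species_id"), "pair table")
    mr <- stats::setNames(stats_df$median_rank, stats_df$entity_id)
    v <- mr[pairs$virus_pop_id]
    h <- mr[pairs$host_species_id]
    ok <- !is.na(v) & !is.na(h)
    ct <- suppressWarnings(
      stats::cor.test(v[ok], h[ok], method = "spearman", exact = FALSE))
    out$spearman <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                         n = sum(ok))
  }
  out
}
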