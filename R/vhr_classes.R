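#' Per-pair median VHRs
#'
#' Collapses a per-sample VHR table to one row per virus-host pair with the
#' median free and cell-associated VHR over the samples where the VHR is
#' defined.
#'
#' @param vhr Output of [computeVHR()].
#' @return data.frame: `virus_pop_id`, `host_species_id`,
#'   `median_vhr_free`, `median_vhr_cell`.
#' @export
pairMedianVHR <- function(vhr) {
  .requireCols(vhr, c("virus_pop_id", "host_species_id", "vhr_free", "vhr_cell"),
               "VHR table")
  key <- paste(vhr$virus_pop_id, vhr$host_species_id, sep = "\r")
  rows <- lapply(split(vhr, key), function(sub) {
    data.frame(virus_pop_id = sub$virus_pop_id[1],
               host_species_id = sub$host_species_id[1],
               median_vhr_free = stats::median(sub$vhr_free, na.rm = TRUE),
               median_vhr_cell = stats::median(sub$vhr_cell, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$virus_pop_id, out$host_species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' VHR quartile thresholds
#'
#' Lower (Q1) and upper (Q3) quartiles of the per-pair median VHRs, pooled
#' across pairs, computed separately for the free and cell-associated
#' fractions. Quartiles use linear interpolation between order statistics.
#' By default VHRs are compared on the log10 scale (ratio axes span
#' decades); non-positive medians are excluded from threshold estimation on
#' the log scale but still classify as "low" downstream.
#'
#' @param pairs Per-pair median VHR table ([pairMedianVHR()]), or a
#'   per-sample VHR table which is collapsed first.
#' @param scale `"log10"` (default) or `"linear"`.
#' @return List of class `VhrThresholds`: `q1_free`, `q3_free`, `q1_cell`,
#'   `q3_cell`, `scale`.
#' @export
vhrQuartiles <- function(pairs, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (!"median_vhr_free" %in% names(pairs)) pairs <- pairMedianVHR(pairs)
  f <- pairs$median_vhr_free
  cc <- pairs$median_vhr_cell
  if (scale == "log10") {
    f <- log10(f[!is.na(f) & f > 0])
    cc <- log10(cc[!is.na(cc) & cc > 0])
  } else {
    f <- f[!is.na(f)]
    cc <- cc[!is.na(cc)]
  }
  if (length(f) < 4 || length(cc) < 4) {
    stop("need at least 4 pairs with defined VHR in both fractions", call. = FALSE)
  }
  qf <- stats::quantile(f, c(0.25, 0.75), type = 7, names = FALSE)
  qc <- stats::quantile(cc, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(q1_free = qf[1], q3_free = qf[2],
                 q1_cell = qc[1], q3_cell = qc[2], scale = scale),
            class = "VhrThresholds")
}

#' Classify virus-host pairs into VHR production categories
#'
#' Labels each pair by its position relative to the VHR quartile lines:
#' high means strictly above Q3, low strictly below Q1 (points on the lines
#' are middle). Category 1 = low cell-associated and high free VHR (stable
#' particles / slow decay); 2 = high in both fractions (productive lytic
#' infections); 3 = low in both (low production, prophage-enriched hosts);
#' 4 = high cell-associated and low free VHR (fast decay or long latency);
#' everything else is `"middle"`. Every pair receives exactly one label.
#'
#' @param pairs Per-pair median VHR table (or per-sample table, collapsed
#'   first).
#' @param thr Thresholds from [vhrQuartiles()].
#' @return The pair table with a `category` column (`"1"`, `"2"`, `"3"`,
#'   `"4"`, `"middle"`).
#' @export
classifyVhrPairs <- function(pairs, thr) {
  stopifnot(inherits(thr, "VhrThresholds"))
  if (!"median_vhr_free" %in% names(pairs)) pairs <- pairMedianVHR(pairs)
  f <- pairs$median_vhr_free
  cc <- pairs$median_vhr_cell
  if (thr$scale == "log10") {
    f <- log10(f)        # zero VHR -> -Inf, classified low
    cc <- log10(cc)
  }
  high_f <- !is.na(f) & f > thr$q3_free
  low_f <- !is.na(f) & f < thr$q1_free
  high_c <- !is.na(cc) & cc > thr$q3_cell
  low_c <- !is.na(cc) & cc < thr$q1_cell
  category <- rep("middle", nrow(pairs))
  category[low_c & high_f] <- "1"
  category[high_c & high_f] <- "2"
  category[low_c & low_f] <- "3"
  category[high_c & low_f] <- "4"
  pairs$category <- category
  pairs
}

#' Compare a measurement across groups with a normality gate
#'
#' Applies a Shapiro-Wilk normality check per group; when any group departs
#' from normality (p < 0.05, or a group is too small to test) the omnibus
#' comparison is a Kruskal-Wallis test followed by pairwise two-sided
#' Wilcoxon rank-sum tests, otherwise one-way ANOVA followed by pairwise
#' t-tests. Wilcoxon tests use the exact method for group sizes up to 25
#' without ties and the normal approximation with continuity correction
#' otherwise. Pairwise results are summarized as compact letter groupings
#' at the `alpha` level (groups sharing a letter are not significantly
#' different). No multiple-testing correction is applied by default; Holm
#' adjustment is available via `adjust`.
#'
#' @param values Numeric vector of measurements.
#' @param labels Group label per value (>= 2 groups, each with >= 2
#'   observations).
#' @param alpha Significance level for the letter grouping.
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @param method `"auto"` (normality-gated, default), or force
#'   `"nonparametric"` (Kruskal-Wallis + Wilcoxon) / `"parametric"`
#'   (ANOVA + t-tests).
#' @return List: `normality` (per-group Shapiro p), `method`
#'   (`"kruskal-wallis"` or `"anova"`), `omnibus` (statistic, p), `pairwise`
#'   (data.frame `group1`, `group2`, `p_value`), `letters` (named character
#'   per group).
#' @export
compareGroups <- function(values, labels, alpha = 0.05, adjust = "none",
                          method = c("auto", "nonparametric", "parametric")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  groups <- split(values, labels)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  shapiro_p <- vapply(groups, function(g) {
    if (length(g) < 3 || length(unique(g)) == 1) return(NA_real_)
    stats::shapiro.test(g[seq_len(min(length(g), 5000))])$p.value
  }, numeric(1))
  normal <- switch(method,
                   auto = all(!is.na(shapiro_p) & shapiro_p >= 0.05),
                   nonparametric = FALSE,
                   parametric = TRUE)

  if (normal) {
    fit <- stats::aov(values ~ factor(labels))
    s <- summary(fit)[[1]]
    omnibus <- list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1])
    method <- "anova"
    pair_test <- function(a, b) stats::t.test(a, b)$p.value
  } else {
    kw <- stats::kruskal.test(values, factor(labels))
    omnibus <- list(statistic = unname(kw$statistic), p_value = kw$p.value)
    method <- "kruskal-wallis"
    pair_test <- function(a, b) {
      exact <- length(a) <= 25 && length(b) <= 25 &&
        !anyDuplicated(c(a, b))
      suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    }
  }

  gnames <- names(groups)
  combos <- utils::combn(gnames, 2)
  pvals <- apply(combos, 2, function(pr) pair_test(groups[[pr[1]]], groups[[pr[2]]]))
  pvals <- stats::p.adjust(pvals, method = adjust)
  pairwise <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                         p_value = pvals, stringsAsFactors = FALSE)

  letters_out <- .compactLetters(gnames, pairwise, alpha,
                                 order_by = vapply(groups, stats::median, numeric(1)))
  list(normality = shapiro_p, method = method, omnibus = omnibus,
       pairwise = pairwise, letters = letters_out)
}

# Compact letter display: letters = maximal cliques of the
# "not significantly different" graph, ordered by group median.
.compactLetters <- function(gnames, pairwise, alpha, order_by) {
  ord <- gnames[order(-order_by)]
  nsd <- matrix(TRUE, length(gnames), length(gnames),
                dimnames = list(gnames, gnames))
  sig <- pairwise$p_value < alpha
  nsd[cbind(pairwise$group1[sig], pairwise$group2[sig])] <- FALSE
  nsd[cbind(pairwise$group2[sig], pairwise$group1[sig])] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(nsd[ord, ord], mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  # stable order: by the best-ranked member of each clique
  first_member <- vapply(cliques, function(cl) min(match(names(cl), ord)), numeric(1))
  cliques <- cliques[order(first_member)]
  out <- stats::setNames(rep("", length(gnames)), ord)
  for (i in seq_along(cliques)) {
    members <- names(cliques[[i]])
    out[members] <- paste0(out[members], letters[i])
  }
  out[gnames]
}

#' Metabolic module presence calls
#'
#' Calls a metabolic module present in a bacterial genome (bMAG) when the
#' genome carries at least 50% of the module's steps or a minimum of three
#' steps; in a viral genome (vMAG) a single step suffices, but genomes with
#' any contamination are excluded entirely.
#'
#' @param stepAnnotations data.frame (`entity_id`, `step_id`) or named list
#'   of step-id vectors per entity.
#' @param defs data.frame (`module_id`, `step_id`) defining module steps.
#' @param entityKind `"bMAG"` or `"vMAG"`.
#' @param contamination Named numeric per entity (vMAG only); entities with
#'   contamination > 0 are dropped.
#' @return Logical matrix, entities x modules.
#' @export
modulePresence <- function(stepAnnotations, defs, entityKind = c("bMAG", "vMAG"),
                           contamination = NULL) {
  entityKind <- match.arg(entityKind)
  .requireCols(defs, c("module_id", "step_id"), "module definitions")
  if (is.data.frame(stepAnnotations)) {
    .requireCols(stepAnnotations, c("entity_id", "step_id"), "step annotations")
    ann <- split(stepAnnotations$step_id, stepAnnotations$entity_id)
  } else {
    ann <- stepAnnotations
  }
  known <- unique(defs$step_id)
  stray <- setdiff(unique(unlist(ann)), known)
  if (length(stray)) {
    warning("ignoring step id(s) absent from module definitions: ",
            paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (entityKind == "vMAG" && !is.null(contamination)) {
    clean <- names(contamination)[contamination == 0]
    ann <- ann[names(ann) %in% clean]
  }
  modules <- split(unique(defs[c("module_id", "step_id")])$step_id,
                   unique(defs[c("module_id", "step_id")])$module_id)
  entities <- names(ann)
  out <- matrix(FALSE, length(entities), length(modules),
                dimnames = list(entities, names(modules)))
  for (e in entities) {
    steps <- unique(ann[[e]])
    for (mo in names(modules)) {
      found <- sum(modules[[mo]] %in% steps)
      total <- length(modules[[mo]])
      out[e, mo] <- if (entityKind == "bMAG") {
        (found / total >= 0.5) || found >= 3
      } else {
        found >= 1
      }
    }
  }
  out
}

#' Metabolic module enrichment by VHR category
#'
#' For each module and VHR category 1-4, the difference between the module
#' frequency among that category's hosts and its frequency among
#' middle-VHR hosts.
#'
#' @param presence Logical presence matrix (hosts x modules) from
#'   [modulePresence()].
#' @param hostCategories Either a named character vector (host id ->
#'   category `"1"`..`"4"`/`"middle"`) or a data.frame with
#'   `host_species_id` and `category` columns (a host linked in several
#'   pairs may then appear under more than one category).
#' @return Numeric matrix, modules x categories (difference in frequency).
#' @export
categoryEnrichment <- function(presence, hostCategories) {
  if (is.data.frame(hostCategories)) {
    .requireCols(hostCategories, c("host_species_id", "category"),
                 "host category table")
    by_cat <- lapply(split(hostCategories$host_species_id,
                           hostCategories$category), unique)
  } else {
    by_cat <- lapply(split(names(hostCategories), hostCategories), unique)
  }
  middle <- intersect(by_cat[["middle"]], rownames(presence))
  if (!length(middle)) stop("middle VHR category is empty", call. = FALSE)
  base <- colMeans(presence[middle, , drop = FALSE])
  cats <- c("1", "2", "3", "4")
  out <- sapply(cats, function(cc) {
    hosts <- intersect(by_cat[[cc]], rownames(presence))
    if (!length(hosts)) return(rep(NA_real_, ncol(presence)))
    colMeans(presence[hosts, , drop = FALSE]) - base
  })
  rownames(out) <- colnames(presence)
  out
}

#' Modules shared between a linked virus and its host
#'
#' Flags (pair, module) combinations where both the virus and its linked
#' host carry the module, indicating potential metabolic overlap.
#'
#' @param presenceVirus,presenceHost Logical presence matrices from
#'   [modulePresence()].
#' @param pairs Pair table (`virus_pop_id`, `host_species_id`).
#' @return data.frame: `virus_pop_id`, `host_species_id`, `module_id`.
#' @export
sharedVirusHostModules <- function(presenceVirus, presenceHost, pairs) {
  .requireCols(pairs, c("virus_pop_id", "host_species_id"), "pair table")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    v <- pairs$virus_pop_id[i]; h <- pairs$host_species_id[i]
    if (!(v %in% rownames(presenceVirus)) || !(h %in% rownames(presenceHost))) next
    shared <- intersect(colnames(presenceVirus)[presenceVirus[v, ]],
                        colnames(presenceHost)[presenceHost[h, ]])
    if (length(shared)) {
      rows[[length(rows) + 1L]] <- data.frame(
        virus_pop_id = v, host_species_id = h, module_id = shared,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(virus_pop_id = character(), host_species_id = character(),
                      module_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
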