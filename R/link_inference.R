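#' Filter prophage candidate alignments
#'
#' Retains BLAST-style alignments of viral contigs against host genomes that
#' pass the prophage evidence thresholds: identity at or above
#' `minIdentity` and query (viral) coverage at or above `minQueryCoverage`,
#' where coverage is `100 * (|query_end - query_start| + 1) / query_length`.
#' Coverage is computed on the viral side only; both thresholds are
#' boundary-inclusive.
#'
#' @param hits data.frame of alignments with at least `query_id`,
#'   `subject_id`, `percent_identity`, `query_start`, `query_end`,
#'   `query_length` (and optionally `sample_id`).
#' @param minIdentity Minimum percent identity (default 95).
#' @param minQueryCoverage Minimum percent query coverage (default 99).
#' @return Link-evidence data.frame: `virus_pop_id`, `host_species_id`,
#'   `evidence_type = "prophage"`, `sample_id`, `support` (retained hits per
#'   pair and sample).
#' @export
filterProphageHits <- function(hits, minIdentity = 95, minQueryCoverage = 99) {
  .requireCols(hits, c("query_id", "subject_id", "percent_identity",
                       "query_start", "query_end"), "prophage hit table")
  if (!"query_length" %in% names(hits) || anyNA(hits$query_length)) {
    bad <- if ("query_length" %in% names(hits)) which(is.na(hits$query_length))[1] else 1L
    stop(sprintf("query_length missing for hit row %d (query %s)", bad,
                 hits$query_id[bad] %||% "?"), call. = FALSE)
  }
  coverage <- 100 * (abs(hits$query_end - hits$query_start) + 1) / hits$query_length
  keep <- hits$percent_identity >= minIdentity & coverage >= minQueryCoverage
  .asLinkEvidence(hits[keep, , drop = FALSE], "prophage",
                  virus_col = "query_id", host_col = "subject_id")
}

#' Filter CRISPR spacer matches
#'
#' Retains spacer-to-virus matches with at most `maxMmGaps` mismatches plus
#' gaps, coverage at least `requiredCoverage` percent, and a matched length
#' of at least `minLength` nucleotides. All thresholds boundary-inclusive.
#'
#' @param matches data.frame with `virus_id`, `host_id`,
#'   `mismatches_plus_gaps`, `coverage_percent`, `matched_length` (and
#'   optionally `sample_id`).
#' @param maxMmGaps Maximum mismatches + gaps (default 2).
#' @param requiredCoverage Required spacer coverage percent (default 100).
#' @param minLength Minimum matched length in nt (default 20).
#' @return Link-evidence data.frame with `evidence_type = "crispr"`.
#' @export
filterSpacerMatches <- function(matches, maxMmGaps = 2, requiredCoverage = 100,
                                minLength = 20) {
  .requireCols(matches, c("virus_id", "host_id", "mismatches_plus_gaps",
                          "coverage_percent", "matched_length"),
               "spacer match table")
  keep <- matches$mismatches_plus_gaps <= maxMmGaps &
    matches$coverage_percent >= requiredCoverage &
    matches$matched_length >= minLength
  .asLinkEvidence(matches[keep, , drop = FALSE], "crispr")
}

#' Filter proximity-ligation (Hi-C) links
#'
#' Transparent stand-in for proprietary Hi-C confidence scoring: retains
#' links with at least `minContacts` chimeric read contacts and a normalized
#' score of at least `minNormalizedScore`.
#'
#' @param links data.frame with `virus_id`, `host_id`, `sample_id`,
#'   `contact_count`, and optionally `normalized_score`.
#' @param minContacts Minimum contact count (default 2).
#' @param minNormalizedScore Minimum normalized score (default 0).
#' @return Link-evidence data.frame with `evidence_type = "hic"`; `support`
#'   is the summed contact count per pair and sample.
#' @export
filterHicLinks <- function(links, minContacts = 2, minNormalizedScore = 0) {
  .requireCols(links, c("virus_id", "host_id", "contact_count"), "Hi-C table")
  if (minContacts < 0 || minNormalizedScore < 0) {
    stop("Hi-C thresholds must be >= 0", call. = FALSE)
  }
  score <- links$normalized_score %||% rep(Inf, nrow(links))
  if (is.null(links$normalized_score)) score <- rep(Inf, nrow(links))
  keep <- links$contact_count >= minContacts & score >= minNormalizedScore
  .asLinkEvidence(links[keep, , drop = FALSE], "hic",
                  support_col = "contact_count")
}

# Collapse a filtered evidence table to one row per (virus, host, sample).
.asLinkEvidence <- function(df, type, virus_col = "virus_id",
                            host_col = "host_id", support_col = NULL) {
  sample <- if ("sample_id" %in% names(df)) df$sample_id else rep(NA_character_, nrow(df))
  support <- if (!is.null(support_col)) df[[support_col]] else rep(1L, nrow(df))
  if (!nrow(df)) {
    return(data.frame(virus_pop_id = character(), host_species_id = character(),
                      evidence_type = character(), sample_id = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  sample[is.na(sample)] <- ""   # aggregate() drops NA grouping levels
  agg <- stats::aggregate(
    list(support = support),
    by = list(virus_pop_id = df[[virus_col]], host_species_id = df[[host_col]],
              sample_id = sample),
    FUN = sum)
  agg$sample_id[agg$sample_id == ""] <- NA_character_
  agg$evidence_type <- type
  agg <- agg[order(agg$virus_pop_id, agg$host_species_id, agg$sample_id),
             c("virus_pop_id", "host_species_id", "evidence_type",
               "sample_id", "support")]
  rownames(agg) <- NULL
  agg
}

#' Dereplicate genomes into populations by single-linkage clustering
#'
#' Clusters genomes whose pairwise similarity satisfies
#' `ani >= aniThreshold` and, when `sharedThreshold` is not `NA`,
#' `shared >= sharedThreshold` (both boundary-inclusive), using
#' single linkage over the resulting graph. The representative of each
#' cluster is its longest member, ties broken by lexicographic id. Viral
#' populations conventionally use 95% ANI with 80% shared genes; host
#' species-level dereplication uses 95% ANI alone (`sharedThreshold = NA`).
#'
#' @param pairwise data.frame with columns `a`, `b`, `ani`, and (if a shared
#'   threshold is used) `shared`; treated as undirected.
#' @param aniThreshold ANI threshold in percent, in (0, 100].
#' @param sharedThreshold Shared-gene threshold in percent, or `NA`.
#' @param memberLengths Named numeric of genome lengths (bp); its names
#'   define the id universe and break cluster-representative ties.
#' @return A [PopulationMap-class].
#' @export
dereplicateGenomes <- function(pairwise, aniThreshold = 95,
                               sharedThreshold = NA, memberLengths) {
  if (aniThreshold <= 0 || aniThreshold > 100 ||
      (!is.na(sharedThreshold) && (sharedThreshold <= 0 || sharedThreshold > 100))) {
    stop("thresholds must be in (0, 100]", call. = FALSE)
  }
  ids <- names(memberLengths)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("memberLengths must be uniquely named by genome id", call. = FALSE)
  }
  if (nrow(pairwise)) {
    .requireCols(pairwise, c("a", "b", "ani"), "pairwise similarity table")
    unknown <- setdiff(unique(c(pairwise$a, pairwise$b)), ids)
    if (length(unknown)) {
      stop("pairwise table references unknown genome id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    pass <- pairwise$ani >= aniThreshold
    if (!is.na(sharedThreshold)) {
      .requireCols(pairwise, "shared", "pairwise similarity table")
      pass <- pass & pairwise$shared >= sharedThreshold
    }
    edges <- pairwise[pass, c("a", "b"), drop = FALSE]
  } else {
    edges <- data.frame(a = character(), b = character())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  map <- vapply(split(names(comp), comp), function(members) {
    lens <- memberLengths[members]
    members[order(-lens, members)][1]
  }, character(1))
  methods::new("PopulationMap",
               map = stats::setNames(unname(map[as.character(comp[ids])]), ids),
               aniThreshold = as.numeric(aniThreshold),
               sharedThreshold = as.numeric(sharedThreshold))
}

#' Merge link evidence into unique species-level pairs
#'
#' Re-keys evidence rows to population/species representatives and collapses
#' them to one row per unique (virus population, host species) pair, with
#' the union of evidence types, per-type support sums, and per-sample
#' presence. Running the function on its own output is a fixed point.
#'
#' @param evidence One link-evidence data.frame (rows from the three
#'   filters, `rbind`-ed), or a previously merged pair table.
#' @param virusMap,hostMap Optional [PopulationMap-class] objects; `NULL`
#'   leaves ids unchanged.
#' @return data.frame with one row per unique pair: `virus_pop_id`,
#'   `host_species_id`, `evidence_types` (comma-joined, sorted),
#'   `support_hic`, `support_prophage`, `support_crispr`, `n_samples`,
#'   `samples`. The attribute `"type_counts"` holds the number of unique
#'   pairs supported by each evidence type and overall.
#' @export
mergeLinks <- function(evidence, virusMap = NULL, hostMap = NULL) {
  if ("evidence_types" %in% names(evidence)) {
    evidence <- .meltMerged(evidence)
  }
  .requireCols(evidence, c("virus_pop_id", "host_species_id", "evidence_type"),
               "link evidence")
  ev <- evidence
  if (!nrow(ev)) {
    out <- data.frame(virus_pop_id = character(), host_species_id = character(),
                      evidence_types = character(), support_hic = numeric(),
                      support_prophage = numeric(), support_crispr = numeric(),
                      n_samples = integer(), samples = character(),
                      stringsAsFactors = FALSE)
    attr(out, "type_counts") <- c(hic = 0L, prophage = 0L, crispr = 0L, total = 0L)
    return(out)
  }
  if (!is.null(virusMap)) ev$virus_pop_id <- mapIds(virusMap, ev$virus_pop_id)
  if (!is.null(hostMap)) ev$host_species_id <- mapIds(hostMap, ev$host_species_id)
  if (is.null(ev$support)) ev$support <- 1L
  if (is.null(ev$sample_id)) ev$sample_id <- NA_character_

  key <- paste(ev$virus_pop_id, ev$host_species_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    sub <- ev[idx, , drop = FALSE]
    sup <- function(type) sum(sub$support[sub$evidence_type == type])
    smp <- sort(unique(stats::na.omit(sub$sample_id)))
    data.frame(virus_pop_id = sub$virus_pop_id[1],
               host_species_id = sub$host_species_id[1],
               evidence_types = paste(sort(unique(sub$evidence_type)),
                                      collapse = ","),
               support_hic = sup("hic"), support_prophage = sup("prophage"),
               support_crispr = sup("crispr"),
               n_samples = length(smp),
               samples = paste(smp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$virus_pop_id, out$host_species_id), , drop = FALSE]
  rownames(out) <- NULL
  has <- function(type) grepl(type, out$evidence_types, fixed = TRUE)
  attr(out, "type_counts") <- c(hic = sum(has("hic")),
                                prophage = sum(has("prophage")),
                                crispr = sum(has("crispr")),
                                total = nrow(out))
  out
}

# Expand a merged pair table back to long evidence form (fixed-point support).
.meltMerged <- function(merged) {
  do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    types <- strsplit(merged$evidence_types[i], ",", fixed = TRUE)[[1]]
    samples <- strsplit(merged$samples[i] %||% "", ",", fixed = TRUE)[[1]]
    if (!length(samples) || identical(samples, "")) samples <- NA_character_
    sup <- c(hic = merged$support_hic[i], prophage = merged$support_prophage[i],
             crispr = merged$support_crispr[i])
    grid <- expand.grid(evidence_type = types, sample_id = samples,
                        stringsAsFactors = FALSE)
    # spread support over the pair's samples so totals are conserved
    data.frame(virus_pop_id = merged$virus_pop_id[i],
               host_species_id = merged$host_species_id[i],
               evidence_type = grid$evidence_type,
               sample_id = grid$sample_id,
               support = unname(sup[grid$evidence_type]) / length(samples),
               stringsAsFactors = FALSE)
  }))
}

#' Classify viral lifestyle from prophage evidence and integrase carriage
#'
#' Prophage evidence takes precedence: an integrated virus is
#' `"temperate_prophage"`; otherwise an integrase-encoding virus is
#' `"temperate"`; everything else is `"lytic"`. The coarse label
#' `"temperate"` covers both temperate subclasses (see
#' [coarseLifestyle()]).
#'
#' @param virusIds Character vector of virus population ids.
#' @param hasIntegrase Logical vector (recycled if length 1) per virus.
#' @param prophagePairs data.frame with a `virus_pop_id` (or `virus_id`)
#'   column listing viruses with prophage evidence, or a character vector of
#'   virus ids.
#' @return Named character vector of labels.
#' @export
classifyLifestyle <- function(virusIds, hasIntegrase, prophagePairs = NULL) {
  if (length(hasIntegrase) == 1L) hasIntegrase <- rep(hasIntegrase, length(virusIds))
  stopifnot(length(hasIntegrase) == length(virusIds))
  prophage_viruses <- character()
  if (!is.null(prophagePairs)) {
    prophage_viruses <- if (is.data.frame(prophagePairs)) {
      unique(prophagePairs$virus_pop_id %||% prophagePairs$virus_id)
    } else unique(prophagePairs)
  }
  labels <- ifelse(virusIds %in% prophage_viruses, "temperate_prophage",
                   ifelse(hasIntegrase, "temperate", "lytic"))
  stats::setNames(labels, virusIds)
}

#' Collapse fine lifestyle labels to temperate/lytic
#'
#' @param labels Labels from [classifyLifestyle()].
#' @return Character vector with `"temperate_prophage"` and `"temperate"`
#'   both mapped to `"temperate"`.
#' @export
coarseLifestyle <- function(labels) {
  out <- ifelse(labels == "lytic", "lytic", "temperate")
  stats::setNames(out, names(labels))
}
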