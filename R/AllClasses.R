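#' CommunityTruth: ground truth for a simulated reef virus-bacteria community
#'
#' Holds the known state of a synthetic community: per-sample genome
#' abundances (genomes/ml) for hosts and for viruses in the free and
#' cell-associated size fractions, the planted infection network, viral
#' lifestyles, prophage carriage, and genome lengths. All downstream evidence
#' tables are derived from an object of this class, so pipeline results can
#' be compared against known truth.
#'
#' @slot hostIds,virusIds Character vectors of genome identifiers.
#' @slot hostAbundance Numeric matrix, hosts x samples, genomes/ml.
#' @slot virusAbundanceFree,virusAbundanceCell Numeric matrices, viruses x
#'   samples, genomes/ml in the free (<0.45 um) and cell-associated
#'   (>0.22 um) fractions.
#' @slot trueLinks data.frame with columns `virus_id`, `host_id`: the planted
#'   infection pairs.
#' @slot lifestyle Named character per virus, `"temperate"` or `"lytic"`.
#' @slot prophageCarriers data.frame (`virus_id`, `host_id`), a subset of
#'   `trueLinks` whose virus is integrated in that host.
#' @slot genomeLengths Named numeric, bp per genome (hosts and viruses).
#' @slot hostModule,virusModule Named integer, planted module membership
#'   (NA for hosts excluded from the link structure).
#' @slot seed Integer seed the community was generated from.
#'
#' @export
setClass("CommunityTruth", representation(
  hostIds = "character",
  virusIds = "character",
  hostAbundance = "matrix",
  virusAbundanceFree = "matrix",
  virusAbundanceCell = "matrix",
  trueLinks = "data.frame",
  lifestyle = "character",
  prophageCarriers = "data.frame",
  genomeLengths = "numeric",
  hostModule = "integer",
  virusModule = "integer",
  seed = "integer"
))

setValidity("CommunityTruth", function(object) {
  msg <- character()
  ids <- c(object@hostIds, object@virusIds)
  if (anyDuplicated(ids)) msg <- c(msg, "host and virus ids must be unique")
  for (nm in c("hostAbundance", "virusAbundanceFree", "virusAbundanceCell")) {
    if (any(slot(object, nm) <= 0)) {
      msg <- c(msg, sprintf("%s must be strictly positive", nm))
    }
  }
  if (!setequal(names(object@genomeLengths), ids)) {
    msg <- c(msg, "genomeLengths must name every host and virus")
  }
  if (any(object@genomeLengths < 1000)) {
    msg <- c(msg, "genome lengths must be >= 1000 bp")
  }
  tl <- object@trueLinks
  if (!all(c("virus_id", "host_id") %in% names(tl))) {
    msg <- c(msg, "trueLinks needs virus_id and host_id columns")
  } else {
    if (!all(tl$virus_id %in% object@virusIds) ||
        !all(tl$host_id %in% object@hostIds)) {
      msg <- c(msg, "trueLinks references unknown ids")
    }
  }
  if (!all(object@lifestyle %in% c("temperate", "lytic")) ||
      !setequal(names(object@lifestyle), object@virusIds)) {
    msg <- c(msg, "lifestyle must label every virus temperate or lytic")
  }
  pc <- object@prophageCarriers
  if (nrow(pc)) {
    link_keys <- paste(tl$virus_id, tl$host_id)
    if (!all(paste(pc$virus_id, pc$host_id) %in% link_keys)) {
      msg <- c(msg, "prophageCarriers must be a subset of trueLinks")
    }
    if (!all(object@lifestyle[pc$virus_id] == "temperate")) {
      msg <- c(msg, "every prophage-carrying virus must be temperate")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CommunityTruth", function(object) {
  cat("CommunityTruth:",
      length(object@hostIds), "hosts,",
      length(object@virusIds), "viruses,",
      ncol(object@hostAbundance), "samples\n")
  cat("  planted links:", nrow(object@trueLinks),
      "| modules:", length(unique(stats::na.omit(object@hostModule))),
      "| temperate viruses:", sum(object@lifestyle == "temperate"),
      "| prophage carriers:", nrow(object@prophageCarriers), "\n")
  cat("  seed:", object@seed, "\n")
})

#' BipartiteIncidence: binary hosts x viruses interaction matrix
#'
#' Rows are host species, columns are virus populations; a cell of 1 records
#' at least one inferred interaction. Construction guarantees no empty rows
#' or columns and deterministic (lexicographic) ordering.
#'
#' @slot incidence Binary numeric matrix with unique dimnames.
#' @export
setClass("BipartiteIncidence", representation(incidence = "matrix"))

setValidity("BipartiteIncidence", function(object) {
  m <- object@incidence
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    msg <- c(msg, "incidence matrix needs unique row and column names")
  }
  if (!all(m %in% c(0, 1))) msg <- c(msg, "incidence must be binary")
  if (nrow(m) && any(rowSums(m) == 0)) msg <- c(msg, "empty host row")
  if (ncol(m) && any(colSums(m) == 0)) msg <- c(msg, "empty virus column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BipartiteIncidence", function(object) {
  m <- object@incidence
  cat(sprintf("BipartiteIncidence: %d hosts x %d viruses, %d links (fill %.4f)\n",
              nrow(m), ncol(m), sum(m), mean(m)))
})

#' PopulationMap: genome-to-representative dereplication map
#'
#' Result of single-linkage clustering of genomes at ANI (and optionally
#' shared-gene) thresholds; maps every member genome to the representative
#' (longest member, ties broken lexicographically) of its cluster.
#'
#' @slot map Named character: member id -> representative id.
#' @slot aniThreshold ANI threshold (percent) used for clustering.
#' @slot sharedThreshold Shared-gene threshold (percent), or NA when only
#'   ANI was used (host-style species dereplication).
#' @export
setClass("PopulationMap", representation(
  map = "character",
  aniThreshold = "numeric",
  sharedThreshold = "numeric"
))

setValidity("PopulationMap", function(object) {
  m <- object@map
  msg <- character()
  if (is.null(names(m)) || anyDuplicated(names(m))) {
    msg <- c(msg, "map must be named uniquely by member id")
  }
  reps <- unique(unname(m))
  if (!all(m[reps] == reps)) {
    msg <- c(msg, "representatives must map to themselves")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationMap", function(object) {
  cat(sprintf("PopulationMap: %d members -> %d representatives (ANI >= %g%%%s)\n",
              length(object@map), length(unique(object@map)),
              object@aniThreshold,
              if (is.na(object@sharedThreshold)) ""
              else sprintf(", shared genes >= %g%%", object@sharedThreshold)))
})
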