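#' @name accessors
#' @title Accessors for reefnet S4 objects
#' @param object A reefnet S4 object.
#' @param ... Further arguments passed to methods.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("hostIds", function(object) standardGeneric("hostIds"))
#' @rdname accessors
#' @export
setGeneric("virusIds", function(object) standardGeneric("virusIds"))
#' @rdname accessors
#' @export
setGeneric("trueLinks", function(object) standardGeneric("trueLinks"))
#' @rdname accessors
#' @export
setGeneric("lifestyles", function(object) standardGeneric("lifestyles"))
#' @rdname accessors
#' @export
setGeneric("prophageCarriers", function(object) standardGeneric("prophageCarriers"))
#' @rdname accessors
#' @export
setGeneric("genomeLengths", function(object) standardGeneric("genomeLengths"))
#' @rdname accessors
#' @export
setGeneric("hostAbundance", function(object) standardGeneric("hostAbundance"))
#' @rdname accessors
#' @param fraction `"free"` or `"cell"`.
#' @export
setGeneric("virusAbundance", function(object, fraction = c("free", "cell"))
  standardGeneric("virusAbundance"))
#' @rdname accessors
#' @export
setGeneric("incidence", function(object) standardGeneric("incidence"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(object) standardGeneric("representatives"))

setMethod("hostIds", "CommunityTruth", function(object) object@hostIds)
setMethod("virusIds", "CommunityTruth", function(object) object@virusIds)
setMethod("trueLinks", "CommunityTruth", function(object) object@trueLinks)
setMethod("lifestyles", "CommunityTruth", function(object) object@lifestyle)
setMethod("prophageCarriers", "CommunityTruth", function(object) object@prophageCarriers)
setMethod("genomeLengths", "CommunityTruth", function(object) object@genomeLengths)
setMethod("hostAbundance", "CommunityTruth", function(object) object@hostAbundance)
setMethod("virusAbundance", "CommunityTruth", function(object, fraction = c("free", "cell")) {
  fraction <- match.arg(fraction)
  if (fraction == "free") object@virusAbundanceFree else object@virusAbundanceCell
})
setMethod("incidence", "BipartiteIncidence", function(object) object@incidence)
setMethod("representatives", "PopulationMap", function(object) unique(unname(object@map)))

#' Map member ids to their population representatives
#'
#' @param object A [PopulationMap-class].
#' @param ids Character vector of member ids; every id must be covered by the
#'   map.
#' @return Character vector of representative ids, same length as `ids`.
#' @export
mapIds <- function(object, ids) {
  stopifnot(is(object, "PopulationMap"))
  unknown <- setdiff(ids, names(object@map))
  if (length(unknown)) {
    stop("ids not covered by the population map: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  unname(object@map[ids])
}

#' @rdname nodf
#' @export
setGeneric("nodf", function(x) standardGeneric("nodf"))

#' @rdname nestednessTemperature
#' @export
setGeneric("nestednessTemperature", function(x) standardGeneric("nestednessTemperature"))

#' @rdname barberModularity
#' @export
setGeneric("barberModularity", function(x, nRestarts = 20, seed = 1, maxIter = 100)
  standardGeneric("barberModularity"))

#' @rdname nullModelSS
#' @export
setGeneric("nullModelSS", function(x, metric, nPermutations = 999, seed = 1)
  standardGeneric("nullModelSS"))

#' @rdname degreeStats
#' @export
setGeneric("degreeStats", function(x, hostClass = NULL) standardGeneric("degreeStats"))
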