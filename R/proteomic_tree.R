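#' Dice distance between two proteomes from summed homology bitscores
#'
#' `distance = max(0, 1 - 2 * ab / (aa + bb))`, where `ab` is the summed
#' bitscore of cross-matches between the protein sets of genomes A and B
#' and `aa`, `bb` are the summed self-match bitscores. Identical proteomes
#' score 0, proteomes with no shared homologs score 1; self-hit inflation
#' that would push the value below 0 is clipped to 0. Vectorized.
#'
#' @param ab,aa,bb Summed bitscores (`ab >= 0`, `aa > 0`, `bb > 0`).
#' @return Distance(s) in `[0, 1]`.
#' @export
diceDistance <- function(ab, aa, bb) {
  if (any(aa <= 0) || any(bb <= 0)) {
    stop("self-match bitscores must be positive", call. = FALSE)
  }
  if (any(ab < 0)) stop("cross-match bitscores must be >= 0", call. = FALSE)
  d <- 1 - 2 * ab / (aa + bb)
  d[d < 0] <- 0     # clip self-hit inflation; shape (incl. matrix) preserved
  d
}

#' Dice distance matrix from all-versus-all bitscore sums
#'
#' Builds a symmetric distance matrix from directed summed bitscores.
#' Directed sums for a pair are symmetrized by their mean (a missing
#' direction counts as 0); genome pairs absent from the table get distance
#' 1. Every genome must have a self row (`query == subject`).
#'
#' @param scores data.frame with columns `query_genome`, `subject_genome`,
#'   `summed_bitscore`, including self rows.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
buildDistanceMatrix <- function(scores) {
  .requireCols(scores, c("query_genome", "subject_genome", "summed_bitscore"),
               "bitscore table")
  genomes <- sort(unique(c(scores$query_genome, scores$subject_genome)))
  self <- scores[scores$query_genome == scores$subject_genome, , drop = FALSE]
  aa <- stats::setNames(rep(NA_real_, length(genomes)), genomes)
  aa[self$query_genome] <- self$summed_bitscore
  if (anyNA(aa)) {
    stop("missing self-match bitscore for: ",
         paste(utils::head(genomes[is.na(aa)], 5), collapse = ", "),
         call. = FALSE)
  }
  dirsum <- matrix(0, length(genomes), length(genomes),
                   dimnames = list(genomes, genomes))
  dirsum[cbind(scores$query_genome, scores$subject_genome)] <- scores$summed_bitscore
  ab <- (dirsum + t(dirsum)) / 2
  d <- diceDistance(ab, matrix(aa, length(genomes), length(genomes)),
                    matrix(aa, length(genomes), length(genomes), byrow = TRUE))
  diag(d) <- 0
  dimnames(d) <- list(genomes, genomes)
  d
}

#' Neighbor-joining proteomic tree from a Dice distance matrix
#'
#' Builds an unrooted Saitou-Nei neighbor-joining tree; negative branch
#' lengths (an NJ artifact on non-additive distances) are set to zero with
#' the deficit transferred to the adjacent branch so path lengths change as
#' little as possible. Taxa are ordered lexicographically before tree
#' construction for deterministic output. On additive matrices the tree
#' reproduces the input path distances exactly.
#'
#' @param d Symmetric distance matrix with at least 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
proteomicTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tree <- ape::nj(stats::as.dist(d))
  .clampNegativeBranches(tree)
}

# Zero out negative branch lengths, transferring the deficit to the
# adjacent branch toward the root of ape's internal edge ordering.
.clampNegativeBranches <- function(tree) {
  el <- tree$edge.length
  edge <- tree$edge
  for (i in order(el)) {
    if (el[i] >= 0) break
    deficit <- el[i]
    el[i] <- 0
    parent <- edge[i, 1]
    adjacent <- which(edge[, 2] == parent)
    if (length(adjacent)) {
      el[adjacent[1]] <- el[adjacent[1]] + deficit
    }
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
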