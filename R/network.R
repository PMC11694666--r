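#' Build a binary hosts x viruses incidence matrix from unique pairs
#'
#' @param pairs data.frame with `virus_pop_id` and `host_species_id`
#'   columns; duplicate rows collapse to a single 1.
#' @return A [BipartiteIncidence-class] with rows (hosts) and columns
#'   (viruses) in lexicographic order.
#' @export
buildIncidenceMatrix <- function(pairs) {
  .requireCols(pairs, c("virus_pop_id", "host_species_id"), "pair table")
  if (!nrow(pairs)) stop("cannot build a matrix from zero pairs", call. = FALSE)
  hosts <- sort(unique(pairs$host_species_id))
  viruses <- sort(unique(pairs$virus_pop_id))
  m <- matrix(0, length(hosts), length(viruses),
              dimnames = list(hosts, viruses))
  m[cbind(pairs$host_species_id, pairs$virus_pop_id)] <- 1
  methods::new("BipartiteIncidence", incidence = m)
}

.coerceMatrix <- function(x) {
  m <- if (methods::is(x, "BipartiteIncidence")) x@incidence else x
  storage.mode(m) <- "numeric"
  (m > 0) + 0
}

#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' Almeida-Neto NODF: over every unordered pair of rows and pair of columns
#' with strictly different marginal totals, the paired overlap is the
#' fraction of the sparser line's presences also found in the fuller line;
#' pairs with equal totals (or an empty sparser line) contribute 0. The
#' result is the mean paired overlap over all row pairs and column pairs,
#' reported on a 0-1 scale.
#'
#' @param x A [BipartiteIncidence-class] or binary matrix.
#' @return NODF in `[0, 1]`.
#' @rdname nodf
#' @export
setMethod("nodf", "BipartiteIncidence", function(x) nodf(.coerceMatrix(x)))

#' @rdname nodf
setMethod("nodf", "matrix", function(x) {
  m <- .coerceMatrix(x)
  line_sum <- function(mat) {
    n <- nrow(mat)
    if (n < 2) return(c(0, 0))
    fills <- rowSums(mat)
    overlap <- tcrossprod(mat)
    lo <- outer(fills, fills, pmin)
    use <- outer(fills, fills, "!=") & lo > 0
    contrib <- matrix(0, n, n)
    contrib[use] <- overlap[use] / lo[use]
    c(sum(contrib[upper.tri(contrib)]), n * (n - 1) / 2)
  }
  rows <- line_sum(m)
  cols <- line_sum(t(m))
  denom <- rows[2] + cols[2]
  if (denom == 0) return(0)
  (rows[1] + cols[1]) / denom
})

# Pack a matrix by descending marginal totals. Ties are broken by
# degree-weighted overlap scores (powers of the opposite marginals), which
# depend only on the matrix structure, making the packed form - and hence
# the temperature - invariant to row/column permutation of the input.
.packMatrix <- function(m) {
  r <- rowSums(m); cc <- colSums(m)
  row_ord <- order(-r, -(m %*% cc), -(m %*% cc^2), -(m %*% cc^3))
  col_ord <- order(-cc, -(t(m) %*% r), -(t(m) %*% r^2), -(t(m) %*% r^3))
  m[row_ord, col_ord, drop = FALSE]
}

#' Nestedness temperature of an incidence matrix
#'
#' Matrix-temperature nestedness in the Atmar-Patterson tradition: the
#' matrix is maximally packed (rows and columns sorted by descending
#' totals), each packed row's expected presences are its leftmost
#' `rowSum` cells (the row-marginal isocline), and every unexpected
#' presence or absence contributes its squared distance from the row
#' boundary, normalized by the largest distance attainable in that row.
#' The mean squared unexpectedness is scaled by the conventional constant
#' (100 / 0.04492, the expectation under total disorder) and truncated to
#' `[0, 100]`; 0 is perfectly nested. Also returns
#' `score = 1 - temperature / 100`, the 0-1 nestedness reading under which
#' 1 means perfectly nested.
#'
#' @param x A [BipartiteIncidence-class] or binary matrix (at least 2x2
#'   unless degenerate).
#' @return List with `temperature` in `[0, 100]` and `score` in `[0, 1]`.
#' @rdname nestednessTemperature
#' @export
setMethod("nestednessTemperature", "BipartiteIncidence",
          function(x) nestednessTemperature(.coerceMatrix(x)))

#' @rdname nestednessTemperature
setMethod("nestednessTemperature", "matrix", function(x) {
  m <- .coerceMatrix(x)
  fill <- mean(m)
  if (fill == 0 || fill == 1) {
    return(list(temperature = 0, score = 1))
  }
  p <- .packMatrix(m)
  nc <- ncol(p)
  xpos <- (seq_len(nc) - 0.5) / nc
  u2 <- 0
  for (i in seq_len(nrow(p))) {
    r <- sum(p[i, ])
    b <- r / nc                       # row boundary (isocline crossing)
    expected <- xpos < b
    unexpected <- xor(p[i, ] > 0, expected)
    if (any(unexpected)) {
      dmax <- max(b, 1 - b)
      d <- abs(xpos[unexpected] - b) / dmax
      u2 <- u2 + sum(d^2)
    }
  }
  temp <- min(100, (100 / 0.04492) * u2 / length(p))
  list(temperature = temp, score = 1 - temp / 100)
})

#' Conserved size-and-fill (SS) null model significance
#'
#' Compares an observed matrix statistic with its distribution over null
#' matrices in which the positions of the 1s are shuffled uniformly over
#' all cells, conserving the matrix size and fill. The p-value is the
#' add-one estimate `(1 + #{null >= observed}) / (1 + nPermutations)`.
#'
#' @param x A [BipartiteIncidence-class] or binary matrix.
#' @param metric Function taking a binary matrix and returning a scalar
#'   (e.g. `nodf`, or `function(m) nestednessTemperature(m)$score`). It must
#'   tolerate null matrices with empty rows or columns.
#' @param nPermutations Number of null matrices (>= 99).
#' @param seed Integer seed (shuffles are deterministic given the seed).
#' @return List with `p_value`, `observed`, and the vector `null`.
#' @rdname nullModelSS
#' @export
setMethod("nullModelSS", "BipartiteIncidence",
          function(x, metric, nPermutations = 999, seed = 1) {
            nullModelSS(.coerceMatrix(x), metric, nPermutations, seed)
          })

#' @rdname nullModelSS
setMethod("nullModelSS", "matrix", function(x, metric, nPermutations = 999, seed = 1) {
  m <- .coerceMatrix(x)
  nPermutations <- .assertCount(nPermutations, "nPermutations", min = 99)
  k <- sum(m)
  observed <- metric(m)
  null <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      shuf <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      shuf[sample.int(length(m), k)] <- 1
      metric(shuf)
    }, numeric(1))
  })
  list(p_value = (1 + sum(null >= observed - 1e-12)) / (1 + nPermutations),
       observed = observed, null = null)
})

## ---- Barber bipartite modularity -------------------------------------

# Collapse the incidence matrix to module-level edge counts: entry (a, b) is
# the number of links between rows labelled a and columns labelled b.
.moduleEdgeCounts <- function(m, rlab, clab) {
  t_rows <- rowsum(m, rlab)
  t(rowsum(t(t_rows), clab))   # labels(rows) x labels(cols), dimnames = labels
}

# Q_B for given row/column labels: (1/m) sum_ij (A_ij - k_i d_j / m) * delta
.barberQ <- function(m, rlab, clab) {
  medges <- sum(m)
  if (medges == 0) return(0)
  E <- .moduleEdgeCounts(m, rlab, clab)
  K <- rowsum(rowSums(m), rlab)
  D <- rowsum(colSums(m), clab)
  common <- intersect(rownames(E), colnames(E))
  if (!length(common)) return(0)
  e_in <- sum(E[cbind(common, common)])
  penalty <- sum(K[common, 1] * D[common, 1])
  e_in / medges - penalty / medges^2
}

# Q of the idealized fully-within-module matrix with the same marginals.
.barberQmax <- function(m, rlab, clab) {
  medges <- sum(m)
  labs <- union(rlab, clab)
  penalty <- sum(vapply(labs, function(lb) {
    sum(rowSums(m)[rlab == lb]) * sum(colSums(m)[clab == lb])
  }, numeric(1)))
  1 - penalty / medges^2
}

# One label-propagation (BRIM-style) run from given column labels.
.brimRun <- function(B, medges, clab, maxIter) {
  nr <- nrow(B); nc <- ncol(B)
  rlab <- integer(nr)
  for (iter in seq_len(maxIter)) {
    Lc <- outer(clab, sort(unique(clab)), "==") + 0
    Sr <- B %*% Lc
    new_rlab <- sort(unique(clab))[max.col(Sr, ties.method = "first")]
    Lr <- outer(new_rlab, sort(unique(new_rlab)), "==") + 0
    Sc <- t(B) %*% Lr
    new_clab <- sort(unique(new_rlab))[max.col(Sc, ties.method = "first")]
    if (identical(new_rlab, rlab) && identical(new_clab, clab)) break
    rlab <- new_rlab; clab <- new_clab
  }
  list(rlab = rlab, clab = clab)
}

# Agglomerative refinement: greedily merge module pairs while Q improves.
# Merging modules a and b changes Q by
#   (E[a,b] + E[b,a]) / m - (K_a D_b + K_b D_a) / m^2
# where E holds module-level edge counts and K, D the module degree sums.
.agglomerate <- function(m, rlab, clab) {
  medges <- sum(m)
  repeat {
    labs <- sort(union(rlab, clab))
    if (length(labs) < 2) break
    L <- as.character(labs)
    E <- matrix(0, length(L), length(L), dimnames = list(L, L))
    Ec <- .moduleEdgeCounts(m, rlab, clab)
    E[rownames(Ec), colnames(Ec)] <- Ec
    K <- stats::setNames(rep(0, length(L)), L)
    D <- K
    Kc <- rowsum(rowSums(m), rlab); K[rownames(Kc)] <- Kc[, 1]
    Dc <- rowsum(colSums(m), clab); D[rownames(Dc)] <- Dc[, 1]
    gains <- (E + t(E)) / medges - (outer(K, D) + t(outer(K, D))) / medges^2
    diag(gains) <- -Inf
    gains[lower.tri(gains)] <- -Inf
    if (max(gains) <= 1e-12) break
    idx <- which(gains == max(gains), arr.ind = TRUE)[1, ]
    keep <- labs[idx[1]]; drop <- labs[idx[2]]
    rlab[rlab == drop] <- keep
    clab[clab == drop] <- keep
  }
  list(rlab = rlab, clab = clab)
}

#' Barber bipartite modularity with module assignments
#'
#' Maximizes Barber's bipartite modularity
#' `Q_B = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(g_i, g_j)` over joint
#' host/virus module assignments using BRIM-style label propagation with
#' agglomerative refinement, taking the best of `nRestarts` seeded random
#' restarts. The normalized score divides `Q_B` by the modularity of the
#' idealized fully-within-module matrix with the same marginals
#' (`Q_max = 1 - sum_c K_c D_c / m^2`); a block-diagonal matrix scores 1.
#' When `Q_max` is 0 (a single module explains the matrix, e.g. complete
#' bipartite), normalized Q is reported as 0.
#'
#' @param x A [BipartiteIncidence-class] or binary matrix.
#' @param nRestarts Random restarts (default 20).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param maxIter Label-propagation iteration cap per restart.
#' @return List with `q_barber`, `q_max`, `q_normalized`, `n_modules`, and
#'   `module_assignment` (data.frame: `node`, `side`, `module` with module
#'   ids contiguous from 1).
#' @rdname barberModularity
#' @export
setMethod("barberModularity", "BipartiteIncidence",
          function(x, nRestarts = 20, seed = 1, maxIter = 100) {
            barberModularity(.coerceMatrix(x), nRestarts, seed, maxIter)
          })

#' @rdname barberModularity
setMethod("barberModularity", "matrix",
          function(x, nRestarts = 20, seed = 1, maxIter = 100) {
  m <- .coerceMatrix(x)
  medges <- sum(m)
  if (medges == 0) stop("matrix has no links", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  B <- m - outer(rowSums(m), colSums(m)) / medges
  best <- NULL; best_q <- -Inf
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      clab0 <- if (r == 1) seq_len(nc) else {
        sample.int(sample.int(nc, 1), nc, replace = TRUE)
      }
      run <- .brimRun(B, medges, clab0, maxIter)
      run <- .agglomerate(m, run$rlab, run$clab)
      run <- .brimRun(B, medges, run$clab, maxIter)
      q <- .barberQ(m, run$rlab, run$clab)
      if (q > best_q + 1e-12) {
        best_q <- q; best <- run
      }
    }
  })
  # contiguous module ids, ordered by first appearance over rows then cols
  all_lab <- c(best$rlab, best$clab)
  relabel <- stats::setNames(seq_along(unique(all_lab)), unique(all_lab))
  rlab <- unname(relabel[as.character(best$rlab)])
  clab <- unname(relabel[as.character(best$clab)])
  qmax <- .barberQmax(m, rlab, clab)
  assignment <- data.frame(
    node = c(rownames(m) %||% paste0("host", seq_len(nr)),
             colnames(m) %||% paste0("virus", seq_len(nc))),
    side = c(rep("host", nr), rep("virus", nc)),
    module = c(rlab, clab), stringsAsFactors = FALSE)
  list(q_barber = best_q, q_max = qmax,
       q_normalized = if (qmax > 1e-12) max(0, min(1, best_q / qmax)) else 0,
       n_modules = length(unique(c(rlab, clab))),
       module_assignment = assignment)
})

#' Barber modularity of a given module partition
#'
#' Evaluates `Q_B`, `Q_max` and the normalized modularity for a fixed joint
#' host/virus module assignment (e.g. the planted modules of a synthetic
#' community), without any optimization.
#'
#' @param x A [BipartiteIncidence-class] or binary matrix.
#' @param rowModules,colModules Module ids per row and per column (any
#'   comparable labels).
#' @return List with `q_barber`, `q_max`, `q_normalized`.
#' @export
partitionModularity <- function(x, rowModules, colModules) {
  m <- .coerceMatrix(x)
  stopifnot(length(rowModules) == nrow(m), length(colModules) == ncol(m))
  q <- .barberQ(m, rowModules, colModules)
  qmax <- .barberQmax(m, rowModules, colModules)
  list(q_barber = q, q_max = qmax,
       q_normalized = if (qmax > 1e-12) q / qmax else 0)
}

#' Degree and specialism statistics of the infection network
#'
#' @param x A [BipartiteIncidence-class] or binary matrix (columns are
#'   viruses).
#' @param hostClass Optional named character mapping host ids to taxonomic
#'   classes, used to count generalists whose hosts span classes.
#' @return List with `specialist_percent` (share of viruses with exactly
#'   one host, as a percentage rounded to one decimal), `virus_degrees`,
#'   `generalists` (named list of host sets), `host_specialist_percent`,
#'   and `cross_class_generalists` when `hostClass` is given.
#' @rdname degreeStats
#' @export
setMethod("degreeStats", "BipartiteIncidence",
          function(x, hostClass = NULL) degreeStats(.coerceMatrix(x), hostClass))

#' @rdname degreeStats
setMethod("degreeStats", "matrix", function(x, hostClass = NULL) {
  m <- .coerceMatrix(x)
  vdeg <- colSums(m)
  hdeg <- rowSums(m)
  gen <- names(vdeg)[vdeg >= 2] %||% which(vdeg >= 2)
  generalists <- lapply(stats::setNames(gen, gen), function(v) {
    rownames(m)[m[, v] > 0]
  })
  out <- list(
    specialist_percent = round(100 * sum(vdeg == 1) / length(vdeg), 1),
    virus_degrees = vdeg,
    generalists = generalists,
    host_specialist_percent = round(100 * sum(hdeg == 1) / length(hdeg), 1))
  if (!is.null(hostClass)) {
    out$cross_class_generalists <- sum(vapply(generalists, function(hs) {
      length(unique(hostClass[hs])) > 1
    }, logical(1)))
  }
  out
})
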