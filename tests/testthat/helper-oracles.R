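# Independent oracles and small fixture builders used across the suite.

# All set partitions of n items as restricted growth strings.
setPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxl) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(prefix, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-search Barber modularity, straight from the definition:
# Q = (1/m) sum_ij (A_ij - k_i d_j / m) [g_i == g_j], maximized over all
# joint set partitions of rows and columns.
oracleBarberQ <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  medges <- sum(m)
  B <- m - outer(rowSums(m), colSums(m)) / medges
  best <- -Inf
  for (part in setPartitions(nr + nc)) {
    rl <- part[seq_len(nr)]
    cl <- part[nr + seq_len(nc)]
    q <- sum(B[outer(rl, cl, "==")]) / medges
    if (q > best) best <- q
  }
  best
}

# Random binary matrix without an all-zero guarantee violation.
randomBinaryMatrix <- function(nr, nc, p = 0.5) {
  repeat {
    m <- matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
    if (sum(m) > 0) return(m)
  }
}

# Pair table from a truth object's planted links.
truthPairs <- function(truth) {
  data.frame(virus_pop_id = trueLinks(truth)$virus_id,
             host_species_id = trueLinks(truth)$host_id,
             stringsAsFactors = FALSE)
}

# Standard noiseless fixture: 2 complete planted modules, 40 links.
noiselessFixture <- function(seed = 5) {
  truth <- simulateCommunity(nHosts = 8, nViruses = 10, nSamples = 2,
                             plantedModules = 2, generalistFraction = 0,
                             temperateFraction = 0.3, fill = 1,
                             dominantFraction = 0, seed = seed)
  evidence <- simulateEvidence(truth, readDepth = 10000,
                               hicLinksPerInfection = 50,
                               prophageNoise = 0, nDecoyAlignments = 0,
                               crisprMismatchRate = 0,
                               microscopyLogSigma = 0, seed = seed + 1)
  list(truth = truth, evidence = evidence)
}

mergedFromEvidence <- function(evidence, ...) {
  mergeLinks(rbind(filterHicLinks(evidence$hic, ...),
                   filterProphageHits(evidence$prophage_hits),
                   filterSpacerMatches(evidence$spacer_matches)))
}

pairKey <- function(df, vcol = "virus_pop_id", hcol = "host_species_id") {
  paste(df[[vcol]], df[[hcol]])
}

# Seeded evaluation that restores the session RNG state afterwards.
.withSeedForTest <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# SYNTHETIC stand-in pair table with the published survey's shape: 88
# viruses and 51 hosts forming 97 unique pairs, 8 generalist viruses
# (7 with two hosts, one with three). The link placement is arbitrary; only
# the marginal structure mirrors the survey.
syntheticSurveyStandin <- function() {
  hosts <- sprintf("h%02d", 1:51)
  virus <- sprintf("v%02d", 1:88)
  pairs <- data.frame(
    virus_pop_id = c(virus[1:51], virus[52:80]),
    host_species_id = c(hosts, hosts[1:29]),
    stringsAsFactors = FALSE)
  gen2 <- do.call(rbind, lapply(1:7, function(i) {
    data.frame(virus_pop_id = virus[80 + i],
               host_species_id = hosts[c(2 * i - 1, 2 * i)],
               stringsAsFactors = FALSE)
  }))
  gen3 <- data.frame(virus_pop_id = virus[88],
                     host_species_id = hosts[15:17],
                     stringsAsFactors = FALSE)
  rbind(pairs, gen2, gen3)
}
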