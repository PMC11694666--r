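#' Simulate a reef-like virus-bacteria community with known ground truth
#'
#' Generates a synthetic oligotrophic-seawater community emulating the study
#' design the package analyses: a log-normally distributed host community
#' with a dominant lineage that carries no detectable virus links (the
#' cyanobacteria analogue), a modular-and-nested planted bipartite infection
#' structure with a small generalist fraction, temperate/lytic lifestyle
#' labels with prophage carriage, and per-sample virus abundances in the
#' free and cell-associated size fractions.
#'
#' Defaults mirror the field study the package is built around: 51 linked
#' host species, 88 virus populations, 29 planted modules, a generalist
#' fraction of 8/88, roughly half the viruses temperate, six samples (the
#' proximity-ligation subset), and host community totals centred on a median
#' bacterial density of 9.6e5 cells/ml.
#'
#' The planted structure is built per module as a nested "staircase": hosts
#' and viruses are split into `plantedModules` contiguous blocks; within a
#' block of h hosts and v viruses the number of links is
#' `max(ceiling(fill * h * v), h + v - 1)` and virus j links hosts
#' `1..d_j` with non-increasing degrees `d_j`, so every block is perfectly
#' nested, every host and virus in the block is linked, and the whole truth
#' matrix is block-diagonal before generalists are added. The first
#' `ceiling(generalistFraction * nViruses)` viruses each gain one
#' out-of-module host (the first host of the next module).
#'
#' @param nHosts,nViruses,nSamples Community dimensions (positive integers).
#' @param plantedModules Number of planted modules (1 <= m <= min dims of
#'   the linked community).
#' @param generalistFraction Fraction of viruses given one extra
#'   out-of-module host.
#' @param temperateFraction Fraction of viruses labelled temperate; every
#'   temperate virus carries a prophage in its first linked host.
#' @param hostLogMu,hostLogSigma Log-normal parameters for per-sample host
#'   abundance (genomes/ml). The default meanlog puts the median sample
#'   total near 9.6e5 cells/ml for the default community (51 hosts
#'   including the boosted dominant lineage).
#' @param virusLogMu,virusLogSigma Log-normal parameters for free-fraction
#'   virus abundance; defaults give a virus-to-microbe ratio of about 5.
#' @param fill Within-module connectance of the planted blocks, in (0, 1].
#' @param dominantFraction Fraction of hosts (ceiling) excluded from the
#'   link structure and boosted in abundance (`dominantBoost`-fold) to mimic
#'   an abundant lineage without detectable links.
#' @param dominantBoost Abundance multiplier for the dominant linkless hosts.
#' @param cellIntensityLogMu,cellIntensityLogSigma Log-normal parameters for
#'   the per-virus infection intensity that converts linked-host abundance
#'   into cell-associated viral genome copies.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A [CommunityTruth-class] object.
#' @examples
#' truth <- simulateCommunity(nHosts = 10, nViruses = 10, nSamples = 2,
#'                            plantedModules = 2, generalistFraction = 0,
#'                            temperateFraction = 0.3, seed = 1)
#' truth
#' @export
simulateCommunity <- function(nHosts = 51, nViruses = 88, nSamples = 6,
                              plantedModules = 29,
                              generalistFraction = 8 / 88,
                              temperateFraction = 0.5,
                              hostLogMu = log(7.3e3), hostLogSigma = 1,
                              virusLogMu = log(3.3e4), virusLogSigma = 1.5,
                              fill = 0.5,
                              dominantFraction = 0.06, dominantBoost = 6,
                              cellIntensityLogMu = log(0.1),
                              cellIntensityLogSigma = 0.5,
                              seed = 1) {
  nHosts <- .assertCount(nHosts, "nHosts")
  nViruses <- .assertCount(nViruses, "nViruses")
  nSamples <- .assertCount(nSamples, "nSamples")
  plantedModules <- .assertCount(plantedModules, "plantedModules")
  generalistFraction <- .assertFraction(generalistFraction, "generalistFraction")
  temperateFraction <- .assertFraction(temperateFraction, "temperateFraction")
  dominantFraction <- .assertFraction(dominantFraction, "dominantFraction")
  if (fill <= 0 || fill > 1) stop("fill must be in (0, 1]", call. = FALSE)

  host_ids <- sprintf("bMAG_%03d", seq_len(nHosts))
  virus_ids <- sprintf("vMAG_%03d", seq_len(nViruses))
  sample_ids <- sprintf("S%02d", seq_len(nSamples))

  n_dominant <- if (dominantFraction > 0) ceiling(dominantFraction * nHosts) else 0L
  linked_hosts <- host_ids[seq_len(nHosts - n_dominant)]
  dominant_hosts <- setdiff(host_ids, linked_hosts)
  if (length(linked_hosts) < plantedModules || nViruses < plantedModules) {
    stop("plantedModules exceeds the number of linkable hosts or viruses",
         call. = FALSE)
  }

  # contiguous, near-even split into modules
  host_mod <- sort(rep_len(seq_len(plantedModules), length(linked_hosts)))
  virus_mod <- sort(rep_len(seq_len(plantedModules), nViruses))

  links <- do.call(rbind, lapply(seq_len(plantedModules), function(m) {
    hs <- linked_hosts[host_mod == m]
    vs <- virus_ids[virus_mod == m]
    h <- length(hs); v <- length(vs)
    k <- min(h * v, max(ceiling(fill * h * v), h + v - 1L))
    # nested prefix degrees: first virus spans all hosts, remaining links
    # stacked onto the earliest viruses so degrees are non-increasing
    d <- rep(1L, v)
    d[1] <- h
    extra <- k - (h + v - 1L)
    j <- 2L
    while (extra > 0 && j <= v) {
      add <- min(extra, h - 1L)
      d[j] <- d[j] + add
      extra <- extra - add
      j <- j + 1L
    }
    data.frame(virus_id = rep(vs, d),
               host_id = unlist(lapply(d, function(k_) hs[seq_len(k_)])),
               stringsAsFactors = FALSE)
  }))

  n_generalists <- ceiling(generalistFraction * nViruses)
  if (n_generalists > 0) {
    if (plantedModules < 2) {
      stop("generalists need at least two modules for an out-of-module host",
           call. = FALSE)
    }
    gen_viruses <- virus_ids[seq_len(n_generalists)]
    extra <- data.frame(
      virus_id = gen_viruses,
      host_id = vapply(gen_viruses, function(v) {
        m <- virus_mod[match(v, virus_ids)]
        target <- (m %% plantedModules) + 1L
        linked_hosts[which(host_mod == target)[1]]
      }, character(1)),
      stringsAsFactors = FALSE
    )
    links <- rbind(links, extra)
  }
  links <- unique(links)
  if (nrow(links) > length(linked_hosts) * nViruses) {
    stop("generalistFraction too large: links exceed matrix size", call. = FALSE)
  }
  rownames(links) <- NULL

  .withSeed(seed, {
    host_ab <- matrix(stats::rlnorm(nHosts * nSamples, hostLogMu, hostLogSigma),
                      nrow = nHosts, dimnames = list(host_ids, sample_ids))
    if (length(dominant_hosts)) {
      host_ab[dominant_hosts, ] <- host_ab[dominant_hosts, , drop = FALSE] * dominantBoost
    }
    virus_free <- matrix(stats::rlnorm(nViruses * nSamples, virusLogMu, virusLogSigma),
                         nrow = nViruses, dimnames = list(virus_ids, sample_ids))

    # cell-associated copies track the abundance of the infected hosts
    intensity <- stats::rlnorm(nViruses, cellIntensityLogMu, cellIntensityLogSigma)
    names(intensity) <- virus_ids
    virus_cell <- matrix(0, nViruses, nSamples, dimnames = list(virus_ids, sample_ids))
    for (i in seq_len(nrow(links))) {
      v <- links$virus_id[i]; h <- links$host_id[i]
      virus_cell[v, ] <- virus_cell[v, ] + host_ab[h, ] * intensity[v]
    }

    n_temperate <- ceiling(temperateFraction * nViruses)
    lifestyle <- stats::setNames(rep("lytic", nViruses), virus_ids)
    if (n_temperate > 0) {
      lifestyle[sample(virus_ids, n_temperate)] <- "temperate"
    }
    temperate <- names(lifestyle)[lifestyle == "temperate"]
    carriers <- links[links$virus_id %in% temperate &
                        !duplicated(links$virus_id), , drop = FALSE]
    rownames(carriers) <- NULL

    lengths <- c(
      stats::setNames(round(stats::runif(nHosts, 2e6, 6e6)), host_ids),
      stats::setNames(round(stats::runif(nViruses, 1e4, 1e5)), virus_ids)
    )

    methods::new("CommunityTruth",
      hostIds = host_ids, virusIds = virus_ids,
      hostAbundance = host_ab,
      virusAbundanceFree = virus_free, virusAbundanceCell = virus_cell,
      trueLinks = links, lifestyle = lifestyle,
      prophageCarriers = carriers, genomeLengths = lengths,
      hostModule = stats::setNames(
        c(host_mod, rep(NA_integer_, length(dominant_hosts)))[match(host_ids, c(linked_hosts, dominant_hosts))],
        host_ids),
      virusModule = stats::setNames(as.integer(virus_mod), virus_ids),
      seed = as.integer(seed))
  })
}

#' Simulate evidence tables from a known community
#'
#' Derives every table the inference pipeline consumes from a
#' [CommunityTruth-class]: proximity-ligation (Hi-C) contact counts,
#' prophage BLAST-style alignments, CRISPR spacer matches, per-fraction
#' read-count tables, and epifluorescence microscopy totals.
#'
#' Model: read counts are multinomial per sample and fraction with weights
#' abundance x genome length (reads scale with DNA mass); Hi-C contact
#' counts are Poisson with mean proportional to host abundance x
#' cell-associated virus abundance, scaled so the mean contact count over
#' true links equals `hicLinksPerInfection`, plus `hicFalsePositiveFloor`
#' spurious single-contact rows per sample; prophage alignments are emitted
#' for every prophage carrier at identity `100 - |N(0, prophageNoise)|` and
#' 100% query coverage, plus `nDecoyAlignments` below-threshold decoys;
#' spacer matches are emitted per true link with mismatch counts
#' binomial(spacer length, `crisprMismatchRate`); microscopy totals are the
#' per-sample column sums of genomes/ml times log-normal noise.
#'
#' @param truth A [CommunityTruth-class].
#' @param readDepth Reads per sample per fraction (>= 1000).
#' @param hicLinksPerInfection Mean Hi-C contacts per true link; 0 leaves
#'   only the false-positive floor.
#' @param hicFalsePositiveFloor Spurious Hi-C rows per sample (default 0; it
#'   exists to exercise filtering).
#' @param prophageNoise SD of the identity jitter for prophage alignments.
#' @param nDecoyAlignments Below-threshold decoy alignments to add.
#' @param crisprMismatchRate Per-nucleotide mismatch probability for spacer
#'   matches.
#' @param microscopyLogSigma sdlog of the multiplicative log-normal noise on
#'   microscopy totals (0.2 approximates epifluorescence counting error).
#' @param seed Integer seed.
#' @return A list with elements `hic`, `prophage_hits`, `spacer_matches`,
#'   `counts_cell`, `counts_free`, `microscopy`, and `params`.
#' @export
simulateEvidence <- function(truth, readDepth = 1e5,
                             hicLinksPerInfection = 50,
                             hicFalsePositiveFloor = 0,
                             prophageNoise = 1.5,
                             nDecoyAlignments = NULL,
                             crisprMismatchRate = 0.02,
                             microscopyLogSigma = 0.2,
                             seed = 1) {
  stopifnot(methods::is(truth, "CommunityTruth"))
  methods::validObject(truth)
  readDepth <- .assertCount(readDepth, "readDepth", min = 1000)
  if (hicLinksPerInfection < 0 || hicFalsePositiveFloor < 0 ||
      prophageNoise < 0 || crisprMismatchRate < 0 || crisprMismatchRate > 1 ||
      microscopyLogSigma < 0) {
    stop("rates and noise parameters must be non-negative", call. = FALSE)
  }
  links <- trueLinks(truth)
  carriers <- prophageCarriers(truth)
  if (is.null(nDecoyAlignments)) nDecoyAlignments <- nrow(carriers)
  host_ab <- hostAbundance(truth)
  v_free <- virusAbundance(truth, "free")
  v_cell <- virusAbundance(truth, "cell")
  lens <- genomeLengths(truth)
  samples <- colnames(host_ab)

  .withSeed(seed, {
    ## --- Hi-C contacts -------------------------------------------------
    hic <- NULL
    if (nrow(links) && hicLinksPerInfection > 0) {
      grid <- merge(links, data.frame(sample_id = samples), by = NULL)
      w <- host_ab[cbind(grid$host_id, grid$sample_id)] *
        v_cell[cbind(grid$virus_id, grid$sample_id)]
      lambda <- hicLinksPerInfection * w / mean(w)
      grid$contact_count <- stats::rpois(nrow(grid), lambda)
      hic <- grid[grid$contact_count > 0, , drop = FALSE]
    }
    if (hicFalsePositiveFloor > 0) {
      link_keys <- paste(links$virus_id, links$host_id)
      fp <- do.call(rbind, lapply(samples, function(s) {
        got <- 0L; out <- NULL
        while (got < hicFalsePositiveFloor) {
          v <- sample(virusIds(truth), 1); h <- sample(hostIds(truth), 1)
          if (!(paste(v, h) %in% link_keys)) {
            out <- rbind(out, data.frame(virus_id = v, host_id = h,
                                         sample_id = s, contact_count = 1L,
                                         stringsAsFactors = FALSE))
            got <- got + 1L
          }
        }
        out
      }))
      hic <- rbind(hic, fp)
    }
    if (is.null(hic)) {
      hic <- data.frame(virus_id = character(), host_id = character(),
                        sample_id = character(), contact_count = integer(),
                        stringsAsFactors = FALSE)
    }
    # share of the virus's within-sample contacts: 1 for specialists
    if (nrow(hic)) {
      tot <- stats::ave(hic$contact_count, hic$virus_id, hic$sample_id, FUN = sum)
      hic$normalized_score <- hic$contact_count / tot
    } else {
      hic$normalized_score <- numeric()
    }
    rownames(hic) <- NULL

    ## --- prophage alignments -------------------------------------------
    mk_hit <- function(query, subject, identity, cov_frac) {
      qlen <- unname(lens[query])
      alen <- max(1L, round(cov_frac * qlen))
      data.frame(query_id = query, subject_id = subject,
                 percent_identity = identity, alignment_length = alen,
                 mismatches = round((100 - identity) / 100 * alen),
                 gap_opens = 0L, query_start = 1L, query_end = alen,
                 subject_start = 1L, subject_end = alen,
                 e_value = 0, bitscore = round(2 * alen * identity / 100),
                 query_length = qlen, stringsAsFactors = FALSE)
    }
    prophage <- NULL
    if (nrow(carriers)) {
      ident <- pmax(0, 100 - abs(stats::rnorm(nrow(carriers), 0, prophageNoise)))
      prophage <- do.call(rbind, lapply(seq_len(nrow(carriers)), function(i) {
        mk_hit(carriers$virus_id[i], carriers$host_id[i], ident[i], 1)
      }))
    }
    if (nDecoyAlignments > 0) {
      decoys <- do.call(rbind, lapply(seq_len(nDecoyAlignments), function(i) {
        v <- sample(virusIds(truth), 1); h <- sample(hostIds(truth), 1)
        if (i %% 2 == 1) {
          mk_hit(v, h, stats::runif(1, 70, 94.5), 1)        # fails identity
        } else {
          mk_hit(v, h, 100, stats::runif(1, 0.3, 0.95))     # fails coverage
        }
      }))
      prophage <- rbind(prophage, decoys)
    }
    if (is.null(prophage)) {
      prophage <- data.frame(query_id = character(), subject_id = character(),
                             percent_identity = numeric(),
                             alignment_length = integer(), mismatches = integer(),
                             gap_opens = integer(), query_start = integer(),
                             query_end = integer(), subject_start = integer(),
                             subject_end = integer(), e_value = numeric(),
                             bitscore = numeric(), query_length = numeric(),
                             stringsAsFactors = FALSE)
    }
    rownames(prophage) <- NULL

    ## --- CRISPR spacer matches -----------------------------------------
    if (nrow(links)) {
      slen <- sample(25:45, nrow(links), replace = TRUE)
      mm <- stats::rbinom(nrow(links), slen, crisprMismatchRate)
      spacers <- data.frame(
        spacer_id = sprintf("spacer_%04d", seq_len(nrow(links))),
        spacer_length = slen,
        virus_id = links$virus_id, host_id = links$host_id,
        mismatches_plus_gaps = mm, coverage_percent = 100,
        matched_length = slen, stringsAsFactors = FALSE)
    } else {
      spacers <- data.frame(spacer_id = character(), spacer_length = integer(),
                            virus_id = character(), host_id = character(),
                            mismatches_plus_gaps = integer(),
                            coverage_percent = numeric(),
                            matched_length = integer(), stringsAsFactors = FALSE)
    }

    ## --- read counts (multinomial, weights = abundance x length) --------
    sample_counts <- function(ab, fraction, kind) {
      entities <- rownames(ab)
      do.call(rbind, lapply(samples, function(s) {
        wt <- ab[, s] * lens[entities]
        data.frame(entity_id = entities, sample_id = s, fraction = fraction,
                   kind = kind,
                   reads = as.integer(stats::rmultinom(1, readDepth, wt)),
                   genome_length = unname(lens[entities]),
                   stringsAsFactors = FALSE)
      }))
    }
    # cell fraction: hosts plus cell-associated viral genomes, one library
    cell_ab <- rbind(host_ab, v_cell)
    wt_split <- lapply(samples, function(s) cell_ab[, s] * lens[rownames(cell_ab)])
    counts_cell <- do.call(rbind, lapply(seq_along(samples), function(si) {
      s <- samples[si]
      reads <- as.integer(stats::rmultinom(1, readDepth, wt_split[[si]]))
      data.frame(entity_id = rownames(cell_ab), sample_id = s,
                 fraction = "cell_associated",
                 kind = c(rep("host", nrow(host_ab)), rep("virus", nrow(v_cell))),
                 reads = reads,
                 genome_length = unname(lens[rownames(cell_ab)]),
                 stringsAsFactors = FALSE)
    }))
    counts_free <- sample_counts(v_free, "free", "virus")
    rownames(counts_cell) <- rownames(counts_free) <- NULL

    ## --- microscopy totals ----------------------------------------------
    noise <- function(n) stats::rlnorm(n, 0, microscopyLogSigma)
    vlp <- colSums(v_free) * noise(length(samples))
    cells <- colSums(host_ab) * noise(length(samples))
    microscopy <- data.frame(sample_id = samples,
                             vlp_per_ml = unname(vlp),
                             cells_per_ml = unname(cells),
                             vmr = unname(vlp / cells),
                             stringsAsFactors = FALSE)

    list(hic = hic, prophage_hits = prophage, spacer_matches = spacers,
         counts_cell = counts_cell, counts_free = counts_free,
         microscopy = microscopy,
         params = list(readDepth = readDepth,
                       hicLinksPerInfection = hicLinksPerInfection,
                       hicFalsePositiveFloor = hicFalsePositiveFloor,
                       prophageNoise = prophageNoise,
                       nDecoyAlignments = nDecoyAlignments,
                       crisprMismatchRate = crisprMismatchRate,
                       microscopyLogSigma = microscopyLogSigma,
                       seed = as.integer(seed)))
  })
}

#' Write simulated evidence tables to disk
#'
#' Writes the tables produced by [simulateEvidence()] in the formats the
#' pipeline readers consume, plus a YAML manifest recording the generator
#' parameters and the planted truth.
#'
#' @param evidence List from [simulateEvidence()].
#' @param truth The [CommunityTruth-class] the evidence derives from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEvidence <- function(evidence, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(evidence$hic, file.path(dir, "hic_links.tsv"))
  writeTsv(evidence$prophage_hits, file.path(dir, "prophage_hits.tsv"))
  writeTsv(evidence$spacer_matches, file.path(dir, "spacer_matches.tsv"))
  writeTsv(evidence$counts_cell, file.path(dir, "counts_cell.tsv"))
  writeTsv(evidence$counts_free, file.path(dir, "counts_free.tsv"))
  utils::write.csv(evidence$microscopy, file.path(dir, "microscopy.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    generator = evidence$params,
    community = list(
      seed = truth@seed,
      n_hosts = length(hostIds(truth)),
      n_viruses = length(virusIds(truth)),
      n_samples = ncol(hostAbundance(truth)),
      n_true_links = nrow(trueLinks(truth)),
      n_prophage_carriers = nrow(prophageCarriers(truth)),
      n_temperate = sum(lifestyles(truth) == "temperate")
    ),
    true_links = paste(trueLinks(truth)$virus_id, trueLinks(truth)$host_id,
                       sep = "\t")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
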