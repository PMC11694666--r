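#' Default pipeline configuration
#'
#' Returns the full run configuration with every threshold at its
#' documented default: prophage filter 95% identity / 99% query coverage,
#' CRISPR filter 2 mismatches+gaps / 100% coverage / 20 nt, Hi-C filter 2
#' contacts / score 0, viral population dereplication 95% ANI / 80% shared
#' genes, host species dereplication 95% ANI, 999 null permutations, 20
#' modularity restarts, log10 VHR quartile scale, seed 1.
#'
#' @param inputDir Optional directory of input tables written by
#'   [writeEvidence()]; fills the standard input paths.
#' @param outputDir Directory for pipeline outputs.
#' @param seed Integer seed for all stochastic stages.
#' @return A nested configuration list.
#' @export
defaultConfig <- function(inputDir = NULL, outputDir = tempfile("reefnet_out"),
                          seed = 1) {
  inputs <- list(hic = NULL, prophage_hits = NULL, spacer_matches = NULL,
                 counts_cell = NULL, counts_free = NULL, microscopy = NULL,
                 virus_pairwise = NULL, host_pairwise = NULL,
                 genome_lengths = NULL, integrase = NULL,
                 bitscores = NULL, module_defs = NULL,
                 host_annotations = NULL, virus_annotations = NULL,
                 virus_contamination = NULL)
  if (!is.null(inputDir)) {
    std <- c(hic = "hic_links.tsv", prophage_hits = "prophage_hits.tsv",
             spacer_matches = "spacer_matches.tsv",
             counts_cell = "counts_cell.tsv", counts_free = "counts_free.tsv",
             microscopy = "microscopy.csv")
    for (nm in names(std)) {
      p <- file.path(inputDir, std[[nm]])
      if (file.exists(p)) inputs[[nm]] <- p
    }
  }
  list(
    inputs = inputs,
    thresholds = list(
      prophage_min_identity = 95, prophage_min_coverage = 99,
      crispr_max_mm_gaps = 2, crispr_required_coverage = 100,
      crispr_min_length = 20,
      hic_min_contacts = 2, hic_min_score = 0,
      virus_ani = 95, virus_shared = 80, host_ani = 95,
      permutations = 999, restarts = 20,
      quartile_scale = "log10"),
    seed = as.integer(seed),
    output_dir = outputDir)
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented range and verifies that
#' the configured input files exist, before any stage runs.
#'
#' @param config Configuration list (see [defaultConfig()]).
#' @return `config`, invisibly; errors on the first violation.
#' @export
validateConfig <- function(config) {
  th <- config$thresholds
  chk <- function(cond, msg) if (!cond) stop("config: ", msg, call. = FALSE)
  chk(!is.null(config$seed) && is.finite(config$seed),
      "seed is required for reproducibility")
  chk(th$prophage_min_identity > 0 && th$prophage_min_identity <= 100,
      "prophage_min_identity must be in (0, 100]")
  chk(th$prophage_min_coverage > 0 && th$prophage_min_coverage <= 100,
      "prophage_min_coverage must be in (0, 100]")
  chk(th$crispr_max_mm_gaps >= 0, "crispr_max_mm_gaps must be >= 0")
  chk(th$crispr_required_coverage > 0 && th$crispr_required_coverage <= 100,
      "crispr_required_coverage must be in (0, 100]")
  chk(th$crispr_min_length >= 1, "crispr_min_length must be >= 1")
  chk(th$hic_min_contacts >= 0 && th$hic_min_score >= 0,
      "Hi-C thresholds must be >= 0")
  chk(th$virus_ani > 0 && th$virus_ani <= 100, "virus_ani must be in (0, 100]")
  chk(th$host_ani > 0 && th$host_ani <= 100, "host_ani must be in (0, 100]")
  chk(is.na(th$virus_shared) || (th$virus_shared > 0 && th$virus_shared <= 100),
      "virus_shared must be in (0, 100] or NA")
  chk(th$permutations >= 99, "permutations must be >= 99")
  chk(th$restarts >= 1, "restarts must be >= 1")
  chk(th$quartile_scale %in% c("log10", "linear"),
      "quartile_scale must be log10 or linear")
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p)) chk(file.exists(p), paste0("input not found: ", nm, " (", p, ")"))
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing fields are filled with defaults.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  config <- defaultConfig()
  for (nm in names(user$inputs %||% list())) config$inputs[[nm]] <- user$inputs[[nm]]
  for (nm in names(user$thresholds %||% list())) {
    config$thresholds[[nm]] <- user$thresholds[[nm]]
  }
  if (!is.null(user$seed)) config$seed <- as.integer(user$seed)
  if (!is.null(user$output_dir)) config$output_dir <- user$output_dir
  validateConfig(config)
}

.stage <- function(name, code) {
  t0 <- Sys.time()
  message(sprintf("[reefnet] stage %-10s ...", name))
  out <- tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[reefnet] stage %-10s done (%.1fs)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full inference pipeline
#'
#' Executes link inference, abundance estimation, network analysis, VHR
#' classification, and (when bitscores are configured) the proteomic tree,
#' writing all module outputs plus a YAML run manifest to the configured
#' output directory. Identical configuration, inputs and seed produce
#' identical outputs.
#'
#' @param config Configuration list (see [defaultConfig()] /
#'   [readRunConfig()]).
#' @return The result bundle (named list of all stage outputs), invisibly.
#' @export
runPipeline <- function(config) {
  validateConfig(config)
  th <- config$thresholds
  inp <- config$inputs
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config)

  ## ---- link inference -------------------------------------------------
  bundle$links <- .stage("links", {
    evidence <- list()
    if (!is.null(inp$hic)) {
      evidence$hic <- filterHicLinks(readHicLinks(inp$hic),
                                     th$hic_min_contacts, th$hic_min_score)
    }
    if (!is.null(inp$prophage_hits)) {
      evidence$prophage <- filterProphageHits(readBlastHits(inp$prophage_hits),
                                              th$prophage_min_identity,
                                              th$prophage_min_coverage)
    }
    if (!is.null(inp$spacer_matches)) {
      evidence$crispr <- filterSpacerMatches(readSpacerMatches(inp$spacer_matches),
                                             th$crispr_max_mm_gaps,
                                             th$crispr_required_coverage,
                                             th$crispr_min_length)
    }
    if (!length(evidence)) stop("no link evidence inputs configured")
    ev <- do.call(rbind, evidence)
    vmap <- hmap <- NULL
    if (!is.null(inp$virus_pairwise) && !is.null(inp$genome_lengths)) {
      lens <- readGenomeLengths(inp$genome_lengths)
      vids <- unique(ev$virus_pop_id)
      vmap <- dereplicateGenomes(readPairwiseSimilarity(inp$virus_pairwise),
                                 th$virus_ani, th$virus_shared,
                                 lens[intersect(names(lens), vids)])
    }
    if (!is.null(inp$host_pairwise) && !is.null(inp$genome_lengths)) {
      lens <- readGenomeLengths(inp$genome_lengths)
      hids <- unique(ev$host_species_id)
      hmap <- dereplicateGenomes(readPairwiseSimilarity(inp$host_pairwise),
                                 th$host_ani, NA,
                                 lens[intersect(names(lens), hids)])
    }
    pairs <- mergeLinks(ev, vmap, hmap)
    writeTsv(pairs, file.path(config$output_dir, "links.tsv"))
    pairs
  })

  ## ---- abundance ------------------------------------------------------
  bundle$abundance <- .stage("abundance", {
    counts_cell <- readCountsTable(inp$counts_cell)
    counts_free <- readCountsTable(inp$counts_free)
    micro <- readMicroscopy(inp$microscopy)
    rel_cell <- relativeAbundance(counts_cell)
    rel_free <- relativeAbundance(counts_free)
    gpm_cell <- scaleByMicroscopy(rel_cell, micro)
    gpm_free <- scaleByMicroscopy(rel_free, micro)
    virus_gpm <- rbind(gpm_cell[gpm_cell$kind == "virus", , drop = FALSE],
                       gpm_free[gpm_free$kind == "virus", , drop = FALSE])
    host_gpm <- gpm_cell[gpm_cell$kind == "host", , drop = FALSE]
    vhr <- computeVHR(bundle$links, virus_gpm, host_gpm)
    ranks <- rankStatistics(rbind(virus_gpm[virus_gpm$fraction == "free", ],
                                  host_gpm),
                            pairs = bundle$links)
    writeTsv(rbind(gpm_cell, gpm_free),
             file.path(config$output_dir, "abundance.tsv"))
    writeTsv(vhr, file.path(config$output_dir, "vhr.tsv"))
    list(microscopy = micro, virus_gpm = virus_gpm, host_gpm = host_gpm,
         vhr = vhr, ranks = ranks)
  })

  ## ---- network --------------------------------------------------------
  bundle$network <- .stage("network", {
    bm <- buildIncidenceMatrix(bundle$links)
    nodf_val <- nodf(bm)
    temp <- nestednessTemperature(bm)
    p_nodf <- nullModelSS(bm, nodf, th$permutations, config$seed)
    p_temp <- nullModelSS(bm, function(m) nestednessTemperature(m)$score,
                          th$permutations, config$seed + 1L)
    mod <- barberModularity(bm, nRestarts = th$restarts, seed = config$seed)
    deg <- degreeStats(bm)
    metrics <- list(
      n_hosts = nrow(incidence(bm)), n_viruses = ncol(incidence(bm)),
      n_links = sum(incidence(bm)), fill = mean(incidence(bm)),
      nodf = nodf_val, nodf_p_value = p_nodf$p_value,
      temperature = temp$temperature, nestedness_score = temp$score,
      nestedness_p_value = p_temp$p_value,
      q_barber = mod$q_barber, q_normalized = mod$q_normalized,
      n_modules = mod$n_modules,
      specialist_percent = deg$specialist_percent,
      n_generalists = length(deg$generalists),
      permutations = th$permutations, restarts = th$restarts,
      seed = config$seed)
    jsonlite::write_json(metrics,
                         file.path(config$output_dir, "network_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeTsv(mod$module_assignment, file.path(config$output_dir, "modules.tsv"))
    edge <- bundle$links[, c("virus_pop_id", "host_species_id")]
    writeTsv(edge, file.path(config$output_dir, "edge_list.tsv"))
    utils::write.table(incidence(bm), file.path(config$output_dir, "matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    list(matrix = bm, metrics = metrics, modularity = mod, degrees = deg)
  })

  ## ---- VHR categories -------------------------------------------------
  bundle$vhr <- .stage("vhr", {
    medians <- pairMedianVHR(bundle$abundance$vhr)
    thr <- vhrQuartiles(medians, scale = th$quartile_scale)
    classified <- classifyVhrPairs(medians, thr)
    writeTsv(classified, file.path(config$output_dir, "vhr_categories.tsv"))
    out <- list(thresholds = thr, categories = classified)

    # lifestyle comparison: needs integrase annotations + prophage evidence
    if (!is.null(inp$integrase)) {
      integ <- readTsv(inp$integrase)
      .requireCols(integ, c("virus_id", "has_integrase"), "integrase table")
      prophage_pairs <- bundle$links[grepl("prophage", bundle$links$evidence_types), ]
      lf <- classifyLifestyle(
        integ$virus_id, as.logical(integ$has_integrase),
        prophage_pairs)
      coarse <- coarseLifestyle(lf)
      cc <- classified
      cc$lifestyle <- unname(coarse[cc$virus_pop_id])
      usable <- !is.na(cc$lifestyle) & is.finite(cc$median_vhr_cell) &
        cc$median_vhr_cell > 0
      if (length(unique(cc$lifestyle[usable])) >= 2 &&
          all(table(cc$lifestyle[usable]) >= 2)) {
        out$lifestyle_test <- compareGroups(log10(cc$median_vhr_cell[usable]),
                                            cc$lifestyle[usable])
      }
      out$lifestyle <- lf
    }

    # metabolic module enrichment by category
    if (!is.null(inp$module_defs) && !is.null(inp$host_annotations)) {
      defs <- readModuleDefinitions(inp$module_defs)
      pres_b <- modulePresence(readTsv(inp$host_annotations), defs, "bMAG")
      host_cat <- data.frame(host_species_id = classified$host_species_id,
                             category = classified$category,
                             stringsAsFactors = FALSE)
      out$enrichment <- categoryEnrichment(pres_b, host_cat)
      enr <- data.frame(module_id = rownames(out$enrichment),
                        out$enrichment, check.names = FALSE)
      writeTsv(enr, file.path(config$output_dir, "enrichment.tsv"))
      if (!is.null(inp$virus_annotations)) {
        contam <- NULL
        if (!is.null(inp$virus_contamination)) {
          ct <- readTsv(inp$virus_contamination)
          contam <- stats::setNames(ct$contamination, ct$entity_id)
        }
        pres_v <- modulePresence(readTsv(inp$virus_annotations), defs, "vMAG",
                                 contamination = contam)
        out$shared_modules <- sharedVirusHostModules(pres_v, pres_b,
                                                     bundle$links)
      }
    }
    out
  })

  ## ---- proteomic tree -------------------------------------------------
  if (!is.null(inp$bitscores)) {
    bundle$tree <- .stage("tree", {
      d <- buildDistanceMatrix(readBitscores(inp$bitscores))
      tree <- proteomicTree(d)
      writeNewick(tree, file.path(config$output_dir, "tree.nwk"))
      utils::write.table(d, file.path(config$output_dir, "dice_distances.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      list(distances = d, tree = tree)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefnet")),
    seed = config$seed,
    thresholds = config$thresholds,
    inputs = Filter(Negate(is.null), config$inputs),
    outputs = list.files(config$output_dir))
  yaml::write_yaml(manifest, file.path(config$output_dir, "run_manifest.yaml"))
  invisible(bundle)
}

#' One-command synthetic demonstration run
#'
#' Simulates a study-scale community ([simulateCommunity()] defaults),
#' derives all evidence tables, writes them to disk, synthesizes small
#' integrase and metabolic-module annotation tables consistent with the
#' planted truth, and runs the full pipeline on the files.
#'
#' @param dir Working directory for inputs and outputs.
#' @param seed Integer seed controlling community, evidence, annotations
#'   and all pipeline stages.
#' @param ... Arguments forwarded to [simulateCommunity()].
#' @param evidenceArgs List of arguments forwarded to [simulateEvidence()].
#' @return List with `truth`, `evidence`, and the pipeline result `bundle`.
#' @export
runDemo <- function(dir = tempfile("reefnet_demo"), seed = 1, ...,
                    evidenceArgs = list()) {
  truth <- simulateCommunity(..., seed = seed)
  evidence <- do.call(simulateEvidence,
                      c(list(truth = truth, seed = seed + 1L), evidenceArgs))
  input_dir <- file.path(dir, "inputs")
  writeEvidence(evidence, truth, input_dir)
  .withSeed(seed + 2L, {
    # integrase flags consistent with planted lifestyles
    lf <- lifestyles(truth)
    carriers <- unique(prophageCarriers(truth)$virus_id)
    integ <- data.frame(
      virus_id = names(lf),
      has_integrase = lf == "temperate" & !(names(lf) %in% carriers) |
        (names(lf) %in% carriers & stats::runif(length(lf)) < 0.5),
      stringsAsFactors = FALSE)
    writeTsv(integ, file.path(input_dir, "integrase.tsv"))

    # small KEGG-like module universe with host/virus step annotations
    defs <- do.call(rbind, lapply(1:8, function(m) {
      data.frame(module_id = sprintf("M%03d", m),
                 step_id = sprintf("K%05d", (m - 1) * 6 + 1:6),
                 stringsAsFactors = FALSE)
    }))
    writeTsv(defs, file.path(input_dir, "module_defs.tsv"))
    hosts <- hostIds(truth)
    host_ann <- do.call(rbind, lapply(hosts, function(h) {
      steps <- sample(defs$step_id, sample(3:12, 1))
      data.frame(entity_id = h, step_id = steps, stringsAsFactors = FALSE)
    }))
    writeTsv(host_ann, file.path(input_dir, "host_annotations.tsv"))
    links <- trueLinks(truth)
    virus_ann <- do.call(rbind, lapply(unique(links$virus_id), function(v) {
      h <- links$host_id[links$virus_id == v][1]
      pool <- host_ann$step_id[host_ann$entity_id == h]
      if (stats::runif(1) < 0.3 && length(pool)) {
        data.frame(entity_id = v, step_id = sample(pool, 1),
                   stringsAsFactors = FALSE)
      }
    }))
    if (!is.null(virus_ann)) {
      writeTsv(virus_ann, file.path(input_dir, "virus_annotations.tsv"))
    }
    writeTsv(data.frame(entity_id = virusIds(truth), contamination = 0),
             file.path(input_dir, "virus_contamination.tsv"))

    # proteome bitscore sums: viruses in the same planted module share genes
    vids <- virusIds(truth)
    vmod <- truth@virusModule
    lens <- genomeLengths(truth)[vids]
    self <- data.frame(query_genome = vids, subject_genome = vids,
                       summed_bitscore = round(2 * lens / 100))
    cross <- NULL
    for (i in seq_along(vids)) {
      for (j in seq_along(vids)) {
        if (i == j || vmod[vids[i]] != vmod[vids[j]]) next
        ab <- round(stats::runif(1, 0.2, 0.6) *
                      min(self$summed_bitscore[c(i, j)]))
        cross <- rbind(cross, data.frame(query_genome = vids[i],
                                         subject_genome = vids[j],
                                         summed_bitscore = ab))
      }
    }
    writeTsv(rbind(self, cross), file.path(input_dir, "bitscores.tsv"))
  })

  config <- defaultConfig(inputDir = input_dir,
                          outputDir = file.path(dir, "results"),
                          seed = seed)
  config$inputs$integrase <- file.path(input_dir, "integrase.tsv")
  config$inputs$module_defs <- file.path(input_dir, "module_defs.tsv")
  config$inputs$host_annotations <- file.path(input_dir, "host_annotations.tsv")
  va <- file.path(input_dir, "virus_annotations.tsv")
  if (file.exists(va)) config$inputs$virus_annotations <- va
  config$inputs$virus_contamination <- file.path(input_dir,
                                                 "virus_contamination.tsv")
  config$inputs$bitscores <- file.path(input_dir, "bitscores.tsv")
  bundle <- runPipeline(config)
  list(truth = truth, evidence = evidence, bundle = bundle)
}
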