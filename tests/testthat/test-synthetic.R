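test_that("community generation is deterministic and respects its invariants", {
  args <- list(nHosts = 12, nViruses = 15, nSamples = 3, plantedModules = 3,
               generalistFraction = 0.1, temperateFraction = 0.4, seed = 11)
  t1 <- do.call(simulateCommunity, args)
  t2 <- do.call(simulateCommunity, args)
  expect_identical(t1, t2)
  expect_true(validObject(t1))
  expect_true(all(hostAbundance(t1) > 0))
  expect_true(all(genomeLengths(t1) >= 1000))
  # prophage carriers are planted links of temperate viruses
  pc <- prophageCarriers(t1)
  expect_true(all(pairKey(pc, "virus_id", "host_id") %in%
                    pairKey(trueLinks(t1), "virus_id", "host_id")))
  expect_true(all(lifestyles(t1)[pc$virus_id] == "temperate"))
})

test_that("planted structure is block-diagonal with perfectly modular truth", {
  truth <- simulateCommunity(nHosts = 10, nViruses = 10, nSamples = 1,
                             plantedModules = 2, generalistFraction = 0,
                             temperateFraction = 0, seed = 1)
  links <- trueLinks(truth)
  vmod <- truth@virusModule
  hmod <- truth@hostModule
  # every planted link stays within its module: two diagonal blocks
  expect_true(all(vmod[links$virus_id] == hmod[links$host_id]))
  expect_setequal(unique(vmod[links$virus_id]), 1:2)
  bm <- buildIncidenceMatrix(truthPairs(truth))
  pm <- partitionModularity(bm,
                            rowModules = hmod[rownames(incidence(bm))],
                            colModules = vmod[colnames(incidence(bm))])
  expect_equal(pm$q_normalized, 1)
})

test_that("generalist count follows the ceiling rule", {
  truth <- simulateCommunity(nHosts = 4, nViruses = 20, nSamples = 1,
                             plantedModules = 4, generalistFraction = 0.1,
                             temperateFraction = 0, dominantFraction = 0,
                             seed = 2)
  deg <- table(trueLinks(truth)$virus_id)
  expect_identical(sum(deg >= 2), 2L)   # ceiling(0.1 * 20)
})

test_that("generator rejects invalid arguments", {
  expect_error(simulateCommunity(nHosts = 0, nViruses = 5, nSamples = 1,
                                 plantedModules = 1, seed = 1),
               "nHosts")
  expect_error(simulateCommunity(nHosts = 4, nViruses = 4, nSamples = 1,
                                 plantedModules = 6, seed = 1),
               "plantedModules")
  expect_error(simulateCommunity(nHosts = 4, nViruses = 4, nSamples = 1,
                                 plantedModules = 1, generalistFraction = 1.2,
                                 seed = 1),
               "generalistFraction")
})

test_that("evidence generation is deterministic and conserves read depth", {
  truth <- simulateCommunity(nHosts = 6, nViruses = 8, nSamples = 2,
                             plantedModules = 2, generalistFraction = 0,
                             temperateFraction = 0.5, dominantFraction = 0,
                             seed = 3)
  e1 <- simulateEvidence(truth, readDepth = 5000, seed = 4)
  e2 <- simulateEvidence(truth, readDepth = 5000, seed = 4)
  expect_identical(e1, e2)
  for (tab in list(e1$counts_cell, e1$counts_free)) {
    expect_true(all(tapply(tab$reads, tab$sample_id, sum) == 5000))
  }
  expect_error(simulateEvidence(truth, readDepth = 5000, prophageNoise = -1),
               "non-negative")
})

test_that("zero Hi-C rate leaves only the false-positive floor", {
  truth <- simulateCommunity(nHosts = 6, nViruses = 8, nSamples = 2,
                             plantedModules = 2, generalistFraction = 0,
                             temperateFraction = 0, dominantFraction = 0,
                             seed = 3)
  ev0 <- simulateEvidence(truth, readDepth = 2000, hicLinksPerInfection = 0,
                          hicFalsePositiveFloor = 0, seed = 5)
  expect_identical(nrow(ev0$hic), 0L)
  ev_fp <- simulateEvidence(truth, readDepth = 2000, hicLinksPerInfection = 0,
                            hicFalsePositiveFloor = 3, seed = 5)
  expect_identical(nrow(ev_fp$hic), 3L * 2L)   # 3 per sample
  tk <- pairKey(trueLinks(truth), "virus_id", "host_id")
  expect_false(any(pairKey(ev_fp$hic, "virus_id", "host_id") %in% tk))
})

test_that("noiseless prophage alignments all pass the 95/99 filter", {
  fx <- noiselessFixture()
  hits <- fx$evidence$prophage_hits
  expect_true(all(hits$percent_identity == 100))
  kept <- filterProphageHits(hits)
  expect_identical(sum(kept$support), nrow(hits))
})

test_that("length-normalized estimates converge to generator truth at high depth", {
  truth <- simulateCommunity(nHosts = 5, nViruses = 20, nSamples = 1,
                             plantedModules = 5, generalistFraction = 0,
                             temperateFraction = 0, dominantFraction = 0,
                             seed = 7)
  ev <- simulateEvidence(truth, readDepth = 1e6, seed = 7)
  rel <- relativeAbundance(ev$counts_free)
  va <- virusAbundance(truth, "free")[, 1]
  expected <- va / sum(va)
  estimate <- stats::setNames(rel$relative, rel$entity_id)[names(expected)]
  expect_lt(max(abs(estimate - expected)), 0.01)
})
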