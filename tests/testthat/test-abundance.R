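counts_df <- function(reads, lengths, sample = "s1", kind = "virus",
                      fraction = "free") {
  data.frame(entity_id = paste0("g", seq_along(reads)), sample_id = sample,
             fraction = fraction, kind = kind, reads = reads,
             genome_length = lengths, stringsAsFactors = FALSE)
}

test_that("relative abundance normalizes reads by genome length", {
  rel <- relativeAbundance(counts_df(c(100, 100), c(1000, 2000)))
  expect_equal(rel$relative, c(2 / 3, 1 / 3))
  expect_equal(rel$fractional, c(0.5, 0.5))
  expect_equal(relativeAbundance(counts_df(42, 5000))$relative, 1)
  expect_error(relativeAbundance(counts_df(c(0, 0), c(1000, 2000))), "s1")
})

test_that("relative abundance is invariant to uniform count scaling", {
  base <- counts_df(c(10, 25, 65), c(1500, 2500, 4000))
  scaled <- base
  scaled$reads <- scaled$reads * 17L
  expect_equal(relativeAbundance(base)$relative,
               relativeAbundance(scaled)$relative)
})

test_that("microscopy scaling conserves totals and proportions", {
  rel <- relativeAbundance(counts_df(c(100, 300), c(1000, 1000)))
  micro <- data.frame(sample_id = "s1", vlp_per_ml = 1e6, cells_per_ml = 2e5)
  gpm <- scaleByMicroscopy(rel, micro)
  expect_equal(sum(gpm$genomes_per_ml), 1e6)
  expect_equal(gpm$genomes_per_ml[2] / gpm$genomes_per_ml[1],
               rel$relative[2] / rel$relative[1])
  expect_equal(gpm$genomes_per_ml[1], 0.25 * 1e6)
  expect_error(scaleByMicroscopy(rel, micro[0, ]), "missing")
})

test_that("mixed-class tables scale each class to its own microscopy total", {
  tab <- rbind(counts_df(c(60, 40), c(1000, 1000), kind = "host",
                         fraction = "cell_associated"),
               counts_df(c(10, 10), c(1000, 1000), kind = "virus",
                         fraction = "cell_associated"))
  tab$entity_id <- c("h1", "h2", "v1", "v2")
  rel <- relativeAbundance(tab)
  micro <- data.frame(sample_id = "s1", vlp_per_ml = 4e6, cells_per_ml = 1e6)
  gpm <- scaleByMicroscopy(rel, micro)
  expect_equal(sum(gpm$genomes_per_ml[gpm$kind == "host"]), 1e6)
  expect_equal(sum(gpm$genomes_per_ml[gpm$kind == "virus"]), 4e6)
})

test_that("VHR is the virus to host genome density ratio per fraction", {
  pairs <- data.frame(virus_pop_id = "v1", host_species_id = "h1")
  vg <- data.frame(entity_id = "v1", sample_id = "s1",
                   fraction = c("cell_associated", "free"),
                   genomes_per_ml = c(1e6, 5e5))
  hg <- data.frame(entity_id = "h1", sample_id = "s1", genomes_per_ml = 1e5)
  vhr <- computeVHR(pairs, vg, hg)
  expect_equal(vhr$vhr_cell, 10)
  expect_equal(vhr$vhr_free, 5)

  # virus undetected in a fraction -> 0; zero-density host -> undefined
  vg0 <- vg[vg$fraction == "free", ]
  expect_equal(computeVHR(pairs, vg0, hg)$vhr_cell, 0)
  hg0 <- transform(hg, genomes_per_ml = 0)
  expect_true(is.na(computeVHR(pairs, vg, hg0)$vhr_cell))
})

test_that("free VHR scales linearly with the VLP total (through the VMR)", {
  fx <- noiselessFixture(seed = 21)
  ev <- fx$evidence
  rel_free <- relativeAbundance(ev$counts_free)
  rel_cell <- relativeAbundance(ev$counts_cell)
  pairs <- truthPairs(fx$truth)
  run <- function(micro) {
    gf <- scaleByMicroscopy(rel_free, micro)
    gc <- scaleByMicroscopy(rel_cell, micro)
    computeVHR(pairs, rbind(gf, gc[gc$kind == "virus", ]),
               gc[gc$kind == "host", ])
  }
  m1 <- ev$microscopy
  m2 <- transform(m1, vlp_per_ml = vlp_per_ml * 3)
  v1 <- run(m1); v2 <- run(m2)
  expect_equal(v2$vhr_free, v1$vhr_free * 3)
  # the free/cell VHR ratio only involves the two viral totals, so a common
  # VLP factor leaves it unchanged
  expect_equal(v2$vhr_free / v2$vhr_cell, v1$vhr_free / v1$vhr_cell)
})

test_that("rank statistics handle constant ranks and perfect concordance", {
  gpm <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s) {
    data.frame(entity_id = c("a", "b", "c"), sample_id = s,
               genomes_per_ml = c(30, 20, 10))
  }))
  rs <- rankStatistics(gpm)
  expect_true(all(rs$stats$rank_sd == 0))
  expect_equal(rs$stats$median_rank[rs$stats$entity_id == "a"], 1)

  # concordant virus/host ranks -> Spearman rho 1; reversed -> -1
  mk <- function(vvals, hvals) {
    rbind(data.frame(entity_id = paste0("v", 1:5), sample_id = "s1",
                     genomes_per_ml = vvals, kind = "virus"),
          data.frame(entity_id = paste0("h", 1:5), sample_id = "s1",
                     genomes_per_ml = hvals, kind = "host"))
  }
  pairs <- data.frame(virus_pop_id = paste0("v", 1:5),
                      host_species_id = paste0("h", 1:5))
  conc <- rankStatistics(mk(5:1, 50:46), pairs)
  expect_equal(conc$spearman$rho, 1)
  anti <- rankStatistics(mk(5:1, 46:50), pairs)
  expect_equal(anti$spearman$rho, -1)
})
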