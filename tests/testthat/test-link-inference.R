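blast_row <- function(query, subject, identity, qstart, qend, qlen) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = identity, alignment_length = qend - qstart + 1,
             mismatches = 0L, gap_opens = 0L,
             query_start = qstart, query_end = qend,
             subject_start = 1L, subject_end = qend - qstart + 1,
             e_value = 0, bitscore = 100, query_length = qlen,
             stringsAsFactors = FALSE)
}

test_that("prophage filter applies boundary-inclusive identity and coverage", {
  hits <- rbind(
    blast_row("v1", "h1", 95.0, 1, 99, 100),    # 95 / 99: boundary, retained
    blast_row("v2", "h1", 94.9, 1, 100, 100),   # identity below
    blast_row("v3", "h2", 100, 1, 98, 100),     # coverage 98, below
    blast_row("v4", "h2", 99, 1, 100, 100),     # retained
    blast_row("v5", "h3", 95, 1, 50, 100),      # coverage 50
    blast_row("v6", "h3", 80, 1, 100, 100))     # identity 80
  out <- filterProphageHits(hits)
  expect_identical(nrow(out), 2L)
  expect_setequal(out$virus_pop_id, c("v1", "v4"))
  expect_true(all(out$evidence_type == "prophage"))
})

test_that("prophage filter errors on missing query length, naming the row", {
  hits <- blast_row("v1", "h1", 99, 1, 100, 100)
  hits$query_length <- NA
  expect_error(filterProphageHits(hits), "query_length.*v1")
})

test_that("spacer filter enforces mismatch budget, coverage, and length", {
  matches <- data.frame(
    virus_id = c("v1", "v2", "v3", "v4"),
    host_id = c("h1", "h1", "h2", "h2"),
    mismatches_plus_gaps = c(2L, 3L, 0L, 0L),
    coverage_percent = c(100, 100, 100, 99),
    matched_length = c(21L, 30L, 19L, 25L),
    stringsAsFactors = FALSE)
  out <- filterSpacerMatches(matches)
  expect_identical(out$virus_pop_id, "v1")   # others fail mm / length / coverage
})

test_that("Hi-C filter keeps links above contact and score thresholds", {
  links <- data.frame(virus_id = c("v1", "v2"), host_id = c("h1", "h2"),
                      sample_id = "s1", contact_count = c(5L, 1L),
                      normalized_score = c(0.9, 0.99), stringsAsFactors = FALSE)
  out <- filterHicLinks(links, minContacts = 2)
  expect_identical(out$virus_pop_id, "v1")
  expect_identical(out$support, 5L)
})

test_that("filters are monotone in their thresholds", {
  fx <- noiselessFixture(seed = 9)
  hits <- simulateEvidence(fx$truth, readDepth = 2000, prophageNoise = 3,
                           nDecoyAlignments = 10, crisprMismatchRate = 0.05,
                           seed = 13)
  for (th in list(c(90, 95), c(95, 99), c(99, 100))) {
    strict <- filterProphageHits(hits$prophage_hits, th[1], th[2])
    relaxed <- filterProphageHits(hits$prophage_hits, th[1] - 5, th[2] - 5)
    expect_true(all(pairKey(strict) %in% pairKey(relaxed)))
  }
  strict <- filterSpacerMatches(hits$spacer_matches, maxMmGaps = 1)
  relaxed <- filterSpacerMatches(hits$spacer_matches, maxMmGaps = 3)
  expect_true(all(pairKey(strict) %in% pairKey(relaxed)))
})

test_that("dereplication follows single linkage with inclusive thresholds", {
  lens <- c(A = 30000, B = 20000, C = 10000)
  pw <- data.frame(a = c("A", "B"), b = c("B", "C"),
                   ani = c(96, 96), shared = c(85, 70))
  pm <- dereplicateGenomes(pw, aniThreshold = 95, sharedThreshold = 80,
                           memberLengths = lens)
  expect_identical(mapIds(pm, c("A", "B", "C")), c("A", "A", "C"))

  # empty table: everything its own representative
  pm0 <- dereplicateGenomes(pw[0, ], 95, 80, lens)
  expect_identical(mapIds(pm0, names(lens)), names(lens))

  # ANI exactly at the threshold joins (inclusive), no shared threshold
  pw2 <- data.frame(a = "A", b = "B", ani = 95.0)
  pm2 <- dereplicateGenomes(pw2, 95, NA, lens[c("A", "B")])
  expect_identical(unname(unique(mapIds(pm2, c("A", "B")))), "A")

  expect_error(dereplicateGenomes(data.frame(a = "A", b = "Z", ani = 99),
                                  95, NA, lens),
               "unknown genome")
})

test_that("representative choice prefers length then lexicographic id", {
  lens <- c(B = 5000, A = 5000)
  pm <- dereplicateGenomes(data.frame(a = "A", b = "B", ani = 99), 95, NA, lens)
  expect_identical(unname(mapIds(pm, "B")), "A")
})

test_that("merge collapses population members and unions evidence types", {
  ev <- data.frame(
    virus_pop_id = c("v1a", "v1b", "v2", "v2"),
    host_species_id = c("h1", "h1", "h2", "h2"),
    evidence_type = c("hic", "hic", "hic", "prophage"),
    sample_id = c("s1", "s2", "s1", "s1"),
    support = c(3L, 4L, 2L, 1L), stringsAsFactors = FALSE)
  vmap <- new("PopulationMap",
              map = c(v1a = "v1a", v1b = "v1a", v2 = "v2"),
              aniThreshold = 95, sharedThreshold = 80)
  merged <- mergeLinks(ev, virusMap = vmap)
  expect_identical(nrow(merged), 2L)
  row1 <- merged[merged$virus_pop_id == "v1a", ]
  expect_equal(row1$support_hic, 7)
  expect_identical(row1$n_samples, 2L)
  row2 <- merged[merged$virus_pop_id == "v2", ]
  expect_identical(row2$evidence_types, "hic,prophage")
  counts <- attr(merged, "type_counts")
  expect_identical(unname(counts["total"]), 2L)
  expect_identical(unname(counts["prophage"]), 1L)

  # fixed point: merging the merged table changes nothing
  again <- mergeLinks(merged)
  expect_equal(again, merged, ignore_attr = TRUE)
  expect_lte(nrow(merged), nrow(ev))
})

test_that("noiseless pipeline recovers exactly the planted links", {
  fx <- noiselessFixture(seed = 5)
  pairs <- mergedFromEvidence(fx$evidence)
  tk <- pairKey(trueLinks(fx$truth), "virus_id", "host_id")
  expect_setequal(pairKey(pairs), tk)
})

test_that("lifestyle classification gives prophage precedence over integrase", {
  labels <- classifyLifestyle(
    c("v1", "v2", "v3"),
    hasIntegrase = c(FALSE, TRUE, FALSE),
    prophagePairs = data.frame(virus_pop_id = "v1", host_species_id = "h1"))
  expect_identical(unname(labels),
                   c("temperate_prophage", "temperate", "lytic"))
  expect_identical(unname(coarseLifestyle(labels)),
                   c("temperate", "temperate", "lytic"))
})
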