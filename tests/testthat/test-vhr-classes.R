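mk_thr <- function(q1, q3, scale = "linear") {
  structure(list(q1_free = q1, q3_free = q3, q1_cell = q1, q3_cell = q3,
                 scale = scale), class = "VhrThresholds")
}

mk_pairs <- function(free, cell) {
  data.frame(virus_pop_id = paste0("v", seq_along(free)),
             host_species_id = paste0("h", seq_along(free)),
             median_vhr_free = free, median_vhr_cell = cell,
             stringsAsFactors = FALSE)
}

test_that("quartiles use linear interpolation between order statistics", {
  pairs <- mk_pairs(c(1, 2, 3, 4), c(1, 2, 3, 4))
  thr <- vhrQuartiles(pairs, scale = "linear")
  expect_equal(thr$q1_free, 1.75)
  expect_equal(thr$q3_free, 3.25)
  thr_const <- vhrQuartiles(mk_pairs(rep(2, 5), rep(2, 5)), scale = "linear")
  expect_equal(thr_const$q1_cell, thr_const$q3_cell)
  expect_error(vhrQuartiles(mk_pairs(1:3, 1:3), scale = "linear"), "at least 4")
})

test_that("pairs are classified into the four corner categories plus middle", {
  thr <- mk_thr(1, 3)
  pairs <- mk_pairs(free = c(5, 5, 0.5, 0.5, 2),
                    cell = c(0.5, 5, 0.5, 5, 2))
  out <- classifyVhrPairs(pairs, thr)
  expect_identical(out$category, c("1", "2", "3", "4", "middle"))
  # points exactly on a quartile line are middle
  on_line <- classifyVhrPairs(mk_pairs(3, 3), thr)
  expect_identical(on_line$category, "middle")
})

test_that("classification partitions pairs and is monotone in Q3", {
  set.seed(41)
  pairs <- mk_pairs(stats::rlnorm(80, 0, 1), stats::rlnorm(80, 0, 1))
  thr <- vhrQuartiles(pairs)
  out <- classifyVhrPairs(pairs, thr)
  expect_identical(nrow(out), 80L)
  expect_identical(sum(table(out$category)), 80L)

  thr_hi <- thr
  thr_hi$q3_free <- thr$q3_free + 0.5
  thr_hi$q3_cell <- thr$q3_cell + 0.5
  out_hi <- classifyVhrPairs(pairs, thr_hi)
  was_high <- out$category %in% c("1", "2", "4")
  now_high <- out_hi$category %in% c("1", "2", "4")
  expect_true(all(now_high <= was_high))   # raising Q3 only demotes
})

test_that("planted category groups are recovered exactly", {
  plant <- rbind(
    mk_pairs(stats::runif(10, 50, 60), stats::runif(10, 0.01, 0.02)),  # 1
    mk_pairs(stats::runif(10, 50, 60), stats::runif(10, 50, 60)),      # 2
    mk_pairs(stats::runif(10, 0.01, 0.02), stats::runif(10, 0.01, 0.02)), # 3
    mk_pairs(stats::runif(10, 0.01, 0.02), stats::runif(10, 50, 60)),  # 4
    mk_pairs(rep(1, 60), rep(1, 60)))   # middle: on the quartile lines
  plant$virus_pop_id <- paste0("v", seq_len(nrow(plant)))
  plant$host_species_id <- paste0("h", seq_len(nrow(plant)))
  thr <- vhrQuartiles(plant)
  out <- classifyVhrPairs(plant, thr)
  counts <- table(out$category)[c("1", "2", "3", "4", "middle")]
  expect_identical(as.integer(counts), c(10L, 10L, 10L, 10L, 60L))
})

test_that("group comparison reproduces exact null and extreme Wilcoxon p-values", {
  # identical groups: no location difference, p = 1
  same <- compareGroups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                        method = "nonparametric")
  expect_equal(same$pairwise$p_value, 1)

  # fully separated n=3 vs n=3: smallest attainable exact two-sided p = 0.1
  sep <- compareGroups(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3),
                       method = "nonparametric")
  expect_equal(sep$pairwise$p_value, 0.1)
  expect_identical(sep$method, "kruskal-wallis")

  expect_error(compareGroups(1:3, c("a", "a", "b")), ">= 2 groups")
})

test_that("compact letters separate a shifted group", {
  set.seed(43)
  vals <- c(stats::rlnorm(20, 0, 0.2), stats::rlnorm(20, 0, 0.2),
            stats::rlnorm(20, 4, 0.2))
  labs <- rep(c("g1", "g2", "g3"), each = 20)
  res <- compareGroups(vals, labs)
  expect_lt(res$omnibus$p_value, 0.001)
  expect_identical(res$letters[["g1"]], res$letters[["g2"]])
  expect_false(res$letters[["g3"]] %in% res$letters[c("g1", "g2")])
})

test_that("module presence applies the 50%-or-three-steps and one-step rules", {
  defs <- rbind(data.frame(module_id = "M1", step_id = paste0("K", 1:6)),
                data.frame(module_id = "M2", step_id = paste0("K", 11:20)),
                data.frame(module_id = "M3", step_id = paste0("K", 21:28)))
  ann_b <- rbind(
    data.frame(entity_id = "b1", step_id = paste0("K", 1:2)),     # 2/6: absent
    data.frame(entity_id = "b2", step_id = paste0("K", 11:13)),   # 3/10: present
    data.frame(entity_id = "b3", step_id = paste0("K", 1:3)))     # 3/6 = 50%
  pres_b <- modulePresence(ann_b, defs, "bMAG")
  expect_false(pres_b["b1", "M1"])
  expect_true(pres_b["b2", "M2"])
  expect_true(pres_b["b3", "M1"])

  ann_v <- data.frame(entity_id = c("v1", "v2"), step_id = c("K21", "K22"))
  pres_v <- modulePresence(ann_v, defs, "vMAG",
                           contamination = c(v1 = 0, v2 = 1.5))
  expect_true(pres_v["v1", "M3"])
  expect_false("v2" %in% rownames(pres_v))   # contaminated genomes excluded

  expect_warning(modulePresence(data.frame(entity_id = "b9", step_id = "K999"),
                                defs, "bMAG"),
                 "ignoring")
})

test_that("category enrichment is the frequency difference against middle hosts", {
  presence <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE,
                       TRUE, TRUE, TRUE, TRUE, TRUE), ncol = 2,
                     dimnames = list(paste0("h", 1:5), c("Mx", "My")))
  cats <- c(h1 = "2", h2 = "2", h3 = "middle", h4 = "middle", h5 = "middle")
  enr <- categoryEnrichment(presence, cats)
  expect_equal(enr["Mx", "2"], 1 - 1 / 3)
  expect_equal(enr["My", "2"], 0)           # ubiquitous module: difference 0
  expect_error(categoryEnrichment(presence, c(h1 = "2")), "middle")
})

test_that("shared virus-host modules are flagged per linked pair", {
  pv <- matrix(c(TRUE, FALSE), 1, 2, dimnames = list("v1", c("M1", "M2")))
  pb <- matrix(c(TRUE, TRUE), 1, 2, dimnames = list("h1", c("M1", "M2")))
  pairs <- data.frame(virus_pop_id = "v1", host_species_id = "h1")
  out <- sharedVirusHostModules(pv, pb, pairs)
  expect_identical(out$module_id, "M1")
})
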