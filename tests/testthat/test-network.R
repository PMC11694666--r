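test_that("incidence matrix construction is deterministic and idempotent", {
  pairs <- data.frame(virus_pop_id = c("v2", "v1", "v3", "v3"),
                      host_species_id = c("h1", "h2", "h1", "h1"))
  bm <- buildIncidenceMatrix(pairs)
  m <- incidence(bm)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(sum(m), 3)          # duplicate pair collapses to one 1
  expect_identical(rownames(m), c("h1", "h2"))
  expect_identical(colnames(m), c("v1", "v2", "v3"))
  expect_error(buildIncidenceMatrix(pairs[0, ]), "zero pairs")
})

test_that("NODF matches hand-computed values", {
  stair <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, byrow = TRUE)
  expect_equal(nodf(stair), 1)
  expect_equal(nodf(diag(3)), 0)
  expect_equal(nodf(matrix(c(1, 1, 1, 0, 0, 1), 3, byrow = TRUE)), 0.5)
})

test_that("NODF and temperature are invariant to row/column permutation", {
  set.seed(31)
  for (i in 1:5) {
    m <- randomBinaryMatrix(6, 7)
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nodf(perm), nodf(m))
    expect_equal(nestednessTemperature(perm)$temperature,
                 nestednessTemperature(m)$temperature)
  }
})

test_that("NODF agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (i in 1:10) {
    m <- randomBinaryMatrix(sample(4:8, 1), sample(4:8, 1))
    ref <- unname(vegan::nestednodf(m)$statistic["NODF"]) / 100
    expect_equal(nodf(m), ref, tolerance = 1e-12)
  }
})

test_that("temperature is 0 for nested matrices and high for checkerboards", {
  stair <- matrix(c(1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 0, 0), 3, byrow = TRUE)
  nt <- nestednessTemperature(stair)
  expect_equal(nt$temperature, 0)
  expect_equal(nt$score, 1)
  cb <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1), 4, byrow = TRUE)
  expect_gte(nestednessTemperature(cb)$temperature, 50)
  # degenerate all-ones matrix: temperature 0 by convention
  expect_equal(nestednessTemperature(matrix(1, 3, 3))$temperature, 0)
})

test_that("SS null model conserves fill and gives calibrated extremes", {
  # metric constant under shuffling -> p = 1
  m <- randomBinaryMatrix(5, 5)
  res <- nullModelSS(m, metric = function(x) sum(x), nPermutations = 199, seed = 1)
  expect_equal(res$p_value, 1)

  # perfectly nested observed matrix, nestedness metric -> minimal p
  stair <- matrix(0, 6, 6)
  for (i in 1:6) stair[i, seq_len(7 - i)] <- 1
  stair <- stair[, 1:6]
  res2 <- nullModelSS(stair, nodf, nPermutations = 999, seed = 11)
  expect_lt(res2$p_value, 0.01)

  # determinism given the seed
  res3 <- nullModelSS(stair, nodf, nPermutations = 999, seed = 11)
  expect_identical(res2, res3)
})

test_that("modularity optimizer matches exhaustive search on small matrices", {
  set.seed(23)
  for (i in 1:12) {
    m <- randomBinaryMatrix(sample(2:4, 1), sample(2:4, 1))
    opt <- barberModularity(m, nRestarts = 20, seed = i)
    expect_equal(opt$q_barber, oracleBarberQ(m), tolerance = 1e-9)
  }
})

test_that("modularity handles block-diagonal and structureless matrices", {
  block <- matrix(0, 4, 4)
  block[1:2, 1:2] <- 1
  block[3:4, 3:4] <- 1
  mod <- barberModularity(block, seed = 1)
  expect_equal(mod$q_normalized, 1)
  expect_identical(mod$n_modules, 2L)
  expect_identical(sort(unique(mod$module_assignment$module)), 1:2)

  complete <- matrix(1, 3, 4)
  mod2 <- barberModularity(complete, seed = 1)
  expect_equal(mod2$q_barber, 0)
  expect_identical(mod2$n_modules, 1L)
  expect_equal(mod2$q_normalized, 0)
})

test_that("five complete planted modules are recovered exactly", {
  truth <- simulateCommunity(nHosts = 10, nViruses = 15, nSamples = 1,
                             plantedModules = 5, generalistFraction = 0,
                             temperateFraction = 0, fill = 1,
                             dominantFraction = 0, seed = 6)
  bm <- buildIncidenceMatrix(truthPairs(truth))
  mod <- barberModularity(bm, seed = 3)
  expect_identical(mod$n_modules, 5L)
  expect_equal(mod$q_normalized, 1)
  # recovered assignment refines to the planted one
  hmod <- truth@hostModule[rownames(incidence(bm))]
  found <- mod$module_assignment
  host_found <- found$module[found$side == "host"]
  expect_identical(length(unique(paste(hmod, host_found))), 5L)
})

test_that("degree statistics report the specialist share to one decimal", {
  m <- matrix(0, 2, 3, dimnames = list(c("h1", "h2"), c("v1", "v2", "v3")))
  m[1, 1] <- 1; m[2, 2] <- 1; m[1, 3] <- 1; m[2, 3] <- 1
  deg <- degreeStats(m)
  expect_equal(deg$specialist_percent, 66.7)
  expect_identical(names(deg$generalists), "v3")
  expect_setequal(deg$generalists$v3, c("h1", "h2"))
  expect_equal(degreeStats(diag(4))$specialist_percent, 100)
  deg2 <- degreeStats(m, hostClass = c(h1 = "Alpha", h2 = "Gamma"))
  expect_identical(deg2$cross_class_generalists, 1L)
})
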