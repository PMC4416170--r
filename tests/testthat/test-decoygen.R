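test_that("RMSD filtering and binning follow the (k-1, k] scheme", {
  cfg <- decoyConfig()
  expect_equal(filterAndBin(c(0.5, 1.5, 9.9, 10.4), cfg),
               c(1L, 2L, 10L, NA))
  # exact bin edges: 1.0 belongs to bin 1, 10.0 to bin 10 (kept)
  expect_equal(filterAndBin(c(1, 10), cfg), c(1L, 10L))
  # everything beyond the filter is dropped
  expect_true(all(is.na(filterAndBin(c(10.01, 15, 20), cfg))))
  # the native (rmsd 0) is dropped unless includeNative
  expect_true(is.na(filterAndBin(0, cfg)))
  expect_equal(filterAndBin(0, decoyConfig(includeNative = TRUE)), 1L)
})

test_that("uniform RMSDs on (0, 12] fill ten bins and drop the rest", {
  set.seed(99)
  rmsds <- 12 * runif(2000)
  bins <- filterAndBin(rmsds, decoyConfig())
  tab <- table(bins)
  expect_length(tab, 10L)
  # ~2000/12 = 167 per bin in expectation
  expect_true(all(tab > 120 & tab < 215))
  expect_equal(sum(is.na(bins)), sum(rmsds > 10))
})

test_that("decoyConfig validates its geometry", {
  expect_error(decoyConfig(maxRmsd = 10, binWidth = 3), "integral")
  expect_error(decoyConfig(clustersPerBin = 0), "clustersPerBin")
  expect_equal(decoyPreset("train50")$clustersPerBin, 5L)
  expect_equal(decoyPreset("test100")$clustersPerBin, 10L)
})

test_that("bin clustering recovers separated pose groups", {
  base <- randomStructure(6, id = "base")
  near <- function(center, eps, id) {
    toyStructure(atomCoords(base) + center + eps, atomElements(base),
                 id = id)
  }
  set.seed(7)
  groupA <- lapply(1:4, function(i) near(0, matrix(rnorm(18, sd = 0.01), 6, 3),
                                         paste0("a", i)))
  groupB <- lapply(1:3, function(i) near(50, matrix(rnorm(18, sd = 0.01), 6, 3),
                                         paste0("b", i)))
  labels <- clusterBin(c(groupA, groupB), k = 2L)
  expect_equal(labels, c(rep(1L, 4), rep(2L, 3)))

  # fewer poses than clusters: all singletons
  expect_equal(clusterBin(groupB, k = 10L), 1:3)

  # identical poses collapse into forced splits only
  same <- lapply(1:5, function(i) near(0, 0, paste0("s", i)))
  expect_equal(length(unique(clusterBin(same, k = 2L))), 2L)
})

test_that("representative selection is argmin energy with index tie-break", {
  expect_equal(selectRepresentatives(c(1L, 1L, 1L), c(-5.2, -7.1, -3.0)), 2L)
  expect_equal(selectRepresentatives(c(1L, 1L), c(-5, -5)), 1L)
  expect_equal(selectRepresentatives(c(2L, 1L, 2L), c(-1, -2, -9)),
               c(2L, 3L))
  expect_error(selectRepresentatives(1L, NA_real_), "energy")
})

test_that("the surrogate energy matches the Lennard-Jones closed form", {
  r <- toyStructure(rbind(c(0, 0, 0)), "C", role = "receptor")
  # single pair at the well minimum r0 * 2^(1/6): energy exactly -1
  at <- toyStructure(rbind(c(3.5 * 2^(1 / 6), 0, 0)), "C")
  expect_equal(builtinEnergy(r, at), -1, tolerance = 1e-12)
  # nothing within 8 A: zero
  expect_identical(builtinEnergy(r, toyStructure(rbind(c(9, 0, 0)))), 0)

  # brute-force double-loop oracle on random complexes
  set.seed(13)
  for (i in 1:10) {
    rec <- randomStructure(25, role = "receptor", spread = 6)
    lig <- randomStructure(8, spread = 6)
    acc <- 0
    for (a in seq_len(25)) for (b in seq_len(8)) {
      d <- sqrt(sum((atomCoords(rec)[a, ] - atomCoords(lig)[b, ])^2))
      if (d <= 8) {
        d <- max(d, 1)
        acc <- acc + 4 * ((3.5 / d)^12 - (3.5 / d)^6)
      }
    }
    expect_equal(builtinEnergy(rec, lig), acc, tolerance = 1e-10)
  }
})

test_that("a well-populated pool yields 100 representatives under test100", {
  sc <- synthScenario(nComplexes = 1, posesPerComplex = 400, seed = 71)
  ps <- makeComplex(sc, 1)
  ds <- buildDecoySet(ps, decoyPreset("test100", energySource = "builtin"))
  man <- decoyManifest(ds)
  sel <- man[man$selected, ]
  expect_equal(nrow(sel), 100L)
  expect_equal(as.integer(table(sel$bin)), rep(10L, 10))
  # every representative's RMSD lies inside its bin's interval
  expect_true(all(sel$rmsd > (sel$bin - 1) & sel$rmsd <= sel$bin))
  # representatives are the energy minima of their clusters
  for (g in split(man[!is.na(man$bin), ], list(man$bin[!is.na(man$bin)],
                                               man$cluster[!is.na(man$bin)]),
                  drop = TRUE)) {
    expect_equal(sum(g$selected), 1L)
    expect_equal(g$energy[g$selected], min(g$energy))
  }
})

test_that("under-populated bins yield fewer representatives, never more", {
  sc <- synthScenario(nComplexes = 1, posesPerComplex = 30, seed = 5)
  ps <- makeComplex(sc, 1)
  ds <- buildDecoySet(ps, decoyPreset("test100", energySource = "builtin"))
  sel <- decoyManifest(ds)[decoyManifest(ds)$selected, ]
  expect_lte(nrow(sel), 100L)
  expect_true(all(table(sel$bin) <= 10L))
})

test_that("the decoy pipeline is deterministic given input order and config", {
  sc <- synthScenario(nComplexes = 1, posesPerComplex = 80, seed = 19)
  ps <- makeComplex(sc, 1)
  cfg <- decoyPreset("train50", energySource = "builtin")
  expect_identical(decoyManifest(buildDecoySet(ps, cfg)),
                   decoyManifest(buildDecoySet(ps, cfg)))
})

test_that("provided-energy mode requires energies", {
  sc <- synthScenario(nComplexes = 1, posesPerComplex = 10, seed = 3)
  ps <- makeComplex(sc, 1)
  expect_error(buildDecoySet(ps, decoyConfig(energySource = "provided")),
               "data error")
})
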