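# exhaustive per-complex enumeration oracle
successOracle <- function(rankedRmsd, C, N, zeroTol = 1e-6) {
  hits <- 0L
  for (r in rankedRmsd) {
    thr <- if (C == 0) zeroTol else C
    best <- Inf
    for (i in seq_len(min(N, length(r)))) best <- min(best, r[i])
    if (best <= thr) hits <- hits + 1L
  }
  100 * hits / length(rankedRmsd)
}

test_that("success rates follow the top-N within-C definition", {
  expect_equal(successRate(list(c(0.5, 3)), C = 1, N = 1), 100)
  r <- list(c(2.5, 0.8, 4.0))
  expect_equal(successRate(r, C = 1, N = 1), 0)
  expect_equal(successRate(r, C = 1, N = 2), 100)
  # the hit test is inclusive at the boundary
  expect_equal(successRate(list(1.0), C = 1, N = 1), 100)
  # C = 0 means exact-native up to the zero tolerance
  expect_equal(successRate(list(c(1e-9, 2)), C = 0, N = 1), 100)
  expect_equal(successRate(list(c(1e-3, 2)), C = 0, N = 1), 0)
  expect_error(successRate(list(c(1), numeric()), 1, 1), "empty ranking")
})

test_that("success rates equal the brute-force oracle on random instances", {
  set.seed(20)
  for (rep in 1:20) {
    ranked <- lapply(seq_len(sample(3:10, 1)), function(i)
      runif(sample(1:10, 1), 0, 6))
    for (C in c(0, 1, 2, 3)) for (N in c(1, 2, 3, 5))
      expect_equal(successRate(ranked, C, N),
                   successOracle(ranked, C, N), tolerance = 1e-12)
  }
})

test_that("reports are monotone in C and N and bounded", {
  set.seed(33)
  ranked <- lapply(1:15, function(i) runif(8, 0, 5))
  rep <- poseforge:::successReport(ranked, evalConfig())
  r <- successRates(rep)
  expect_true(all(r$rate >= 0 & r$rate <= 100))
  for (nn in unique(r$N))
    expect_false(is.unsorted(r$rate[r$N == nn][order(r$C[r$N == nn])]))
  for (cc in unique(r$C))
    expect_false(is.unsorted(r$rate[r$C == cc][order(r$N[r$C == cc])]))
  # with a cutoff above every RMSD the rate saturates at 100
  expect_equal(successRate(ranked, C = 10, N = 1), 100)
  # hit matrix dimensions
  expect_equal(dim(hitMatrix(rep)), c(15L, 16L))
})

test_that("a perfect oracle model attains S0^1 = 100 and an inverted one 0", {
  bench <- smallBenchmark()
  # 1-NN on the true RMSD column is a perfect oracle on its training data
  d <- featureData(bench$table)
  d$R.oracle <- d$RMSD
  fam <- c(featureFamilies(bench$table), R.oracle = "R")
  tab <- FeatureTable(d, fam)
  oracle <- fitScoringModel(tab, "kNN", "RMSD", columns = "R.oracle",
                            params = list(k = 1L, q = 1))
  rep <- evaluateModel(oracle, tab)
  r <- successRates(rep)
  expect_equal(r$rate[r$C == 0 & r$N == 1], 100)

  # inverted oracle: its "RMSD" prediction reverses the true pose order
  dInv <- d
  dInv$RMSD <- max(d$RMSD) - d$RMSD
  inv <- fitScoringModel(FeatureTable(dInv, fam), "kNN", "RMSD",
                         columns = "R.oracle", params = list(k = 1L, q = 1))
  repInv <- evaluateModel(inv, tab)  # ranks each complex worst-first
  # worst pose of every complex is > 1 A here, so S1^1 must be 0
  worst <- tapply(d$RMSD, d$complex_id, max)
  expect_true(all(worst > 1))
  rInv <- successRates(repInv)
  expect_equal(rInv$rate[rInv$C == 1 & rInv$N == 1], 0)
})

test_that("excluding the native pose never improves exact-native success", {
  bench <- smallBenchmark()
  m <- fitScoringModel(bench$table, "MLR", "RMSD", families = "XARG")
  with_ <- evaluateModel(m, bench$table, evalConfig(includeNative = TRUE))
  without <- evaluateModel(m, bench$table, evalConfig(includeNative = FALSE))
  s01 <- function(rep) {
    r <- successRates(rep)
    r$rate[r$C == 0 & r$N == 1]
  }
  expect_lte(s01(without), s01(with_))
  expect_equal(s01(without), 0)  # no native row can remain a C=0 hit
})

test_that("learning curves at 100% have zero sampling variance", {
  bench <- smallBenchmark()
  test <- smallBenchmark(nComplexes = 10L, seed = 12L)
  lc <- learningCurve(bench$table, test$table, method = "MLR",
                      response = "RMSD", families = "R",
                      sizes = c(50, 100), repeats = 3L, seed = 9L)
  expect_equal(nrow(lc), 2L)
  expect_equal(lc$sd[lc$size == 100], 0)
  expect_error(
    learningCurve(bench$table, test$table, method = "MLR",
                  response = "RMSD", families = "R", sizes = 1,
                  repeats = 1L),
    "configuration")
})

test_that("per-pose subsampling keeps the native row and x poses", {
  bench <- smallBenchmark()
  test <- smallBenchmark(nComplexes = 10L, seed = 12L)
  lc <- learningCurve(bench$table, test$table, method = "MLR",
                      response = "RMSD", families = "R",
                      sizes = c(2, 8), mode = "poses", repeats = 2L,
                      seed = 9L)
  expect_equal(nrow(lc), 2L)
  expect_true(all(is.finite(lc$rate)))
})

test_that("feature curves cap at the pool and sample without replacement", {
  bench <- smallBenchmark()
  test <- smallBenchmark(nComplexes = 10L, seed = 12L)
  pool <- length(featureFamilies(bench$table))
  fc <- featureCurve(bench$table, test$table, method = "MLR",
                     response = "RMSD", sizes = c(10, pool),
                     repeats = 3L, seed = 21L)
  expect_equal(fc$repeats, c(3L, 1L))   # full pool is deterministic
  expect_equal(fc$sd[2], 0)
  expect_error(featureCurve(bench$table, test$table, sizes = pool + 1),
               "configuration")
  # sampled subsets contain no duplicated columns by construction
  cols <- poseforge:::withSeed(3L,
    sample(names(featureFamilies(bench$table)), 10))
  expect_false(anyDuplicated(cols) > 0)
})
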