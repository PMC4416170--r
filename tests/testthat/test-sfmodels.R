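# small deterministic regression table: y = 2 x1 - 3 x2 + 1 on noise features
linearTable <- function(n = 60, seed = 2) {
  set.seed(seed)
  d <- data.frame(complex_id = paste0("c", seq_len(n)), pose_id = "native",
                  R.f1 = runif(n), R.f2 = runif(n), R.f3 = runif(n))
  d$RMSD <- pmax(0, 2 * d$R.f1 - 3 * d$R.f2 + 1)
  FeatureTable(d, c(R.f1 = "R", R.f2 = "R", R.f3 = "R"))
}

test_that("MLR recovers an exact linear rule", {
  tab <- linearTable()
  d <- featureData(tab)
  keep <- d$RMSD > 0  # strictly interior rows so the rule is exactly linear
  m <- fitScoringModel(tab[keep], "MLR", "RMSD")
  pred <- predict(m, tab[keep])
  expect_equal(pred, d$RMSD[keep], tolerance = 1e-10)
  expect_equal(unname(m@fit$coef), c(1, 2, -3, 0), tolerance = 1e-8)
})

test_that("kNN with k = 1 reproduces its training rows", {
  tab <- linearTable(n = 40)
  m <- fitScoringModel(tab, "kNN", "RMSD", params = list(k = 1L, q = 1))
  expect_equal(predict(m, tab), featureData(tab)$RMSD, tolerance = 1e-12)
})

test_that("BA-response models train on native rows only", {
  bench <- smallBenchmark()
  m <- fitScoringModel(bench$table, "MLR", "BA", families = "X")
  expect_equal(m@nTrain, 25L)  # one native row per complex
  mR <- fitScoringModel(bench$table, "MLR", "RMSD", families = "X")
  expect_equal(mR@nTrain, 25L * 9L)  # every pose is a training record
})

test_that("predictions are finite, row-permutation invariant and typed", {
  bench <- smallBenchmark()
  for (method in c("MLR", "MARS", "kNN", "SVM")) {
    m <- fitScoringModel(bench$table, method, "RMSD", families = "RG")
    p <- predict(m, bench$table)
    expect_true(all(is.finite(p)))
    set.seed(1)
    perm <- sample(length(p))
    expect_equal(predict(m, bench$table[perm]), p[perm], tolerance = 1e-12)
  }
})

test_that("feature-signature mismatches are schema errors", {
  bench <- smallBenchmark()
  m <- fitScoringModel(bench$table, "MLR", "RMSD", families = "R")
  dropped <- featureData(bench$table)
  dropped <- dropped[, !grepl("^R\\.C", names(dropped))]
  fam <- featureFamilies(bench$table)
  fam <- fam[names(fam) %in% names(dropped)]
  expect_error(predict(m, FeatureTable(dropped, fam)), "schema")
})

test_that("identical table, params and seed give identical predictions", {
  bench <- smallBenchmark()
  for (method in c("RF", "BRT")) {
    params <- if (method == "RF") list(nTrees = 50L)
              else list(nTrees = 30L)
    m1 <- fitScoringModel(bench$table, method, "RMSD", families = "R",
                          params = params, seed = 77L)
    m2 <- fitScoringModel(bench$table, method, "RMSD", families = "R",
                          params = params, seed = 77L)
    expect_identical(predict(m1, bench$table), predict(m2, bench$table))
  }
})

test_that("save/load round-trips reproduce predictions bitwise", {
  bench <- smallBenchmark()
  for (method in c("MLR", "MARS", "kNN", "SVM", "RF", "BRT")) {
    params <- switch(method, RF = list(nTrees = 40L),
                     BRT = list(nTrees = 25L), list())
    m <- fitScoringModel(bench$table, method, "RMSD", families = "RG",
                         params = params)
    path <- tempfile(fileext = ".rds")
    saveScoringModel(m, path)
    back <- loadScoringModel(path)
    expect_identical(predict(back, bench$table), predict(m, bench$table))
  }
})

test_that("pose ranking follows the response direction with stable ties", {
  d <- data.frame(complex_id = "c1", pose_id = paste0("p", 1:3),
                  R.f1 = c(0.1, 0.2, 0.3), RMSD = c(1, 1, 1))
  tab <- FeatureTable(d, c(R.f1 = "R"))

  # a 1-NN model trained at the query features reproduces `preds` exactly
  fake <- function(response, preds) {
    td <- data.frame(complex_id = "t", pose_id = paste0("q", seq_along(preds)),
                     R.f1 = c(0.1, 0.2, 0.3)[seq_along(preds)], RMSD = preds)
    m <- fitScoringModel(FeatureTable(td, c(R.f1 = "R")), "kNN", "RMSD",
                         params = list(k = 1L, q = 1))
    m@response <- response
    m
  }
  # RMSD response: ascending predicted score
  r <- rankPoses(fake("RMSD", c(2.1, 0.3, 5.0)), tab)
  expect_equal(unname(r$c1), c(2L, 1L, 3L))
  # BA response: descending predicted score
  tab2 <- FeatureTable(d[1:2, ], c(R.f1 = "R"))
  b <- rankPoses(fake("BA", c(6.2, 7.9)), tab2)
  expect_equal(unname(b$c1), c(2L, 1L))
  # exact tie: original order preserved
  t <- rankPoses(fake("RMSD", c(1, 1, 1)), tab)
  expect_equal(unname(t$c1), c(1L, 2L, 3L))
})

test_that("single-point grids return directly and empty ranges error", {
  bench <- smallBenchmark()
  res <- tuneScoringModel(bench$table, "kNN", "RMSD", families = "R",
                          grid = list(k = 7L, q = 1))
  expect_equal(res$params$k, 7L)
  expect_null(res$results)
  expect_error(tuneScoringModel(bench$table, "kNN", "RMSD", families = "R",
                                grid = list(k = integer(), q = 1)),
               "configuration")
})

test_that("CV tuning matches an exhaustive fold-loop oracle for kNN", {
  # response varies at single-neighbour scale, so small k should win
  set.seed(8)
  n <- 80
  d <- data.frame(complex_id = paste0("c", 1:n), pose_id = "native",
                  R.f1 = runif(n, 0, 10))
  d$RMSD <- abs(sin(3 * d$R.f1)) * 5
  tab <- FeatureTable(d, c(R.f1 = "R"))
  grid <- list(k = c(1L, 5L, 15L, 30L), q = 1)
  res <- tuneScoringModel(tab, "kNN", "RMSD", grid = grid, seed = 123L)
  expect_lte(res$params$k, 5L)

  # independent oracle: plain double loop over folds and grid points
  folds <- poseforge:::withSeed(123L, sample(rep(1:10, length.out = n)))
  x <- scale(d$R.f1)
  oracleMse <- sapply(grid$k, function(k) {
    mean(sapply(1:10, function(f) {
      tr <- folds != f
      preds <- sapply(which(!tr), function(i) {
        dist <- abs(x[tr] - x[i])
        mean(d$RMSD[tr][order(dist)[seq_len(min(k, sum(tr)))]])
      })
      mean((preds - d$RMSD[!tr])^2)
    }))
  })
  expect_equal(res$results$mse, oracleMse, tolerance = 1e-10)
  expect_equal(res$params$k, grid$k[which.min(oracleMse)])
})

test_that("RF mtry tuning uses out-of-bag error deterministically", {
  bench <- smallBenchmark()
  r1 <- tuneScoringModel(bench$table, "RF", "RMSD", families = "R",
                         grid = list(mtry = c(3L, 12L)), tuneTrees = 60L,
                         seed = 5L)
  r2 <- tuneScoringModel(bench$table, "RF", "RMSD", families = "R",
                         grid = list(mtry = c(3L, 12L)), tuneTrees = 60L,
                         seed = 5L)
  expect_identical(r1$results$mse, r2$results$mse)
  expect_true(r1$params$mtry %in% c(3L, 12L))
})

test_that("shipped tuned values load by method and feature signature", {
  expect_equal(tunedParams("RF", "XARG")$mtry, 35L)
  expect_equal(tunedParams("MARS", "X")$degree, 2L)
  expect_equal(tunedParams("MARS", "XR")$penalty, 2)
  expect_equal(tunedParams("kNN", "XA")$k, 9L)
  expect_equal(tunedParams("SVM", "XR")$sigma, 0.031)
  expect_equal(tunedParams("BRT", "XARG")$nTrees, 2859L)
  expect_true(all(sapply(enumerateFamilyCombinations(),
                         function(f) tunedParams("kNN", f)$q) == 1))
  expect_error(tunedParams("RF", "ZZ"), "no tuned parameters")
})

test_that("BRT training error is non-increasing as trees are added", {
  bench <- smallBenchmark()
  m <- fitScoringModel(bench$table, "BRT", "RMSD", families = "R",
                       params = list(nTrees = 60L))
  X <- poseforge:::featureMatrix(bench$table, families = "R")
  y <- featureData(bench$table)$RMSD
  errs <- sapply(seq(5L, 60L, 5L), function(k) {
    p <- predict(m@fit, xgboost::xgb.DMatrix(X), iterationrange = c(1, k))
    mean((p - y)^2)
  })
  expect_true(all(diff(errs) <= 1e-9))
})
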