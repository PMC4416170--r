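#' @name sfmodels
#' @title The six regression scoring functions
#' @description
#' Scoring functions are regressors mapping per-pose descriptors to either
#' experimental binding affinity (response `"BA"`, trained on native poses
#' only — affinities exist only for natives) or RMSD to the native pose
#' (response `"RMSD"`, trained on all poses, so the training table scales
#' with the number of generated poses per complex). Supported methods:
#'
#' * `MLR` — multiple linear regression (`stats::lm`).
#' * `MARS` — in-house multivariate adaptive regression splines
#'   (see [mars]); tuned by `degree` and `penalty`, term count
#'   auto-selected by GCV.
#' * `kNN` — k-nearest-neighbour regression with Minkowski distance of
#'   degree `q`, in-house.
#' * `SVM` — epsilon-regression SVM with an RBF kernel
#'   (`e1071::svm`); the kernel width `sigma` parameterises
#'   `exp(-||u - v||^2 / (2 sigma^2))`, i.e. `gamma = 1/(2 sigma^2)`.
#' * `RF` — random forest (`randomForest`), 2000 trees by default, `mtry`
#'   tuned on out-of-bag error.
#' * `BRT` — boosted regression trees (gradient boosting via `xgboost`),
#'   shrinkage fixed at 0.005, tree count selected by internal 5-fold
#'   cross-validation, `interactionDepth` tuned.
#'
#' Features are standardised to zero mean / unit variance for kNN and SVM
#' only (both are distance/kernel based); linear and tree methods see raw
#' features.
NULL

sfMethods <- c("MLR", "MARS", "kNN", "SVM", "RF", "BRT")

defaultSfSeed <- 20070101L

defaultParams <- function(method, p) {
  switch(method,
    MLR  = list(),
    MARS = list(degree = 1L, penalty = 3),
    kNN  = list(k = 9L, q = 1),
    SVM  = list(C = 1, epsilon = 0.25, sigma = 0.125),
    RF   = list(mtry = max(1L, floor(p / 3)), nTrees = 2000L),
    BRT  = list(interactionDepth = 10L, nTrees = NULL, shrinkage = 0.005))
}

#' Default hyperparameter grids
#'
#' Per-method search ranges used by [tuneScoringModel()]. Fixed constants
#' (2000 trees for RF, shrinkage 0.005 for BRT) are not part of any grid.
#'
#' @param method one of MLR, MARS, kNN, SVM, RF, BRT.
#' @param p number of features (used for the RF mtry range).
#' @return named list of parameter value vectors (empty for MLR).
#' @export
defaultGrid <- function(method = sfMethods, p = 36L) {
  method <- match.arg(method)
  switch(method,
    MLR  = list(),
    MARS = list(degree = 1:2, penalty = 2:7),
    kNN  = list(k = seq(3L, 21L, 2L), q = 1:2),
    SVM  = list(C = c(1, 2, 4), epsilon = c(0.125, 0.25, 0.5),
                sigma = c(0.031, 0.125, 0.25, 1)),
    RF   = list(mtry = unique(pmax(1L, floor(p * c(1/6, 1/3, 1/2, 2/3))))),
    BRT  = list(interactionDepth = c(5L, 10L, 15L, 20L)))
}

# ---- backend fit/predict ----------------------------------------------

knnFit <- function(X, y, params) {
  list(X = X, y = y, k = as.integer(params$k), q = params$q)
}

knnPredict <- function(fit, X) {
  k <- min(fit$k, nrow(fit$X))
  apply(X, 1L, function(row) {
    d <- rowSums(abs(sweep(fit$X, 2L, row))^fit$q)^(1 / fit$q)
    mean(fit$y[order(d)[seq_len(k)]])
  })
}

brtCvRounds <- function(X, y, params, nfold = 5L, maxRounds = 3000L) {
  cv <- xgboost::xgb.cv(
    params = list(objective = "reg:squarederror", eta = params$shrinkage,
                  max_depth = params$interactionDepth, nthread = 1L),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = maxRounds,
    nfold = nfold, early_stopping_rounds = 50L, verbose = 0L)
  max(1L, cv$early_stop$best_iteration %||% cv$niter)
}

fitBackend <- function(method, X, y, params) {
  switch(method,
    MLR = {
      fit <- stats::lm.fit(cbind(1, X), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    MARS = marsFit(X, y, degree = params$degree, penalty = params$penalty,
                   maxTerms = params$maxTerms %||% 21L),
    kNN = knnFit(X, y, params),
    SVM = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = params$C,
                     epsilon = params$epsilon,
                     gamma = 1 / (2 * params$sigma^2), scale = FALSE),
    RF = randomForest::randomForest(x = X, y = y,
                                    ntree = params$nTrees %||% 2000L,
                                    mtry = min(params$mtry, ncol(X))),
    BRT = {
      nTrees <- params$nTrees
      if (is.null(nTrees)) nTrees <- brtCvRounds(X, y, params)
      xgboost::xgb.train(
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = nTrees,
        verbose = 0L,
        params = list(objective = "reg:squarederror",
                      eta = params$shrinkage,
                      max_depth = params$interactionDepth, nthread = 1L))
    })
}

predictBackend <- function(method, fit, X, params) {
  switch(method,
    MLR = drop(cbind(1, X) %*% fit$coef),
    MARS = marsPredict(fit, X),
    kNN = knnPredict(fit, X),
    SVM = as.numeric(stats::predict(fit, X)),
    RF = as.numeric(stats::predict(fit, X)),
    BRT = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X))))
}

# ---- user-facing fit / tune / predict ---------------------------------

# training design matrix + response for one (table, response, selection)
trainingDesign <- function(table, response, families = NULL,
                           columns = NULL) {
  d <- featureData(table)
  if (response == "BA") {
    rows <- which(!is.na(d$BA))
    if (!length(rows))
      stop("data error: no rows carry a BA response", call. = FALSE)
    y <- d$BA[rows]
  } else {
    if (!"RMSD" %in% names(d))
      stop("data error: table lacks the RMSD response column", call. = FALSE)
    rows <- seq_len(nrow(d))
    y <- d$RMSD
  }
  X <- featureMatrix(table, families = families, columns = columns)[rows, ,
                                                                    drop = FALSE]
  bad <- which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0)
  if (length(bad))
    stop("data error: non-finite features in row(s) ",
         paste(utils::head(rows[bad], 10L), collapse = ", "), call. = FALSE)
  list(X = X, y = y, rows = rows)
}

#' Fit a scoring model
#'
#' @param table a [FeatureTable-class] carrying the requested features and
#'   the response column (`BA` on native rows, or `RMSD` on all rows).
#' @param method one of `"MLR"`, `"MARS"`, `"kNN"`, `"SVM"`, `"RF"`,
#'   `"BRT"`.
#' @param response `"RMSD"` or `"BA"`. With `"BA"` only rows carrying an
#'   affinity (the natives) are used, so the training size equals the
#'   number of complexes; with `"RMSD"` every pose is a training record.
#' @param families descriptor-family selection (e.g. `"XARG"` or
#'   `c("R","G")`); `NULL` uses all feature columns.
#' @param columns explicit feature column selection (overrides
#'   `families`).
#' @param params named list of hyperparameters; missing entries take the
#'   method defaults (see [sfmodels]).
#' @param seed integer seed controlling all fit-time randomness.
#' @return a [ScoringModel-class].
#' @examples
#' bench <- makeBenchmark(synthScenario(nComplexes = 12, posesPerComplex = 6))
#' m <- fitScoringModel(bench$table, "MLR", response = "RMSD", families = "R")
#' m
#' @export
fitScoringModel <- function(table, method = sfMethods,
                            response = c("RMSD", "BA"), families = NULL,
                            columns = NULL, params = list(),
                            seed = defaultSfSeed) {
  method <- match.arg(method)
  response <- match.arg(response)
  des <- trainingDesign(table, response, families, columns)
  X <- des$X
  full <- defaultParams(method, ncol(X))
  full[names(params)] <- params
  center <- scale <- numeric()
  if (method %in% c("kNN", "SVM")) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }
  fit <- withSeed(seed, fitBackend(method, X, des$y, full))
  famSig <- if (!is.null(columns)) "custom"
            else if (is.null(families)) {
              fams <- unique(featureFamilies(table))
              c("X", "A", "R", "G")[c("X", "A", "R", "G") %in% fams]
            } else if (length(families) == 1L && nchar(families) > 1L)
              strsplit(families, "")[[1L]]
            else families
  new("ScoringModel", method = method, response = response,
      families = famSig, featureNames = colnames(des$X),
      params = full, fit = fit, center = center, scale = scale,
      seed = as.integer(seed), nTrain = nrow(X))
}

#' Tune scoring-model hyperparameters
#'
#' Grid search minimising mean-squared error. MARS, kNN, SVM and BRT are
#' tuned by 10-fold cross-validation over the training table; RF's `mtry`
#' is tuned on out-of-bag error, the forest's own internal validation set.
#' Deterministic given `seed`; on ties the first (smallest, in documented
#' grid order) parameter combination wins. A single-point grid is returned
#' directly without cross-validation.
#'
#' @inheritParams fitScoringModel
#' @param grid named list of parameter value vectors (default
#'   [defaultGrid()]); expanded with the first parameter varying fastest.
#' @param nFolds number of CV folds (default 10).
#' @param tuneTrees forest size used while tuning RF mtry (the final model
#'   is still fitted with its own `nTrees`).
#' @return list with `params` (the winning combination) and `results`
#'   (data.frame of grid points and their validation MSE; `NULL` for a
#'   single-point grid).
#' @export
tuneScoringModel <- function(table, method = sfMethods,
                             response = c("RMSD", "BA"), families = NULL,
                             columns = NULL, grid = NULL, nFolds = 10L,
                             tuneTrees = 500L, seed = defaultSfSeed) {
  method <- match.arg(method)
  response <- match.arg(response)
  des <- trainingDesign(table, response, families, columns)
  if (nrow(des$X) < 20L)
    stop("configuration error: tuning needs at least 20 training rows",
         call. = FALSE)
  if (is.null(grid)) grid <- defaultGrid(method, ncol(des$X))
  if (method == "MLR" || !length(grid))
    return(list(params = list(), results = NULL))
  if (any(!lengths(grid)))
    stop("configuration error: empty parameter range in grid", call. = FALSE)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) == 1L)
    return(list(params = as.list(pts[1L, , drop = FALSE]), results = NULL))

  X <- des$X
  y <- des$y
  if (method %in% c("kNN", "SVM")) {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  }
  full0 <- defaultParams(method, ncol(X))

  if (method == "RF") {
    mse <- withSeed(seed, vapply(seq_len(nrow(pts)), function(i) {
      p <- full0
      p[names(pts)] <- as.list(pts[i, , drop = FALSE])
      p$nTrees <- tuneTrees
      rf <- fitBackend("RF", X, y, p)
      rf$mse[length(rf$mse)]   # OOB MSE of the full forest
    }, numeric(1)))
  } else {
    folds <- withSeed(seed, sample(rep(seq_len(nFolds),
                                       length.out = nrow(X))))
    mse <- vapply(seq_len(nrow(pts)), function(i) {
      p <- full0
      p[names(pts)] <- as.list(pts[i, , drop = FALSE])
      if (method == "BRT" && is.null(p$nTrees))
        p$nTrees <- 500L       # fixed modest count inside the tuning loop
      errs <- vapply(seq_len(nFolds), function(f) {
        tr <- folds != f
        fit <- withSeed(seed + f, fitBackend(method,
                                             X[tr, , drop = FALSE], y[tr], p))
        pred <- predictBackend(method, fit, X[!tr, , drop = FALSE], p)
        mean((pred - y[!tr])^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  }
  best <- which.min(mse)       # first minimum = smallest tuple in grid order
  list(params = as.list(pts[best, , drop = FALSE]),
       results = cbind(pts, mse = mse))
}

#' Published tuned hyperparameters
#'
#' Returns the benchmark-tuned parameter values shipped with the package
#' (file `extdata/tuned_params.csv`) for a method and feature-set
#' signature, ready to pass as `params` to [fitScoringModel()].
#'
#' @param method one of MARS, kNN, SVM, RF, BRT.
#' @param features feature-set signature, e.g. `"XARG"`.
#' @return named list of parameter values.
#' @examples
#' tunedParams("RF", "XARG")  # mtry = 35
#' @export
tunedParams <- function(method, features) {
  path <- system.file("extdata", "tuned_params.csv", package = "poseforge")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sel <- tab[tab$method == method & tab$featureset == features, ]
  if (!nrow(sel))
    stop("no tuned parameters recorded for ", method, "::", features,
         call. = FALSE)
  out <- as.list(sel$value)
  names(out) <- sel$param
  if ("k" %in% names(out)) out$k <- as.integer(out$k)
  if ("mtry" %in% names(out)) out$mtry <- as.integer(out$mtry)
  if ("interactionDepth" %in% names(out))
    out$interactionDepth <- as.integer(out$interactionDepth)
  if ("nTrees" %in% names(out)) out$nTrees <- as.integer(out$nTrees)
  if ("degree" %in% names(out)) out$degree <- as.integer(out$degree)
  out
}

#' Predict pose scores
#'
#' @param object a [ScoringModel-class].
#' @param newdata a [FeatureTable-class] (or matrix/data.frame) carrying
#'   exactly the model's training feature columns.
#' @return numeric vector of scores, one per row.
#' @export
setMethod("predict", "ScoringModel", function(object, newdata) {
  X <- if (is(newdata, "FeatureTable")) {
    d <- featureData(newdata)
    miss <- setdiff(object@featureNames, names(d))
    if (length(miss))
      stop("schema error: table lacks model feature column(s) ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    featureMatrix(newdata, columns = object@featureNames)
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m))) {
      miss <- setdiff(object@featureNames, colnames(m))
      if (length(miss))
        stop("schema error: missing feature column(s) ",
             paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
      m <- m[, object@featureNames, drop = FALSE]
    } else if (ncol(m) != length(object@featureNames))
      stop("schema error: expected ", length(object@featureNames),
           " feature columns, got ", ncol(m), call. = FALSE)
    storage.mode(m) <- "double"
    m
  }
  if (length(object@center))
    X <- sweep(sweep(X, 2L, object@center), 2L, object@scale, "/")
  scores <- predictBackend(object@method, object@fit, X, object@params)
  if (any(!is.finite(scores)))
    stop("data error: non-finite predictions", call. = FALSE)
  scores
})

#' Rank poses by predicted score
#'
#' Orders the rows of each complex by the model's prediction: ascending
#' for RMSD-response models (lower predicted RMSD = better pose),
#' descending for BA-response models (higher predicted affinity = better
#' pose). Ties are broken by the original row order (stable).
#'
#' @param model a [ScoringModel-class].
#' @param table a [FeatureTable-class].
#' @return named list (one element per complex, in first-appearance order)
#'   of integer row indices into `table`, best pose first.
#' @export
rankPoses <- function(model, table) {
  d <- featureData(table)
  scores <- predict(model, table)
  key <- if (model@response == "RMSD") scores else -scores
  idx <- split(seq_len(nrow(d)), factor(d$complex_id,
                                        levels = unique(d$complex_id)))
  lapply(idx, function(i) i[order(key[i], i)])
}

# ---- persistence -------------------------------------------------------

#' Save / load a fitted scoring model
#'
#' Persists a [ScoringModel-class] as a single-file bundle (an RDS archive
#' holding a format version, the parameter set as plain data and the
#' serialised backend state; xgboost boosters are stored in their own raw
#' format). A reloaded model reproduces predictions bitwise.
#'
#' @param model a [ScoringModel-class].
#' @param path file path for the bundle.
#' @return `saveScoringModel`: `path` invisibly; `loadScoringModel`: the
#'   restored [ScoringModel-class].
#' @export
saveScoringModel <- function(model, path) {
  stopifnot(is(model, "ScoringModel"))
  fit <- model@fit
  xgbRaw <- NULL
  if (model@method == "BRT") {
    xgbRaw <- xgboost::xgb.save.raw(fit)
    fit <- NULL
  }
  bundle <- list(format = "poseforge-model/1", method = model@method,
                 response = model@response, families = model@families,
                 featureNames = model@featureNames, params = model@params,
                 center = model@center, scale = model@scale,
                 seed = model@seed, nTrain = model@nTrain,
                 fit = fit, xgbRaw = xgbRaw)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname saveScoringModel
#' @export
loadScoringModel <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "poseforge-model/1"))
    stop("not a poseforge model bundle: ", path, call. = FALSE)
  fit <- b$fit
  if (b$method == "BRT") fit <- xgboost::xgb.load.raw(b$xgbRaw)
  new("ScoringModel", method = b$method, response = b$response,
      families = b$families, featureNames = b$featureNames,
      params = b$params, fit = fit, center = b$center, scale = b$scale,
      seed = b$seed, nTrain = b$nTrain)
}
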