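#' Docking-power evaluation configuration
#'
#' Grid of RMSD cutoffs C and ranking depths N over which success rates
#' are computed. `S[C]^[N]` is the percentage of complexes for which at
#' least one of the N top-ranked poses lies within C Angstrom of the
#' native pose; `S0^1` (best-ranked pose *is* the native, up to
#' `zeroTolerance`) is the most stringent statistic.
#'
#' @param cutoffs RMSD cutoffs C in Angstrom (default 0, 1, 2, 3).
#' @param depths ranking depths N (default 1, 2, 3, 5).
#' @param includeNative keep native poses (RMSD <= `zeroTolerance`) in the
#'   ranked pool (default `TRUE`).
#' @param zeroTolerance Angstrom tolerance implementing the C = 0 case
#'   robustly against floating-point noise (default 1e-6).
#' @return list of class `"evalConfig"`.
#' @export
evalConfig <- function(cutoffs = c(0, 1, 2, 3), depths = c(1, 2, 3, 5),
                       includeNative = TRUE, zeroTolerance = 1e-6) {
  stopifnot(all(cutoffs >= 0), all(depths >= 1))
  structure(list(cutoffs = sort(cutoffs), depths = sort(as.integer(depths)),
                 includeNative = includeNative,
                 zeroTolerance = zeroTolerance),
            class = "evalConfig")
}

#' Docking success rate for one cutoff/depth pair
#'
#' A complex is a hit when the minimum true RMSD among its N top-ranked
#' poses is at most C (inclusive); C = 0 means RMSD at most
#' `zeroTolerance`. The rate is `100 * hits / n_complexes`.
#'
#' @param rankedRmsd list with one element per complex: the true RMSD
#'   values of its poses in ranked order (best-scored first).
#' @param C RMSD cutoff in Angstrom.
#' @param N ranking depth.
#' @param zeroTolerance tolerance used when `C == 0`.
#' @return success rate in percent.
#' @examples
#' successRate(list(c(2.5, 0.8, 4)), C = 1, N = 1)  # 0
#' successRate(list(c(2.5, 0.8, 4)), C = 1, N = 2)  # 100
#' @export
successRate <- function(rankedRmsd, C, N, zeroTolerance = 1e-6) {
  hits <- successHits(rankedRmsd, C, N, zeroTolerance)
  100 * mean(hits)
}

successHits <- function(rankedRmsd, C, N, zeroTolerance = 1e-6) {
  if (!length(rankedRmsd))
    stop("data error: no complexes to evaluate", call. = FALSE)
  empty <- which(!lengths(rankedRmsd))
  if (length(empty))
    stop("data error: empty ranking for complex(es) ",
         paste(utils::head(names(rankedRmsd)[empty] %||% empty, 5L),
               collapse = ", "), call. = FALSE)
  thr <- if (C == 0) zeroTolerance else C
  vapply(rankedRmsd, function(r)
    min(r[seq_len(min(N, length(r)))]) <= thr, logical(1))
}

#' Evaluate a scoring model's docking power
#'
#' Ranks each complex's poses with [rankPoses()], then computes the
#' success rate over the full cutoff x depth grid of `config`. With
#' `includeNative = FALSE`, rows whose true RMSD is within
#' `zeroTolerance` are removed before ranking, measuring performance when
#' the exact native pose is absent from the candidate pool.
#'
#' @param model a [ScoringModel-class].
#' @param table a [FeatureTable-class] with true `RMSD` annotations.
#' @param config an [evalConfig()].
#' @return a [SuccessRateReport-class].
#' @export
evaluateModel <- function(model, table, config = evalConfig()) {
  d <- featureData(table)
  if (!config$includeNative) {
    keep <- d$RMSD > config$zeroTolerance
    table <- table[keep]
    d <- featureData(table)
  }
  ranks <- rankPoses(model, table)
  rankedRmsd <- lapply(ranks, function(i) d$RMSD[i])
  successReport(rankedRmsd, config)
}

# assemble a SuccessRateReport from ranked true-RMSD lists
successReport <- function(rankedRmsd, config = evalConfig()) {
  grid <- expand.grid(C = config$cutoffs, N = config$depths,
                      KEEP.OUT.ATTRS = FALSE)
  ids <- names(rankedRmsd) %||% as.character(seq_along(rankedRmsd))
  hitRows <- lapply(seq_len(nrow(grid)), function(g) {
    h <- successHits(rankedRmsd, grid$C[g], grid$N[g],
                     config$zeroTolerance)
    data.frame(complex_id = ids, C = grid$C[g], N = grid$N[g], hit = h,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  hits <- do.call(rbind, hitRows)
  grid$rate <- vapply(hitRows, function(h) 100 * mean(h$hit), numeric(1))
  new("SuccessRateReport", rates = grid, hits = hits,
      nComplexes = length(rankedRmsd))
}

#' Learning curve: docking power versus training-set size
#'
#' Retrains a scoring model on random subsamples of the training table and
#' measures the mean `S1^1` success rate on a fixed test table, averaged
#' over `repeats` random draws.
#'
#' Two sampling modes mirror the two ways an RMSD-response training set
#' can grow: `"complexes"` samples a fraction `x`% of the training
#' complexes (all their poses); `"poses"` keeps every complex but samples
#' `x` poses per complex (the native row is retained when present so BA
#' responses stay defined).
#'
#' @param train,test [FeatureTable-class] objects.
#' @param method,response,families,params,seed as in
#'   [fitScoringModel()].
#' @param sizes fractions in percent (mode `"complexes"`, default
#'   `seq(10, 100, 10)`) or poses-per-complex counts (mode `"poses"`).
#' @param mode `"complexes"` or `"poses"`.
#' @param repeats random repeats per size (default 50).
#' @param C,N the success statistic to track (default `S1^1`).
#' @return data.frame with columns size, rate (mean percent), sd, repeats.
#' @export
learningCurve <- function(train, test, method = "RF",
                          response = c("RMSD", "BA"), families = NULL,
                          params = list(), sizes = seq(10, 100, 10),
                          mode = c("complexes", "poses"), repeats = 50L,
                          C = 1, N = 1L, seed = defaultSfSeed) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  d <- featureData(train)
  complexes <- unique(d$complex_id)
  seeds <- deriveSeeds(seed, length(sizes) * repeats)
  si <- 0L
  out <- lapply(seq_along(sizes), function(s) {
    x <- sizes[s]
    rates <- vapply(seq_len(repeats), function(r) {
      si <<- si + 1L
      sub <- withSeed(seeds[si], {
        if (mode == "complexes") {
          nC <- max(1L, round(length(complexes) * x / 100))
          keep <- d$complex_id %in% sample(complexes, nC)
        } else {
          keep <- unlist(lapply(split(seq_len(nrow(d)), d$complex_id),
                                function(i) {
            nat <- i[is.finite(d$BA[i])]
            pool <- setdiff(i, nat)
            c(nat, sample(pool, min(as.integer(x), length(pool))))
          }), use.names = FALSE)
          seq_len(nrow(d)) %in% keep
        }
        keep
      })
      if (sum(sub) < 10L)
        stop("configuration error: size ", x, " yields fewer than 10 rows",
             call. = FALSE)
      m <- fitScoringModel(train[sub], method, response,
                           families = families, params = params,
                           seed = seeds[si])
      rep <- evaluateModel(m, test, evalConfig(cutoffs = C, depths = N))
      successRates(rep)$rate[1L]
    }, numeric(1))
    data.frame(size = x, rate = mean(rates), sd = stats::sd(rates),
               repeats = repeats)
  })
  do.call(rbind, out)
}

#' Feature curve: docking power versus number of features
#'
#' Samples `size` feature columns without replacement from the training
#' table's feature pool, fits the model on the subset and measures `S1^1`
#' on the test table; averaged over `repeats` random subsets per size.
#' When `size` equals the pool width the subset is the full deterministic
#' pool.
#'
#' @inheritParams learningCurve
#' @param sizes numbers of features to sample (default
#'   `seq(20, 220, 40)`, capped at the pool width).
#' @param repeats random subsets per size (default 100).
#' @return data.frame with columns size, rate, sd, repeats.
#' @export
featureCurve <- function(train, test, method = "MLR",
                         response = c("RMSD", "BA"), params = list(),
                         sizes = seq(20, 220, 40), repeats = 100L,
                         C = 1, N = 1L, seed = defaultSfSeed) {
  response <- match.arg(response)
  pool <- names(featureFamilies(train))
  if (any(sizes > length(pool)))
    stop("configuration error: requested size exceeds the ",
         length(pool), "-feature pool", call. = FALSE)
  seeds <- deriveSeeds(seed, length(sizes) * repeats)
  si <- 0L
  out <- lapply(sizes, function(x) {
    reps <- if (x == length(pool)) 1L else repeats
    rates <- vapply(seq_len(reps), function(r) {
      si <<- si + 1L
      cols <- if (x == length(pool)) pool
              else withSeed(seeds[si], sample(pool, x))
      m <- fitScoringModel(train, method, response, columns = cols,
                           params = params, seed = seeds[si])
      rep <- evaluateModel(m, test, evalConfig(cutoffs = C, depths = N))
      successRates(rep)$rate[1L]
    }, numeric(1))
    data.frame(size = x, rate = mean(rates),
               sd = if (reps > 1L) stats::sd(rates) else 0,
               repeats = reps)
  })
  do.call(rbind, out)
}
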