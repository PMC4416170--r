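#' @name simsplit
#' @title Similarity-constrained train/test splitting
#' @description
#' Implements the novel-target evaluation protocol: a test set of
#' complexes is drawn at random, and the training set is drawn from the
#' remaining complexes whose binding-site similarity to *every* test
#' complex is at most a cutoff S. If too few complexes qualify, a fresh
#' test set is drawn and the process repeats. Similarities are consumed as
#' a precomputed symmetric percentage matrix, which keeps the module
#' independent of any alignment tool; [sequenceIdentity()] provides a
#' deterministic built-in surrogate for building such matrices from
#' binding-site sequences.
NULL

#' Validate a pairwise similarity matrix
#'
#' @param sim square numeric matrix of pairwise similarities in percent,
#'   with complex ids as dimnames, diagonal 100 and symmetric to 1e-9.
#' @return the matrix, invisibly, after validation.
#' @export
validateSimilarityMatrix <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("similarity matrix must be square", call. = FALSE)
  if (is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim)))
    stop("similarity matrix needs identical row/column id names",
         call. = FALSE)
  if (any(sim < 0 | sim > 100))
    stop("similarities must lie in [0, 100]", call. = FALSE)
  if (max(abs(sim - t(sim))) > 1e-9)
    stop("similarity matrix must be symmetric (tolerance 1e-9)",
         call. = FALSE)
  if (any(abs(diag(sim) - 100) > 1e-9))
    stop("diagonal must equal 100", call. = FALSE)
  invisible(sim)
}

#' Read a similarity matrix from CSV
#'
#' Square CSV with header ids and matching first column of ids.
#'
#' @param path CSV path.
#' @return validated numeric matrix.
#' @export
readSimilarityMatrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(d)
  validateSimilarityMatrix(m)
  m
}

#' Draw one similarity-constrained train/test split
#'
#' Samples `nTest` ids without replacement as the test set, then samples
#' `nTrain` ids from those remaining whose similarity to every test id is
#' at most `S`. If fewer than `nTrain` qualify the test set is redrawn,
#' up to `maxRetries` times; exhaustion raises an infeasibility error
#' reporting the best achievable training size.
#'
#' @param sim validated similarity matrix (percent).
#' @param S similarity cutoff in percent (0 < S <= 100).
#' @param nTrain training-set size T.
#' @param nTest test-set size (default 100).
#' @param maxRetries maximum test-set redraws (default 50).
#' @param seed integer seed.
#' @return list with `train`, `test` (character id vectors) and
#'   `attempts`.
#' @export
constrainedSplit <- function(sim, S, nTrain, nTest = 100L,
                             maxRetries = 50L, seed = defaultSfSeed) {
  validateSimilarityMatrix(sim)
  stopifnot(S > 0, S <= 100, nTrain >= 1L, nTest >= 1L)
  ids <- rownames(sim)
  if (length(ids) < nTest + nTrain)
    stop("infeasibility error: only ", length(ids),
         " ids for nTest + nTrain = ", nTest + nTrain, call. = FALSE)
  seeds <- deriveSeeds(seed, maxRetries)
  bestT <- 0L
  for (attempt in seq_len(maxRetries)) {
    res <- withSeed(seeds[attempt], {
      test <- sample(ids, nTest)
      rest <- setdiff(ids, test)
      maxSim <- apply(sim[rest, test, drop = FALSE], 1L, max)
      pool <- rest[maxSim <= S]
      if (length(pool) >= nTrain)
        list(train = sample(pool, nTrain), test = test)
      else length(pool)
    })
    if (is.list(res)) {
      res$attempts <- attempt
      return(res)
    }
    bestT <- max(bestT, res)
  }
  stop("infeasibility error: no test set admitted ", nTrain,
       " training complexes at S = ", S, " within ", maxRetries,
       " retries (best achievable T = ", bestT, ")", call. = FALSE)
}

#' Draw repeated independent constrained splits
#'
#' `nRepeats` independent splits with per-repeat seeds derived
#' deterministically from `seed`; every returned pair satisfies the
#' constraint (see [verifySplit()]).
#'
#' @inheritParams constrainedSplit
#' @param nRepeats number of splits (default 100).
#' @return list of split lists as returned by [constrainedSplit()].
#' @export
repeatSplits <- function(sim, S, nTrain, nTest = 100L, nRepeats = 100L,
                         maxRetries = 50L, seed = defaultSfSeed) {
  seeds <- deriveSeeds(seed, nRepeats)
  lapply(seq_len(nRepeats), function(i) {
    tryCatch(constrainedSplit(sim, S, nTrain, nTest, maxRetries, seeds[i]),
             error = function(e)
               stop("repeat ", i, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Verify a similarity-constrained split
#'
#' @param split list with `train` and `test` id vectors.
#' @param sim similarity matrix.
#' @param S cutoff in percent.
#' @return `TRUE` if the sides are disjoint and every train--test
#'   similarity is at most `S`; otherwise `FALSE`.
#' @export
verifySplit <- function(split, sim, S) {
  if (length(intersect(split$train, split$test))) return(FALSE)
  all(sim[split$train, split$test, drop = FALSE] <= S)
}

#' Global-alignment sequence identity (percent)
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1 per position; identity is the number of matched
#' positions divided by the alignment length, times 100. This is a
#' deterministic built-in surrogate for externally computed binding-site
#' similarities (e.g. BLAST); it is not claimed to be equivalent to them.
#'
#' @param a,b amino-acid sequences (single strings over the 20-letter
#'   alphabet).
#' @return identity in percent.
#' @examples
#' sequenceIdentity("ACDEFG", "ACDEYG")  # 5/6 of positions match
#' @export
sequenceIdentity <- function(a, b) {
  aa <- Biostrings::AA_STANDARD
  for (s in c(a, b)) {
    bad <- setdiff(strsplit(toupper(s), "")[[1L]], aa)
    if (length(bad))
      stop("alphabet error: invalid residue letter(s) ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  subst <- matrix(0, length(aa), length(aa), dimnames = list(aa, aa))
  diag(subst) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = subst,
    gapOpening = 0, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}
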