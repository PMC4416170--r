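# internal helpers shared across modules

# canonical capitalisation of element symbols ("CL" -> "Cl", "c" -> "C")
normalizeElement <- function(x) {
  x <- trimws(as.character(x))
  bad <- !nzchar(x)
  if (any(bad)) stop("empty element symbol at atom ", which(bad)[1L])
  paste0(toupper(substr(x, 1L, 1L)),
         tolower(substr(x, 2L, nchar(x))))
}

# evaluate expr with a private RNG state: the caller's .Random.seed is
# untouched and results depend only on `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds (< 2^31) from one parent seed
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# squared-distance matrix between two coordinate sets (rows = atoms)
crossDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
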