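#' @name mars
#' @title In-house multivariate adaptive regression splines
#' @description
#' A self-contained MARS regressor in the Friedman style: a forward pass
#' greedily adds reflected pairs of hinge basis functions
#' `max(0, x_v - t)` / `max(0, t - x_v)` (optionally multiplied into an
#' existing basis term up to the requested interaction `degree`), then a
#' backward pass prunes terms by generalised cross-validation,
#' `GCV = RSS/n / (1 - C(M)/n)^2` with effective parameter count
#' `C(M) = M + penalty * (M - 1) / 2` for M retained terms (intercept
#' included). The final number of terms is selected automatically by the
#' GCV minimum; only `degree` and `penalty` are tuned externally.
#' Candidate knots are placed at up to `maxKnots` quantiles of each
#' predictor.
NULL

# build the model-matrix column of one basis term (list of components,
# each a list(var, knot, sign)); an empty component list is the intercept
marsBasisColumn <- function(term, x) {
  col <- rep(1, nrow(x))
  for (cmp in term) {
    h <- cmp$sign * (x[, cmp$var] - cmp$knot)
    col <- col * pmax(h, 0)
  }
  col
}

marsBasisMatrix <- function(terms, x) {
  vapply(terms, marsBasisColumn, numeric(nrow(x)), x = x)
}

# forward + backward MARS fit; returns list(terms, coef, gcv, trace)
marsFit <- function(x, y, degree = 1L, penalty = 3, maxTerms = 21L,
                    maxKnots = 20L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(n == length(y), n > 2L)
  maxTerms <- min(maxTerms, max(3L, n - 2L))

  # candidate knots: interior quantiles of each predictor's unique values
  knotList <- lapply(seq_len(p), function(v) {
    u <- sort(unique(x[, v]))
    if (length(u) < 2L) return(numeric())
    u <- u[-length(u)]  # hinge at the maximum is identically zero one side
    if (length(u) > maxKnots)
      u <- unique(stats::quantile(u, probs = seq(0, 1,
                                                 length.out = maxKnots),
                                  names = FALSE, type = 1L))
    u
  })
  varOf <- rep(seq_len(p), lengths(knotList))
  knotOf <- unlist(knotList)
  nCand <- length(varOf)
  if (!nCand) stop("data error: no usable predictor variation", call. = FALSE)
  # raw hinge columns for every (variable, knot) candidate
  H1 <- matrix(0, n, nCand)  # max(0, x - t)
  H2 <- matrix(0, n, nCand)  # max(0, t - x)
  for (j in seq_len(nCand)) {
    h <- x[, varOf[j]] - knotOf[j]
    H1[, j] <- pmax(h, 0)
    H2[, j] <- pmax(-h, 0)
  }

  terms <- list(list())                       # start from the intercept
  B <- matrix(1, n, 1L)
  Q <- matrix(1 / sqrt(n), n, 1L)             # orthonormal basis of span(B)
  resid <- y - mean(y)
  rss <- sum(resid^2)
  tol <- max(rss, 1e-8) * 1e-10

  while (length(terms) + 2L <= maxTerms && rss > tol) {
    best <- list(gain = 0)
    for (m in seq_along(terms)) {
      parent <- terms[[m]]
      if (length(parent) >= degree) next
      parentVars <- vapply(parent, `[[`, integer(1), "var")
      usable <- !(varOf %in% parentVars)
      if (!any(usable)) next
      pc <- B[, m]
      C1 <- H1[, usable, drop = FALSE] * pc
      C2 <- H2[, usable, drop = FALSE] * pc
      # orthogonalise candidates against the current fit span
      C1p <- C1 - Q %*% crossprod(Q, C1)
      C2p <- C2 - Q %*% crossprod(Q, C2)
      n1 <- colSums(C1p^2); n2 <- colSums(C2p^2)
      a1 <- colSums(C1p * resid); a2 <- colSums(C2p * resid)
      d12 <- colSums(C1p * C2p)
      g1 <- ifelse(n1 > 1e-10, a1^2 / n1, 0)
      # second column orthogonalised against the first of its pair
      n2b <- n2 - ifelse(n1 > 1e-10, d12^2 / n1, 0)
      a2b <- a2 - ifelse(n1 > 1e-10, d12 * a1 / n1, 0)
      g2 <- ifelse(n2b > 1e-10, a2b^2 / n2b, 0)
      gain <- g1 + g2
      j <- which.max(gain)
      if (gain[j] > best$gain)
        best <- list(gain = gain[j], parent = m,
                     cand = which(usable)[j],
                     c1 = C1[, j], c2 = C2[, j])
    }
    if (best$gain <= max(tol, 1e-12)) break
    v <- varOf[best$cand]; t <- knotOf[best$cand]
    parent <- terms[[best$parent]]
    terms <- c(terms,
               list(c(parent, list(list(var = v, knot = t, sign = 1))),
                    c(parent, list(list(var = v, knot = t, sign = -1)))))
    for (col in list(best$c1, best$c2)) {
      B <- cbind(B, col)
      q <- col - Q %*% crossprod(Q, col)
      nq <- sqrt(sum(q^2))
      if (nq > 1e-8) Q <- cbind(Q, q / nq)
    }
    resid <- drop(y - Q %*% crossprod(Q, y))
    rss <- sum(resid^2)
  }

  # backward pruning by GCV
  gcvOf <- function(rssVal, M) {
    cM <- M + penalty * (M - 1) / 2
    if (cM >= n) return(Inf)
    (rssVal / n) / (1 - cM / n)^2
  }
  active <- seq_along(terms)
  fit <- stats::lm.fit(B[, active, drop = FALSE], y)
  bestSet <- active
  bestGcv <- gcvOf(sum(fit$residuals^2), length(active))
  current <- active
  while (length(current) > 1L) {
    rssDrop <- vapply(current[-1L], function(drop) {
      keep <- setdiff(current, drop)
      sum(stats::lm.fit(B[, keep, drop = FALSE], y)$residuals^2)
    }, numeric(1))
    worst <- current[-1L][which.min(rssDrop)]
    current <- setdiff(current, worst)
    g <- gcvOf(min(rssDrop), length(current))
    if (g < bestGcv) {
      bestGcv <- g
      bestSet <- current
    }
  }
  coefs <- stats::lm.fit(B[, bestSet, drop = FALSE], y)$coefficients
  coefs[is.na(coefs)] <- 0
  list(terms = terms[bestSet], coef = unname(coefs), gcv = bestGcv,
       penalty = penalty, degree = degree, p = p)
}

marsPredict <- function(fit, x) {
  x <- as.matrix(x)
  drop(marsBasisMatrix(fit$terms, x) %*% fit$coef)
}

#' Inspect the terms of a fitted MARS scoring model
#'
#' @param model a [ScoringModel-class] with `method = "MARS"`.
#' @return data.frame with one row per basis term: its interaction degree
#'   and a readable description.
#' @export
marsTerms <- function(model) {
  stopifnot(is(model, "ScoringModel"), model@method == "MARS")
  fit <- model@fit
  data.frame(
    term = vapply(fit$terms, function(tm) {
      if (!length(tm)) return("(intercept)")
      paste(vapply(tm, function(cmp) {
        nm <- model@featureNames[cmp$var]
        if (cmp$sign > 0) sprintf("h(%s - %.4g)", nm, cmp$knot)
        else sprintf("h(%.4g - %s)", cmp$knot, nm)
      }, character(1)), collapse = " * ")
    }, character(1)),
    degree = vapply(fit$terms, length, integer(1)),
    coef = fit$coef,
    stringsAsFactors = FALSE)
}
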