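#' @name geomfeat
#' @title Geometrical atom-pair count descriptors
#' @description
#' The geometrical descriptor family (family R) counts occurrences of
#' protein--ligand heavy-atom element pairs within a distance cutoff.
#' Protein atoms are typed over \{C, N, O, S\} and ligand atoms over
#' \{C, N, O, F, P, S, Cl, Br, I\}, giving a fixed 4 x 9 = 36-key schema.
#' Atoms of other elements are retained in structures but contribute
#' nothing. The binned variant splits the counts over contiguous distance
#' intervals, yielding 36 x 5 = 180 features under the default
#' (0,4], (4,8], ..., (16,20] Angstrom scheme.
NULL

proteinElements <- c("C", "N", "O", "S")
ligandElements  <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# fixed key order: protein element major, then ligand element, then
# (for the binned variant) distance bin ascending
pairKeys <- function(binLabels = NULL) {
  base <- as.vector(t(outer(proteinElements, ligandElements, paste, sep = ".")))
  if (is.null(binLabels)) return(base)
  as.vector(t(outer(base, binLabels, paste, sep = ".")))
}

#' Protein-ligand atom-pair counts within a cutoff
#'
#' Counts, for each of the 36 (protein element, ligand element) pairs, the
#' number of heavy-atom pairs at Euclidean distance d with 0 < d <= cutoff.
#' The upper bound is inclusive.
#'
#' @param receptor,ligand non-empty [MoleculeStructure-class] objects.
#' @param cutoff distance cutoff in Angstrom (default 12).
#' @return named integer vector of length 36; names are
#'   `"<protein>.<ligand>"` in fixed schema order.
#' @examples
#' r <- MoleculeStructure("r", "N", rbind(c(0, 0, 0)), role = "receptor")
#' l <- MoleculeStructure("l", "C", rbind(c(5, 0, 0)))
#' pairCounts(r, l)[["N.C"]]
#' @export
pairCounts <- function(receptor, ligand, cutoff = 12) {
  binnedPairCounts(receptor, ligand, binEdges = c(0, cutoff),
                   binLabels = FALSE)
}

#' Distance-binned protein-ligand atom-pair counts
#'
#' Extends [pairCounts()] by resolving each pair count over contiguous
#' distance intervals (lo, hi] (half-open at the left). The default
#' five-bin 4 Angstrom scheme produces 36 x 5 = 180 features.
#'
#' @inheritParams pairCounts
#' @param binEdges strictly increasing numeric vector of interval edges
#'   starting at 0 (default `c(0, 4, 8, 12, 16, 20)`).
#' @param binLabels internal; set `FALSE` to collapse labels for the
#'   single-bin case.
#' @return named integer vector of length `36 * nbins`; keys are
#'   `"<protein>.<ligand>.b<k>"` with bins ascending within each pair.
#' @export
binnedPairCounts <- function(receptor, ligand,
                             binEdges = c(0, 4, 8, 12, 16, 20),
                             binLabels = TRUE) {
  stopifnot(is(receptor, "MoleculeStructure"), is(ligand, "MoleculeStructure"))
  if (!is.numeric(binEdges) || length(binEdges) < 2L ||
      binEdges[1L] != 0 || any(diff(binEdges) <= 0))
    stop("configuration error: 'binEdges' must be strictly increasing and start at 0",
         call. = FALSE)
  nb <- length(binEdges) - 1L
  labels <- if (isTRUE(binLabels)) paste0("b", seq_len(nb)) else NULL
  keys <- pairKeys(labels)
  counts <- integer(length(keys))
  names(counts) <- keys

  pe <- atomElements(receptor)
  le <- atomElements(ligand)
  pKeep <- pe %in% proteinElements
  lKeep <- le %in% ligandElements
  if (!any(pKeep) || !any(lKeep)) return(counts)

  d <- crossDist(atomCoords(receptor)[pKeep, , drop = FALSE],
                 atomCoords(ligand)[lKeep, , drop = FALSE])
  # bin b: d in (edges[b], edges[b+1]]; d == 0 (coincident atoms) excluded
  bin <- matrix(findInterval(d, binEdges, left.open = TRUE), nrow = nrow(d))
  bin[d <= 0 | bin < 1L | bin > nb] <- NA_integer_

  pi <- match(pe[pKeep], proteinElements)
  li <- match(le[lKeep], ligandElements)
  pairIdx <- (rep(pi, times = length(li)) - 1L) * length(ligandElements) +
             rep(li, each = length(pi))
  ok <- !is.na(bin)
  if (any(ok)) {
    if (is.null(labels)) {
      tab <- tabulate(pairIdx[ok], nbins = length(keys))
    } else {
      slot <- (pairIdx[ok] - 1L) * nb + bin[ok]
      tab <- tabulate(slot, nbins = length(keys))
    }
    counts[] <- tab
  }
  counts
}

#' Enumerate feature-family combinations
#'
#' All non-empty subsets of the available descriptor families, in
#' deterministic order: by subset size, then lexicographically in the
#' canonical family order X, A, R, G. Four families give the 15
#' combinations X, A, R, G, XA, XR, XG, AR, AG, RG, XAR, XAG, XRG, ARG,
#' XARG.
#'
#' @param available non-empty subset of `c("X", "A", "R", "G")`.
#' @return character vector of family signatures (e.g. `"XR"`).
#' @examples
#' enumerateFamilyCombinations()           # 15 signatures
#' enumerateFamilyCombinations(c("X", "G"))  # "X" "G" "XG"
#' @export
enumerateFamilyCombinations <- function(available = c("X", "A", "R", "G")) {
  canon <- c("X", "A", "R", "G")
  available <- unique(available)
  if (!length(available) || !all(available %in% canon))
    stop("'available' must be a non-empty subset of {X, A, R, G}",
         call. = FALSE)
  fams <- canon[canon %in% available]
  out <- character()
  for (k in seq_along(fams)) {
    combos <- utils::combn(fams, k, paste, collapse = "")
    out <- c(out, combos)
  }
  out
}

# nominal column widths of the externally computed descriptor families
familyWidths <- c(X = 6L, A = 30L, G = 14L)

#' Load an externally computed descriptor table
#'
#' Reads a CSV/TSV table of descriptors produced outside this package
#' (family X: empirical scoring-tool terms, 6 columns; A: physicochemical
#' terms, 30 columns; G: docking-tool descriptors, 14 columns), keyed by
#' `complex_id` and `pose_id`. A column count differing from the family's
#' nominal width raises a warning, not an error.
#'
#' @param path CSV or TSV file with a header row containing `complex_id`
#'   and `pose_id`.
#' @param family one of `"X"`, `"A"`, `"G"`.
#' @return data.frame fragment with attribute `"family"`; feature columns
#'   are renamed `<family>.<name>` unless already prefixed.
#' @export
loadExternalFeatures <- function(path, family = c("X", "A", "G")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("complex_id", "pose_id") %in% names(d)))
    stop("schema error: '", path,
         "' lacks the key columns complex_id, pose_id", call. = FALSE)
  key <- paste(d$complex_id, d$pose_id, sep = "/")
  if (anyDuplicated(key))
    stop("schema error: duplicated (complex_id, pose_id) key '",
         key[duplicated(key)][1L], "' in '", path, "'", call. = FALSE)
  featCols <- setdiff(names(d), c("complex_id", "pose_id"))
  if (length(featCols) != familyWidths[[family]])
    warning(sprintf(
      "family %s table has %d feature columns; nominal width is %d",
      family, length(featCols), familyWidths[[family]]), call. = FALSE)
  pref <- paste0(family, ".")
  renamed <- ifelse(startsWith(featCols, pref), featCols,
                    paste0(pref, featCols))
  names(d)[match(featCols, names(d))] <- renamed
  attr(d, "family") <- family
  d
}

#' Build a feature table from pose sets and external fragments
#'
#' Produces one row per (complex, pose) — native poses included, with
#' RMSD = 0 — carrying the requested descriptor families. Geometrical (R)
#' features are computed from the structures; X, A and G features are
#' joined from externally loaded fragments ([loadExternalFeatures()]).
#' Binding affinity, when supplied, is attached to native rows only:
#' affinities are experimental quantities defined for the native pose, not
#' for decoys.
#'
#' @param poseSets list of [PoseSet-class] objects.
#' @param families character vector of requested families (subset of
#'   X, A, R, G) or a signature string such as `"XARG"`.
#' @param external named list of data.frame fragments (names = family
#'   letters) for the non-geometrical families.
#' @param ba optional named numeric of per-complex binding affinities
#'   (names = complex ids).
#' @param scheme `"r36"` (36 counts at `cutoff`) or `"r180"` (binned).
#' @param cutoff,binEdges geometry parameters for the R family.
#' @param nativePoseId pose id assigned to native rows (default
#'   `"native"`).
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(poseSets, families = "R", external = list(),
                              ba = NULL, scheme = c("r36", "r180"),
                              cutoff = 12, binEdges = c(0, 4, 8, 12, 16, 20),
                              nativePoseId = "native") {
  scheme <- match.arg(scheme)
  if (length(families) == 1L && nchar(families) > 1L)
    families <- strsplit(families, "")[[1L]]
  if (!length(families) || !all(families %in% c("X", "A", "R", "G")))
    stop("'families' must be a non-empty subset of {X, A, R, G}",
         call. = FALSE)
  families <- c("X", "A", "R", "G")[c("X", "A", "R", "G") %in% families]
  if (is(poseSets, "PoseSet")) poseSets <- list(poseSets)

  rows <- lapply(poseSets, function(ps) {
    poses <- c(list(nativePose(ps)), candidatePoses(ps))
    ids <- c(nativePoseId,
             vapply(candidatePoses(ps), moleculeId, character(1)))
    if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
    rmsd <- c(0, rmsdToNative(ps) %||%
                vapply(candidatePoses(ps), poseRmsd, numeric(1),
                       nativePose(ps)))
    out <- data.frame(complex_id = complexId(ps), pose_id = ids,
                      RMSD = rmsd, stringsAsFactors = FALSE)
    if ("R" %in% families) {
      feats <- t(vapply(poses, function(p) {
        if (scheme == "r36") pairCounts(receptor(ps), p, cutoff = cutoff)
        else binnedPairCounts(receptor(ps), p, binEdges = binEdges)
      }, numeric(if (scheme == "r36") 36L
                 else 36L * (length(binEdges) - 1L))))
      colnames(feats) <- paste0("R.", colnames(feats))
      out <- cbind(out, as.data.frame(feats))
    }
    out
  })
  d <- do.call(rbind, rows)

  famMap <- character()
  if ("R" %in% families) {
    rCols <- grep("^R\\.", names(d), value = TRUE)
    famMap[rCols] <- "R"
  }
  for (fam in intersect(families, c("X", "A", "G"))) {
    frag <- external[[fam]]
    if (is.null(frag))
      stop("coverage error: family ", fam,
           " requested but no external fragment supplied", call. = FALSE)
    fragKey <- paste(frag$complex_id, frag$pose_id, sep = "/")
    rowKey <- paste(d$complex_id, d$pose_id, sep = "/")
    idx <- match(rowKey, fragKey)
    if (anyNA(idx))
      stop("coverage error: family ", fam, " fragment lacks key(s) ",
           paste(utils::head(rowKey[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    featCols <- setdiff(names(frag), c("complex_id", "pose_id"))
    vals <- frag[idx, featCols, drop = FALSE]
    if (any(!vapply(vals, is.numeric, logical(1))) ||
        any(vapply(vals, function(v) any(!is.finite(v)), logical(1))))
      stop("data error: non-finite or non-numeric values in family ", fam,
           " fragment (no imputation is performed)", call. = FALSE)
    d <- cbind(d, vals)
    famMap[featCols] <- fam
  }

  d$BA <- NA_real_
  if (!is.null(ba)) {
    isNative <- d$pose_id == nativePoseId
    d$BA[isNative] <- as.numeric(ba[d$complex_id[isNative]])
  }
  # canonical column order: keys, features (X, A, R, G), responses
  canonCols <- names(famMap)[order(match(famMap, c("X", "A", "R", "G")))]
  famMap <- famMap[canonCols]
  d <- d[, c("complex_id", "pose_id", canonCols, "BA", "RMSD")]
  rownames(d) <- NULL
  new("FeatureTable", data = d, familyMap = famMap)
}

#' Assemble a FeatureTable from a prepared data.frame
#'
#' Lower-level constructor used when descriptors come from disk or from the
#' synthetic-data generator rather than from structures.
#'
#' @param data data.frame with `complex_id`, `pose_id`, feature columns and
#'   (optionally) `BA` and `RMSD`.
#' @param familyMap named character vector mapping feature columns to
#'   families.
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(data, familyMap) {
  canonCols <- names(familyMap)[order(match(familyMap,
                                            c("X", "A", "R", "G")))]
  famMap <- familyMap[canonCols]
  keep <- c("complex_id", "pose_id", canonCols,
            intersect(c("BA", "RMSD"), names(data)))
  new("FeatureTable", data = data[, keep, drop = FALSE], familyMap = famMap)
}

# feature sub-matrix for a family selection, in canonical order
featureMatrix <- function(ft, families = NULL, columns = NULL) {
  if (is.null(columns)) {
    fm <- featureFamilies(ft)
    if (is.null(families)) columns <- names(fm)
    else {
      if (length(families) == 1L && nchar(families) > 1L)
        families <- strsplit(families, "")[[1L]]
      miss <- setdiff(families, fm)
      if (length(miss))
        stop("coverage error: family(ies) ", paste(miss, collapse = ", "),
             " absent from the table", call. = FALSE)
      columns <- names(fm)[fm %in% families]
    }
  }
  m <- as.matrix(featureData(ft)[, columns, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Subset a FeatureTable by row
#'
#' @param x a [FeatureTable-class].
#' @param i row index.
#' @param j,drop,... ignored (rows only).
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  d <- x@data[i, , drop = FALSE]
  rownames(d) <- NULL
  new("FeatureTable", data = d, familyMap = x@familyMap)
})
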