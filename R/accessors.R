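#' @rdname MoleculeStructure-class
setMethod("moleculeId", "MoleculeStructure", function(x) x@moleculeId)

#' @rdname MoleculeStructure-class
setMethod("atomElements", "MoleculeStructure", function(x) x@elements)

#' @rdname MoleculeStructure-class
setMethod("atomCoords", "MoleculeStructure", function(x) x@coords)

#' @rdname MoleculeStructure-class
setMethod("nAtoms", "MoleculeStructure", function(x) length(x@elements))

setMethod("show", "MoleculeStructure", function(object) {
  cat(sprintf("MoleculeStructure '%s' (%s): %d heavy atoms [%s]\n",
              object@moleculeId, object@role, nAtoms(object),
              paste(utils::head(sort(unique(object@elements)), 8L),
                    collapse = " ")))
})

#' @rdname PoseSet-class
setMethod("complexId", "PoseSet", function(x) x@complexId)

#' @rdname PoseSet-class
setMethod("receptor", "PoseSet", function(x) x@receptor)

#' @rdname PoseSet-class
setMethod("nativePose", "PoseSet", function(x) x@native)

#' @rdname PoseSet-class
setMethod("candidatePoses", "PoseSet", function(x) x@candidates)

#' @rdname PoseSet-class
setMethod("poseEnergies", "PoseSet", function(x) {
  if (length(x@energies)) x@energies else NULL
})

#' @rdname PoseSet-class
setMethod("rmsdToNative", "PoseSet", function(x) {
  if (length(x@rmsdToNative)) x@rmsdToNative else NULL
})

setMethod("show", "PoseSet", function(object) {
  cat(sprintf("PoseSet '%s': receptor %d atoms, ligand %d atoms, %d candidate pose(s)\n",
              object@complexId, nAtoms(object@receptor),
              nAtoms(object@native), length(object@candidates)))
  if (length(object@rmsdToNative))
    cat(sprintf("  RMSD to native: %.2f - %.2f A\n",
                min(object@rmsdToNative), max(object@rmsdToNative)))
})

#' @rdname FeatureTable-class
setMethod("featureData", "FeatureTable", function(x) x@data)

#' @rdname FeatureTable-class
setMethod("featureFamilies", "FeatureTable", function(x) x@familyMap)

setMethod("dim", "FeatureTable", function(x) dim(x@data))

setMethod("show", "FeatureTable", function(object) {
  fam <- table(factor(object@familyMap, levels = c("X", "A", "R", "G")))
  cat(sprintf("FeatureTable: %d rows (%d complexes), %d feature columns (%s)\n",
              nrow(object@data), length(unique(object@data$complex_id)),
              length(object@familyMap),
              paste(sprintf("%s=%d", names(fam), fam), collapse = ", ")))
  cat(sprintf("  responses: RMSD %s, BA on %d row(s)\n",
              if ("RMSD" %in% names(object@data)) "present" else "absent",
              if ("BA" %in% names(object@data))
                sum(!is.na(object@data$BA)) else 0L))
})

#' @rdname DecoySet-class
setMethod("complexId", "DecoySet", function(x) x@complexId)

#' @rdname DecoySet-class
setMethod("decoyManifest", "DecoySet", function(x) x@manifest)

#' @rdname DecoySet-class
setMethod("representativePoses", "DecoySet", function(x) x@poses)

setMethod("show", "DecoySet", function(object) {
  sel <- object@manifest[object@manifest$selected, , drop = FALSE]
  cat(sprintf("DecoySet '%s': %d candidates -> %d representatives in %d bin(s)\n",
              object@complexId, nrow(object@manifest), nrow(sel),
              length(unique(sel$bin))))
})

setMethod("show", "ScoringModel", function(object) {
  cat(sprintf("ScoringModel %s::%s (response = %s)\n",
              object@method, paste(object@families, collapse = ""),
              object@response))
  cat(sprintf("  %d features, %d training rows, seed %d\n",
              length(object@featureNames), object@nTrain, object@seed))
  if (length(object@params)) {
    p <- vapply(object@params, function(v) paste(format(v), collapse = ","),
                character(1))
    cat(sprintf("  params: %s\n",
                paste(sprintf("%s=%s", names(p), p), collapse = ", ")))
  }
})

#' @rdname SuccessRateReport-class
setMethod("successRates", "SuccessRateReport", function(x) x@rates)

#' Per-complex hit indicators as a matrix
#'
#' @return logical matrix, complexes in rows, one column per (C, N) grid
#'   cell named `S<C>^<N>`.
#' @rdname SuccessRateReport-class
setMethod("hitMatrix", "SuccessRateReport", function(x) {
  h <- x@hits
  cn <- sprintf("S%g^%d", h$C, h$N)
  ids <- unique(h$complex_id)
  cols <- unique(cn)
  m <- matrix(NA, length(ids), length(cols), dimnames = list(ids, cols))
  m[cbind(match(h$complex_id, ids), match(cn, cols))] <- h$hit
  m
})

setMethod("show", "SuccessRateReport", function(object) {
  cat(sprintf("SuccessRateReport over %d complexes\n", object@nComplexes))
  w <- stats::reshape(object@rates, idvar = "C", timevar = "N",
                      direction = "wide")
  names(w) <- sub("^rate\\.", "N=", names(w))
  print(w, row.names = FALSE)
})
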