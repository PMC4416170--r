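#' @import methods
NULL

#' MoleculeStructure: an element-typed heavy-atom coordinate set
#'
#' Container for a single rigid structure (a receptor or one ligand pose):
#' an ordered vector of chemical element symbols paired with an n x 3
#' coordinate matrix in Angstroms. Atom order is significant — it defines
#' the pairing used by [poseRmsd()] — so all poses of one ligand must share
#' the same atom ordering.
#'
#' @slot moleculeId single character identifier.
#' @slot elements character vector of uppercase element symbols, one per atom.
#' @slot coords numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @slot role either `"receptor"` or `"ligand"`.
#'
#' @seealso [MoleculeStructure()], [readReceptor()], [readPoses()]
#' @exportClass MoleculeStructure
setClass("MoleculeStructure",
  representation(
    moleculeId = "character",
    elements   = "character",
    coords     = "matrix",
    role       = "character"
  ),
  prototype(role = "ligand")
)

setValidity("MoleculeStructure", function(object) {
  msg <- character()
  if (length(object@moleculeId) != 1L || !nzchar(object@moleculeId))
    msg <- c(msg, "'moleculeId' must be a single non-empty string")
  n <- length(object@elements)
  if (n < 1L)
    msg <- c(msg, "structure must contain at least one atom")
  if (any(!nzchar(object@elements)))
    msg <- c(msg, "element symbols must be non-empty")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "'coords' must be a numeric matrix with 3 columns")
  else {
    if (nrow(object@coords) != n)
      msg <- c(msg, "number of coordinate rows must equal number of elements")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (!object@role %in% c("receptor", "ligand"))
    msg <- c(msg, "'role' must be 'receptor' or 'ligand'")
  if (length(msg)) msg else TRUE
})

#' Construct a MoleculeStructure
#'
#' @param moleculeId identifier string.
#' @param elements character vector of element symbols (case-normalised to
#'   the conventional capitalisation, e.g. `"CL"` becomes `"Cl"`).
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param role `"receptor"` or `"ligand"`.
#' @return a [MoleculeStructure-class] object.
#' @examples
#' m <- MoleculeStructure("lig", c("C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
#' nAtoms(m)
#' @export
MoleculeStructure <- function(moleculeId, elements, coords,
                              role = c("ligand", "receptor")) {
  role <- match.arg(role)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("MoleculeStructure",
      moleculeId = as.character(moleculeId),
      elements = normalizeElement(elements),
      coords = coords, role = role)
}

#' PoseSet: one complex's native pose plus candidate poses
#'
#' Bundles a receptor, the native ligand pose and an ordered list of
#' candidate poses for one protein--ligand complex, together with optional
#' per-candidate energies and the RMSD of each candidate to the native pose.
#'
#' @slot complexId single character identifier.
#' @slot receptor,native [MoleculeStructure-class] objects.
#' @slot candidates list of [MoleculeStructure-class], all atom-compatible
#'   with the native pose.
#' @slot energies numeric per-candidate energy (arbitrary units, lower is
#'   more favourable), or length 0 when absent.
#' @slot rmsdToNative numeric per-candidate RMSD in Angstrom, or length 0.
#' @exportClass PoseSet
setClass("PoseSet",
  representation(
    complexId    = "character",
    receptor     = "MoleculeStructure",
    native       = "MoleculeStructure",
    candidates   = "list",
    energies     = "numeric",
    rmsdToNative = "numeric"
  )
)

setValidity("PoseSet", function(object) {
  msg <- character()
  if (length(object@complexId) != 1L || !nzchar(object@complexId))
    msg <- c(msg, "'complexId' must be a single non-empty string")
  nat <- object@native
  for (i in seq_along(object@candidates)) {
    cand <- object@candidates[[i]]
    if (!is(cand, "MoleculeStructure")) {
      msg <- c(msg, sprintf("candidate %d is not a MoleculeStructure", i))
      next
    }
    if (length(cand@elements) != length(nat@elements))
      msg <- c(msg, sprintf(
        "candidate %d has %d atoms but the native pose has %d",
        i, length(cand@elements), length(nat@elements)))
  }
  nc <- length(object@candidates)
  if (length(object@energies) && length(object@energies) != nc)
    msg <- c(msg, "'energies' must have one value per candidate")
  if (length(object@rmsdToNative)) {
    if (length(object@rmsdToNative) != nc)
      msg <- c(msg, "'rmsdToNative' must have one value per candidate")
    else if (any(object@rmsdToNative < 0))
      msg <- c(msg, "'rmsdToNative' must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureTable: per-pose descriptors plus responses
#'
#' A rectangular table with one row per (complex, pose), key columns
#' `complex_id` and `pose_id`, feature columns tagged with a descriptor
#' family (X, A, R or G) and two response columns: `RMSD` (Angstrom, defined
#' for every pose; 0 for natives) and `BA` (experimental binding affinity,
#' defined only on native rows).
#'
#' @slot data data.frame holding keys, features and responses.
#' @slot familyMap named character vector mapping each feature column name to
#'   its family tag, in canonical column order.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(data = "data.frame", familyMap = "character")
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  d <- object@data
  need <- c("complex_id", "pose_id")
  if (!all(need %in% names(d)))
    msg <- c(msg, "data must contain 'complex_id' and 'pose_id' columns")
  else {
    key <- paste(d$complex_id, d$pose_id, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicate (complex_id, pose_id) keys, e.g. %s",
                            sub("\r", "/", key[duplicated(key)][1L])))
  }
  fm <- object@familyMap
  if (length(fm)) {
    if (is.null(names(fm)) || any(!nzchar(names(fm))))
      msg <- c(msg, "familyMap must be named by feature column")
    else if (!all(names(fm) %in% names(d)))
      msg <- c(msg, "familyMap names must be columns of the data")
    if (!all(fm %in% c("X", "A", "R", "G")))
      msg <- c(msg, "family tags must be in {X, A, R, G}")
  }
  if ("RMSD" %in% names(d) && any(d$RMSD < 0, na.rm = TRUE))
    msg <- c(msg, "RMSD column must be non-negative")
  if (length(msg)) msg else TRUE
})

#' DecoySet: the retained representative decoy poses for one complex
#'
#' Result of the decoy pipeline: every candidate pose annotated with its
#' RMSD bin, within-bin cluster and energy, plus the `selected` flag marking
#' the lowest-energy representative of each cluster.
#'
#' @slot complexId complex identifier.
#' @slot manifest data.frame with columns pose_id, rmsd, bin, cluster,
#'   energy, selected (poses dropped by the RMSD filter have bin = NA).
#' @slot poses list of the selected representative [MoleculeStructure-class]
#'   objects, in manifest order.
#' @slot config the [decoyConfig()] list used.
#' @exportClass DecoySet
setClass("DecoySet",
  representation(complexId = "character", manifest = "data.frame",
                 poses = "list", config = "list")
)

setValidity("DecoySet", function(object) {
  msg <- character()
  m <- object@manifest
  need <- c("pose_id", "rmsd", "bin", "cluster", "energy", "selected")
  if (!all(need %in% names(m)))
    msg <- c(msg, "manifest must have pose_id, rmsd, bin, cluster, energy, selected")
  else {
    sel <- m[m$selected, , drop = FALSE]
    cfg <- object@config
    if (length(cfg)) {
      if (any(sel$rmsd > cfg$maxRmsd + 1e-12))
        msg <- c(msg, "selected representative beyond maxRmsd")
      if (nrow(sel) && any(table(sel$bin) > cfg$clustersPerBin))
        msg <- c(msg, "more representatives than clustersPerBin in a bin")
    }
    if (nrow(sel) && anyDuplicated(sel[, c("bin", "cluster")]))
      msg <- c(msg, "two representatives from the same cluster")
  }
  if (length(msg)) msg else TRUE
})

#' ScoringModel: a fitted pose-scoring regressor
#'
#' A trained scoring function: the regression method, the response it was
#' trained on (`"BA"` or `"RMSD"`), the descriptor-family signature, tuned
#' hyperparameters, the fitted state and a training fingerprint. Predictions
#' only accept tables carrying exactly the training feature columns.
#'
#' @slot method one of MLR, MARS, kNN, SVM, RF, BRT.
#' @slot response `"BA"` or `"RMSD"`.
#' @slot families the descriptor families used (subset of X, A, R, G), or
#'   `"custom"` when fitted on an explicit column set.
#' @slot featureNames training feature columns, in order.
#' @slot params tuned hyperparameter list.
#' @slot fit fitted backend object.
#' @slot center,scale standardisation vectors (length 0 when the method uses
#'   raw features).
#' @slot seed integer seed used at fit time.
#' @slot nTrain number of training rows.
#' @exportClass ScoringModel
setClass("ScoringModel",
  representation(
    method = "character", response = "character", families = "character",
    featureNames = "character", params = "list", fit = "ANY",
    center = "numeric", scale = "numeric", seed = "integer",
    nTrain = "integer"
  )
)

setValidity("ScoringModel", function(object) {
  msg <- character()
  if (!object@method %in% c("MLR", "MARS", "kNN", "SVM", "RF", "BRT"))
    msg <- c(msg, "unknown method")
  if (!object@response %in% c("BA", "RMSD"))
    msg <- c(msg, "response must be 'BA' or 'RMSD'")
  if (!length(object@featureNames))
    msg <- c(msg, "model must record its feature signature")
  if (length(msg)) msg else TRUE
})

#' SuccessRateReport: docking-power success rates over a cutoff/depth grid
#'
#' Holds the success rate (in percent) for every combination of RMSD cutoff
#' C and ranking depth N, plus the per-complex hit indicators they were
#' computed from. A complex counts as a hit at (C, N) when the best true
#' RMSD among its N top-ranked poses is at most C.
#'
#' @slot rates data.frame with columns C, N, rate (percent).
#' @slot hits data.frame with columns complex_id, C, N, hit (logical).
#' @slot nComplexes number of complexes evaluated.
#' @exportClass SuccessRateReport
setClass("SuccessRateReport",
  representation(rates = "data.frame", hits = "data.frame",
                 nComplexes = "integer")
)

setValidity("SuccessRateReport", function(object) {
  msg <- character()
  r <- object@rates
  if (!all(c("C", "N", "rate") %in% names(r)))
    msg <- c(msg, "rates must have columns C, N, rate")
  else {
    if (any(r$rate < 0 | r$rate > 100))
      msg <- c(msg, "rates must lie in [0, 100]")
    # success is monotone in both the cutoff and the depth
    for (nn in unique(r$N)) {
      sub <- r[r$N == nn, ]
      if (is.unsorted(sub$rate[order(sub$C)]))
        msg <- c(msg, sprintf("rate not non-decreasing in C at N=%s", nn))
    }
    for (cc in unique(r$C)) {
      sub <- r[r$C == cc, ]
      if (is.unsorted(sub$rate[order(sub$N)]))
        msg <- c(msg, sprintf("rate not non-decreasing in N at C=%s", cc))
    }
  }
  if (length(msg)) msg else TRUE
})
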