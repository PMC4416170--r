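#' Decoy pipeline configuration
#'
#' Parameters of the decoy-set construction pipeline: candidate poses more
#' than `maxRmsd` Angstrom from the native pose are discarded, survivors
#' are grouped into `maxRmsd/binWidth` RMSD bins, each bin is clustered
#' into at most `clustersPerBin` clusters and the lowest-energy member of
#' each cluster is retained. The defaults (10 Angstrom filter, ten 1
#' Angstrom bins, ten clusters per bin) yield up to 10 x 10 = 100 diverse
#' representatives per complex.
#'
#' @param maxRmsd RMSD filter in Angstrom (default 10).
#' @param binWidth bin width in Angstrom (default 1); `maxRmsd` must be an
#'   integral multiple.
#' @param clustersPerBin maximum representatives per bin (default 10).
#' @param includeNative should an exact-native pose (RMSD = 0) be binned
#'   (into bin 1) rather than dropped? Default `FALSE`.
#' @param energySource `"provided"` (a per-pose energy column must be
#'   supplied) or `"builtin"` (the [builtinEnergy()] surrogate).
#' @return a list of class `"decoyConfig"`.
#' @seealso [decoyPreset()], [buildDecoySet()]
#' @export
decoyConfig <- function(maxRmsd = 10, binWidth = 1, clustersPerBin = 10,
                        includeNative = FALSE,
                        energySource = c("provided", "builtin")) {
  energySource <- match.arg(energySource)
  nBins <- maxRmsd / binWidth
  if (abs(nBins - round(nBins)) > 1e-9)
    stop("configuration error: maxRmsd must be an integral number of bins",
         call. = FALSE)
  if (clustersPerBin < 1L)
    stop("configuration error: clustersPerBin must be >= 1", call. = FALSE)
  structure(list(maxRmsd = maxRmsd, binWidth = binWidth,
                 nBins = as.integer(round(nBins)),
                 clustersPerBin = as.integer(clustersPerBin),
                 includeNative = includeNative,
                 energySource = energySource),
            class = "decoyConfig")
}

#' Named decoy-pipeline presets
#'
#' `"test100"` retains up to 100 representatives per complex (10 bins x 10
#' clusters), the regime used for benchmark test sets; `"train50"` retains
#' up to 50 (10 bins x 5 clusters), the lighter regime used for training
#' sets.
#'
#' @param name `"test100"` or `"train50"`.
#' @param ... overrides passed to [decoyConfig()].
#' @return a `"decoyConfig"` list.
#' @export
decoyPreset <- function(name = c("test100", "train50"), ...) {
  name <- match.arg(name)
  switch(name,
    test100 = decoyConfig(clustersPerBin = 10, ...),
    train50 = decoyConfig(clustersPerBin = 5, ...))
}

#' Assign candidate poses to RMSD bins
#'
#' Poses with RMSD > `maxRmsd` are discarded. Bin k (k = 1..nBins) holds
#' RMSD in ((k-1) * binWidth, k * binWidth]. An RMSD of exactly 0 (the
#' native pose) falls outside every half-open bin and is assigned to bin 1
#' only when `includeNative` is set.
#'
#' @param rmsd numeric vector of RMSD annotations (Angstrom).
#' @param config a [decoyConfig()] list.
#' @return integer vector of bin indices, `NA` for discarded poses.
#' @examples
#' cfg <- decoyConfig()
#' filterAndBin(c(0.5, 1.5, 9.9, 10.4), cfg)  # 1 2 10 NA
#' @export
filterAndBin <- function(rmsd, config = decoyConfig()) {
  if (anyNA(rmsd) || any(rmsd < 0))
    stop("data error: RMSD annotations must be present and non-negative",
         call. = FALSE)
  bin <- as.integer(ceiling(rmsd / config$binWidth))
  bin[rmsd > config$maxRmsd] <- NA_integer_
  isNative <- rmsd == 0
  bin[isNative] <- if (config$includeNative) 1L else NA_integer_
  bin
}

#' Cluster the poses of one RMSD bin
#'
#' Complete-linkage hierarchical clustering on the pairwise heavy-atom
#' pose--pose RMSD matrix, cut at `min(k, n)` clusters. Deterministic
#' given input order; with fewer poses than clusters every pose is a
#' singleton.
#'
#' @param poses non-empty list of atom-compatible
#'   [MoleculeStructure-class] poses.
#' @param k target number of clusters.
#' @return integer vector of cluster labels (1-based, labelled in order of
#'   first appearance).
#' @export
clusterBin <- function(poses, k) {
  n <- length(poses)
  if (!n) stop("empty bin", call. = FALSE)
  if (n == 1L) return(1L)
  d <- stats::as.dist(poseRmsdMatrix(poses))
  labels <- stats::cutree(stats::hclust(d, method = "complete"),
                          k = min(k, n))
  # relabel in order of first appearance so labels are input-order stable
  match(labels, unique(labels))
}

#' Select the lowest-energy representative of each cluster
#'
#' @param labels integer cluster labels.
#' @param energies numeric per-pose energies (lower = more favourable).
#' @return integer indices of the selected poses, one per cluster, in
#'   cluster-label order; ties go to the lowest pose index.
#' @export
selectRepresentatives <- function(labels, energies) {
  if (length(labels) != length(energies) || anyNA(energies))
    stop("data error: one finite energy per pose is required", call. = FALSE)
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(energies[idx])]  # which.min takes the first on ties
  }, integer(1))
}

#' Surrogate protein-ligand interaction energy
#'
#' Deterministic Lennard-Jones-like pairwise score summed over
#' protein--ligand heavy-atom pairs within 8 Angstrom:
#' `4 * ((r0/d)^12 - (r0/d)^6)` with `r0` = 3.5 Angstrom and distances
#' clamped at d >= 1 Angstrom. Lower is more favourable. This is a
#' **surrogate** for docking-tool interaction energies so the pipeline can
#' run on synthetic data; it has no physical calibration.
#'
#' @param receptor,pose [MoleculeStructure-class] objects.
#' @param r0 well-minimum distance parameter (Angstrom).
#' @param cutoff pair inclusion cutoff (Angstrom, default 8).
#' @return single numeric score (0 when no pair is within the cutoff).
#' @export
builtinEnergy <- function(receptor, pose, r0 = 3.5, cutoff = 8) {
  d <- crossDist(atomCoords(receptor), atomCoords(pose))
  d <- d[d <= cutoff]
  if (!length(d)) return(0)
  d <- pmax(d, 1)
  s <- (r0 / d)^6
  sum(4 * (s^2 - s))
}

#' Run the full decoy pipeline for one complex
#'
#' Filters candidates by RMSD, bins, clusters each bin and keeps the
#' lowest-energy representative per cluster (see [decoyConfig()]). Bins
#' holding fewer than `clustersPerBin` mutually distinct poses contribute
#' fewer representatives, so the total can fall short of
#' `nBins * clustersPerBin`.
#'
#' @param poseSet a [PoseSet-class] with RMSD annotations.
#' @param config a [decoyConfig()] or [decoyPreset()] list.
#' @return a [DecoySet-class].
#' @export
buildDecoySet <- function(poseSet, config = decoyPreset("test100")) {
  stopifnot(is(poseSet, "PoseSet"))
  cands <- candidatePoses(poseSet)
  rmsd <- rmsdToNative(poseSet)
  if (is.null(rmsd))
    stop("data error: poseSet lacks RMSD annotations", call. = FALSE)
  energies <- poseEnergies(poseSet)
  if (config$energySource == "provided") {
    if (is.null(energies))
      stop("data error: energySource='provided' but the pose set has no energies",
           call. = FALSE)
  } else {
    energies <- vapply(cands, builtinEnergy, numeric(1),
                       receptor = receptor(poseSet))
  }
  bin <- filterAndBin(rmsd, config)
  manifest <- data.frame(
    pose_id = vapply(cands, moleculeId, character(1)),
    rmsd = rmsd, bin = bin, cluster = NA_integer_,
    energy = energies, selected = FALSE, stringsAsFactors = FALSE)

  for (b in sort(unique(bin[!is.na(bin)]))) {
    idx <- which(!is.na(bin) & bin == b)
    labels <- clusterBin(cands[idx], config$clustersPerBin)
    manifest$cluster[idx] <- labels
    rep <- idx[selectRepresentatives(labels, energies[idx])]
    manifest$selected[rep] <- TRUE
  }
  new("DecoySet", complexId = complexId(poseSet), manifest = manifest,
      poses = cands[manifest$selected], config = unclass(config))
}
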