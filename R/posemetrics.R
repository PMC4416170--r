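#' Heavy-atom RMSD between two ligand poses
#'
#' Root-mean-square deviation of paired atom coordinates:
#' `sqrt(mean(|a_i - b_i|^2))` over atoms i, in Angstrom. Atoms are paired
#' by index and **no superposition is performed** — docking decoys are
#' compared in the shared receptor frame, so a rigid displacement of one
#' pose contributes fully to the RMSD.
#'
#' No automorphism (symmetry) correction is applied; supply a
#' `atomMapping` permutation of `b`'s atoms to plug in an external matching
#' strategy.
#'
#' @param a,b [MoleculeStructure-class] poses with equal heavy-atom counts.
#' @param atomMapping optional integer permutation mapping atoms of `a` to
#'   atoms of `b` (default: identity, i.e. pairing by index).
#' @return RMSD in Angstrom (single non-negative numeric).
#' @examples
#' m <- MoleculeStructure("x", c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' t <- MoleculeStructure("y", c("C", "C"), rbind(c(3, 4, 0), c(4, 4, 0)))
#' poseRmsd(m, t)  # uniform (3,4,0) translation -> 5
#' @export
poseRmsd <- function(a, b, atomMapping = NULL) {
  ca <- atomCoords(a)
  cb <- atomCoords(b)
  if (nrow(ca) != nrow(cb))
    stop("atom pairing error: poses have ", nrow(ca), " and ", nrow(cb),
         " heavy atoms", call. = FALSE)
  if (!is.null(atomMapping)) {
    if (length(atomMapping) != nrow(cb) ||
        !setequal(atomMapping, seq_len(nrow(cb))))
      stop("'atomMapping' must be a permutation of 1..", nrow(cb),
           call. = FALSE)
    cb <- cb[atomMapping, , drop = FALSE]
  }
  sqrt(mean(rowSums((ca - cb)^2)))
}

# pairwise RMSD matrix for a list of atom-compatible poses; exploits that
# index-paired frame RMSD is the Euclidean distance between flattened
# coordinate vectors scaled by 1/sqrt(n_atoms)
poseRmsdMatrix <- function(poses) {
  n <- length(poses)
  nat <- nAtoms(poses[[1L]])
  flat <- t(vapply(poses, function(p) as.numeric(atomCoords(p)),
                   numeric(3L * nat)))
  as.matrix(stats::dist(flat)) / sqrt(nat)
}
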