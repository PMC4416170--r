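#' Read a receptor structure from a PDB file
#'
#' Parses ATOM (and optionally standard-residue HETATM) records into a
#' heavy-atom [MoleculeStructure-class]. Hydrogens are dropped, element
#' symbols are normalised, and waters (HOH/WAT/DOD residues) are always
#' excluded. Non-standard HETATM records (ions, cofactors, buffer molecules)
#' are excluded by default because bound ligands are supplied separately
#' through [readPoses()]; set `keepHetatm = TRUE` to retain them.
#'
#' @param path path to a PDB file.
#' @param keepHetatm keep non-water HETATM records (default `FALSE`).
#' @return a [MoleculeStructure-class] with `role = "receptor"`.
#' @examples
#' pdb <- system.file("extdata", "mini_receptor.pdb", package = "poseforge")
#' readReceptor(pdb)
#' @export
readReceptor <- function(path, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keepHetatm) keep <- keep | at$type == "HETATM"
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elem <- elementFromPdb(at)
  heavy <- toupper(elem) != "H" & toupper(elem) != "D"
  at <- at[heavy, , drop = FALSE]
  elem <- elem[heavy]
  if (!nrow(at))
    stop("no heavy atoms in '", path, "' after filtering", call. = FALSE)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("malformed coordinate field in '", path, "' (record ",
         which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1L],
         ")", call. = FALSE)
  MoleculeStructure(
    moleculeId = tools::file_path_sans_ext(basename(path)),
    elements = elem,
    coords = cbind(at$x, at$y, at$z),
    role = "receptor")
}

# element symbol from a bio3d atom table: trust the element column when
# present, else fall back to the leading letters of the atom name
elementFromPdb <- function(at) {
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) {
    guess <- sub("^[0-9' ]*", "", at$elety[miss])
    guess <- sub("[0-9'].*$", "", guess)
    elem[miss] <- substr(guess, 1L, ifelse(toupper(guess) %in%
      c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), 2L, 1L))
  }
  normalizeElement(elem)
}

#' Read ligand poses from a multi-record MOL2 or SD file
#'
#' Returns one heavy-atom [MoleculeStructure-class] per record, in file
#' order. Records whose heavy-atom count differs from the first record are
#' reported with a warning (not dropped): RMSD pairing requires a common
#' atom ordering across poses of the same ligand.
#'
#' @param path path to the pose file.
#' @param format `"sdf"` or `"mol2"`; inferred from the file extension when
#'   omitted.
#' @return list of [MoleculeStructure-class] objects.
#' @examples
#' sdf <- system.file("extdata", "mini_poses.sdf", package = "poseforge")
#' length(readPoses(sdf))
#' @export
readPoses <- function(path, format = c("auto", "sdf", "mol2")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", sd = "sdf", mol2 = "mol2",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  structs <- if (format == "sdf") readSdfPoses(path) else readMol2Poses(path)
  if (!length(structs)) stop("no records in '", path, "'", call. = FALSE)
  counts <- vapply(structs, nAtoms, integer(1))
  if (length(unique(counts)) > 1L) {
    off <- which(counts != counts[1L])
    warning("inconsistent heavy-atom counts across records; record(s) ",
            paste(off, collapse = ", "), " differ from record 1 (",
            counts[1L], " atoms)", call. = FALSE)
  }
  structs
}

readSdfPoses <- function(path) {
  # bond-free records (legal for bare pose coordinates) trip ChemmineR's
  # validity warning; everything else is re-signalled
  sdf <- withCallingHandlers(
    tryCatch(ChemmineR::read.SDFset(path),
             error = function(e)
               stop("SDF parse failure in '", path, "': ",
                    conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid SDFs detected", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lapply(seq_along(ChemmineR::cid(sdf)), function(i) {
    rec <- sdf[[i]]
    ab <- ChemmineR::atomblock(rec)
    elem <- normalizeElement(sub("_.*$", "", rownames(ab)))
    heavy <- elem != "H"
    if (!any(heavy))
      stop("record ", i, " of '", path, "' has no heavy atoms", call. = FALSE)
    id <- ChemmineR::sdfid(rec)
    if (!length(id) || is.na(id) || !nzchar(id)) id <- sprintf("pose%03d", i)
    MoleculeStructure(id, elem[heavy], ab[heavy, 1:3, drop = FALSE])
  })
}

readMol2Poses <- function(path) {
  mol <- tryCatch(bio3d::read.mol2(path),
                  error = function(e)
                    stop("MOL2 parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (inherits(mol, "mol2")) mol <- list(mol)
  lapply(seq_along(mol), function(i) {
    at <- mol[[i]]$atom
    elem <- normalizeElement(sub("\\..*$", "", at$elety))
    heavy <- elem != "H"
    if (!any(heavy))
      stop("record ", i, " of '", path, "' has no heavy atoms", call. = FALSE)
    id <- mol[[i]]$name
    if (!length(id) || !nzchar(id)) id <- sprintf("pose%03d", i)
    MoleculeStructure(id, elem[heavy],
                      cbind(at$x, at$y, at$z)[heavy, , drop = FALSE])
  })
}

#' Write structures to an SD (V2000) file
#'
#' Minimal V2000 writer for round-tripping poses: elements and coordinates
#' only, no bond block. Coordinates are written at 1e-4 Angstrom precision.
#'
#' @param structures a [MoleculeStructure-class] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSdf <- function(structures, path) {
  if (is(structures, "MoleculeStructure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    xyz <- atomCoords(s)
    writeLines(c(moleculeId(s), "  poseforge", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nAtoms(s), 0L), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], atomElements(s)), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Assemble a PoseSet with computed RMSD annotations
#'
#' Bundles receptor, native pose and candidates into a [PoseSet-class],
#' computing each candidate's RMSD to the native pose with [poseRmsd()].
#'
#' @param receptor,native [MoleculeStructure-class] objects.
#' @param candidates list of candidate poses, atom-compatible with `native`.
#' @param energies optional numeric per-candidate energy (lower = better).
#' @param complexId identifier; defaults to the receptor's id.
#' @return a [PoseSet-class].
#' @export
assemblePoseSet <- function(receptor, native, candidates, energies = NULL,
                            complexId = moleculeId(receptor)) {
  stopifnot(is(receptor, "MoleculeStructure"), is(native, "MoleculeStructure"))
  if (is(candidates, "MoleculeStructure")) candidates <- list(candidates)
  nNat <- nAtoms(native)
  bad <- which(vapply(candidates, nAtoms, integer(1)) != nNat)
  if (length(bad))
    stop("atom pairing error: candidate(s) ", paste(bad, collapse = ", "),
         " do not match the native pose's ", nNat, " heavy atoms",
         call. = FALSE)
  rmsds <- vapply(candidates, poseRmsd, numeric(1), native)
  new("PoseSet", complexId = as.character(complexId), receptor = receptor,
      native = native, candidates = candidates,
      energies = if (is.null(energies)) numeric() else as.numeric(energies),
      rmsdToNative = rmsds)
}
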