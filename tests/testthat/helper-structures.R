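# in-code fixture builders shared across test files

# a ligand-like structure with given coordinates
toyStructure <- function(coords, elements = NULL, id = "toy",
                         role = "ligand") {
  coords <- as.matrix(coords)
  if (is.null(elements)) elements <- rep("C", nrow(coords))
  MoleculeStructure(id, elements, coords, role = role)
}

# random structure with elements drawn from the featurizer sets
randomStructure <- function(n, id = "rnd", role = "ligand",
                            spread = 10) {
  elems <- if (role == "receptor")
    sample(c("C", "N", "O", "S"), n, replace = TRUE)
  else
    sample(c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I"), n,
           replace = TRUE)
  MoleculeStructure(id, elems, matrix(runif(3 * n, -spread, spread), n, 3L),
                    role = role)
}

# tiny three-residue-ish PDB text: 5 heavy ATOM atoms, 1 hydrogen,
# 1 water and 1 non-standard HETATM (zinc)
miniPdbLines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.674   6.719  -4.163  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.462   6.563  -4.307  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      11.891   4.623  -4.741  1.00  0.00           C",
    "ATOM      6  H   ALA A   1      10.321   5.668  -6.802  1.00  0.00           H",
    "HETATM    7  O   HOH A  90      13.100   2.000   1.000  1.00  0.00           O",
    "HETATM    8 ZN    ZN A  91       5.000   5.000   5.000  1.00  0.00          ZN",
    "END")
}

writeMiniPdb <- function(path = tempfile(fileext = ".pdb"),
                         lines = miniPdbLines()) {
  writeLines(lines, path)
  path
}

# a V2000 SDF with the given per-record element/coordinate sets
writeSdfRecords <- function(records, path = tempfile(fileext = ".sdf")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    r <- records[[nm]]
    writeLines(c(nm, "  fixture", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(r$coords), 0L), con)
    writeLines(sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      r$coords[, 1], r$coords[, 2], r$coords[, 3], r$elements), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  path
}

# small synthetic benchmark shared by model tests (memoised per session)
.benchCache <- new.env(parent = emptyenv())
smallBenchmark <- function(nComplexes = 25L, posesPerComplex = 8L,
                           seed = 11L, ...) {
  key <- paste(nComplexes, posesPerComplex, seed, ...)
  if (is.null(.benchCache[[key]]))
    .benchCache[[key]] <- makeBenchmark(synthScenario(
      nComplexes = nComplexes, posesPerComplex = posesPerComplex,
      seed = seed, ...))
  .benchCache[[key]]
}
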