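# exhaustive double-loop oracle over all atom pairs
pairCountOracle <- function(receptor, ligand, binEdges) {
  pe <- atomElements(receptor); le <- atomElements(ligand)
  pc <- atomCoords(receptor); lc <- atomCoords(ligand)
  nb <- length(binEdges) - 1L
  labels <- if (nb > 1L) paste0("b", seq_len(nb)) else NULL
  keys <- poseforge:::pairKeys(labels)
  counts <- setNames(integer(length(keys)), keys)
  for (i in seq_along(pe)) for (j in seq_along(le)) {
    if (!pe[i] %in% poseforge:::proteinElements) next
    if (!le[j] %in% poseforge:::ligandElements) next
    d <- sqrt(sum((pc[i, ] - lc[j, ])^2))
    for (b in seq_len(nb)) {
      if (d > binEdges[b] && d <= binEdges[b + 1L]) {
        key <- paste(pe[i], le[j], sep = ".")
        if (nb > 1L) key <- paste0(key, ".b", b)
        counts[key] <- counts[key] + 1L
      }
    }
  }
  counts
}

test_that("single-pair geometries count into the right key", {
  r <- toyStructure(rbind(c(0, 0, 0)), "N", role = "receptor")
  l <- toyStructure(rbind(c(5, 0, 0)), "C")
  v <- pairCounts(r, l)
  expect_length(v, 36L)
  expect_equal(unname(v[["N.C"]]), 1)
  expect_equal(sum(v), 1)

  # beyond the cutoff: all zero; at exactly the cutoff: counted (inclusive)
  far <- toyStructure(rbind(c(12.5, 0, 0)), "C")
  expect_equal(sum(pairCounts(r, far)), 0)
  edge <- toyStructure(rbind(c(12, 0, 0)), "C")
  expect_equal(sum(pairCounts(r, edge)), 1)
})

test_that("elements outside the schema contribute nothing", {
  r <- toyStructure(rbind(c(0, 0, 0), c(1, 0, 0)), c("Zn", "C"),
                    role = "receptor")
  l <- toyStructure(rbind(c(3, 0, 0), c(4, 0, 0)), c("C", "Se"))
  v <- pairCounts(r, l)
  expect_equal(sum(v), 1)  # only the C-C pair
  expect_equal(unname(v[["C.C"]]), 1)
})

test_that("binned counts have width 180 and bin by (lo, hi]", {
  r <- toyStructure(rbind(c(0, 0, 0)), "C", role = "receptor")
  l <- toyStructure(rbind(c(9, 0, 0)), "O")
  v <- binnedPairCounts(r, l)
  expect_length(v, 180L)
  expect_equal(unname(v[["C.O.b3"]]), 1)  # 9 A is in (8, 12]
  expect_equal(sum(v), 1)

  # boundary: exactly 8 A belongs to bin 2 (4, 8], not bin 3
  l8 <- toyStructure(rbind(c(8, 0, 0)), "O")
  v8 <- binnedPairCounts(r, l8)
  expect_equal(unname(v8[["C.O.b2"]]), 1)
  expect_equal(unname(v8[["C.O.b3"]]), 0)

  expect_error(binnedPairCounts(r, l, binEdges = c(0, 4, 3)),
               "configuration")
})

test_that("pair counts match the exhaustive oracle and conserve over bins", {
  set.seed(23)
  for (i in 1:8) {
    rec <- randomStructure(50, role = "receptor", spread = 8)
    lig <- randomStructure(10, spread = 8)
    expect_identical(as.integer(pairCounts(rec, lig)),
                     as.integer(pairCountOracle(rec, lig, c(0, 12))))
    binned <- binnedPairCounts(rec, lig)
    expect_identical(as.integer(binned),
                     as.integer(pairCountOracle(rec, lig,
                                                c(0, 4, 8, 12, 16, 20))))
    # count conservation: first three 4 A bins sum to the 12 A counts
    first3 <- sapply(poseforge:::pairKeys(), function(k)
      sum(binned[paste0(k, ".b", 1:3)]))
    expect_equal(unname(first3), unname(pairCounts(rec, lig)))
  }
})

test_that("pair counts are invariant to atom input order", {
  set.seed(41)
  rec <- randomStructure(30, role = "receptor")
  lig <- randomStructure(12)
  perm <- sample(nAtoms(rec))
  permRec <- MoleculeStructure("perm", atomElements(rec)[perm],
                               atomCoords(rec)[perm, ], role = "receptor")
  expect_identical(pairCounts(rec, lig), pairCounts(permRec, lig))
  expect_identical(binnedPairCounts(rec, lig),
                   binnedPairCounts(permRec, lig))
})

test_that("family combinations enumerate non-empty subsets deterministically", {
  all4 <- enumerateFamilyCombinations()
  expect_length(all4, 15L)
  expect_equal(all4, c("X", "A", "R", "G", "XA", "XR", "XG", "AR", "AG",
                       "RG", "XAR", "XAG", "XRG", "ARG", "XARG"))
  expect_equal(enumerateFamilyCombinations(c("X", "G")), c("X", "G", "XG"))
  expect_equal(enumerateFamilyCombinations("R"), "R")
  expect_error(enumerateFamilyCombinations(character()), "non-empty")
})

test_that("external descriptor tables validate keys and widths", {
  d <- data.frame(complex_id = rep(c("c1", "c2"), each = 5),
                  pose_id = rep(paste0("p", 1:5), 2))
  for (j in 1:6) d[[paste0("f", j)]] <- rnorm(10)
  path <- tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  frag <- loadExternalFeatures(path, "X")
  expect_equal(nrow(frag), 10L)
  expect_equal(attr(frag, "family"), "X")
  expect_true(all(startsWith(setdiff(names(frag),
                                     c("complex_id", "pose_id")), "X.")))

  # 6 columns loaded as family A (nominal 30) warns but loads
  expect_warning(loadExternalFeatures(path, "A"), "nominal width")

  # duplicated key is a schema error
  dup <- rbind(d, d[1, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(loadExternalFeatures(path, "X"), "schema.*c1/p1")

  # missing key columns are a schema error
  write.csv(d[, -1], path, row.names = FALSE)
  expect_error(loadExternalFeatures(path, "X"), "key columns")
})

test_that("feature tables have one row per pose, native rows at RMSD 0", {
  set.seed(3)
  poseSets <- lapply(1:2, function(i) {
    nat <- randomStructure(8, id = "nat")
    cands <- lapply(1:4, function(p)
      perturbToRmsd(nat, p, seed = p, id = paste0("p", p)))
    assemblePoseSet(randomStructure(20, role = "receptor"), nat, cands,
                    complexId = paste0("c", i))
  })
  tab <- buildFeatureTable(poseSets, families = "R")
  d <- featureData(tab)
  expect_equal(nrow(d), 10L)  # 2 complexes x (1 native + 4 decoys)
  expect_equal(sum(featureFamilies(tab) == "R"), 36L)
  expect_true(all(d$RMSD[d$pose_id == "native"] == 0))

  # BA lands on native rows only
  tabBa <- buildFeatureTable(poseSets, families = "R",
                             ba = c(c1 = 6.2, c2 = 7.9))
  dBa <- featureData(tabBa)
  expect_equal(sum(!is.na(dBa$BA)), 2L)
  expect_true(all(dBa$pose_id[!is.na(dBa$BA)] == "native"))

  # requesting a family whose fragment lacks one pose is a coverage error
  frag <- d[d$pose_id != "p4", c("complex_id", "pose_id")]
  frag$G.g1 <- rnorm(nrow(frag))
  expect_error(
    buildFeatureTable(poseSets, families = "RG", external = list(G = frag)),
    "coverage")
})
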