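test_that("compound tables load with optional activity, duplicate and weight checks", {
  cfg <- prepConfig()
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("theophylline", "b"),
                              smiles = c("Cn1c(=O)c2[nH]cnc2n(C)c1=O", "CCO"),
                              pIC50 = c(NA, 5.0)),
                   path, row.names = FALSE)
  mset <- loadCompoundTable(path, config = cfg)
  expect_equal(length(mset), 2L)
  expect_true(is.na(mset[["theophylline"]]$pIC50))
  expect_equal(mset[["b"]]$pIC50, 5.0)

  utils::write.csv(data.frame(id = c("a", "b", "a"),
                              smiles = c("C", "CC", "CCC")),
                   path, row.names = FALSE)
  expect_error(loadCompoundTable(path, config = cfg), "duplicate.*a")

  utils::write.csv(data.frame(id = "noid", notsmiles = "C"), path,
                   row.names = FALSE)
  expect_error(loadCompoundTable(path, config = cfg), "missing.*column")

  # a >1000 Da peptide-like SMILES is excluded and logged
  big <- paste0("CC(=O)", paste(rep("NC(C)C(=O)", 15), collapse = ""), "O")
  utils::write.csv(data.frame(id = c("small", "big"),
                              smiles = c("CCO", big)),
                   path, row.names = FALSE)
  expect_message(mset <- loadCompoundTable(path, config = cfg),
                 "excluded by the 1000 Da")
  expect_equal(moleculeIds(mset), "small")
  expect_equal(mset@exclusions$id, "big")

  utils::write.csv(data.frame(id = c("ok", "bad"),
                              smiles = c("CC", "not_a_smiles(((")),
                   path, row.names = FALSE)
  expect_error(loadCompoundTable(path, config = cfg), "row")
  expect_warning(mset <- loadCompoundTable(path, config = cfg,
                                           onParseError = "drop"),
                 "dropped")
  expect_equal(moleculeIds(mset), "ok")
})

test_that("standardization strips salts and applies the pH-7 ionization rules", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    id = c("na_acetate", "amine", "tetrazole", "aniline"),
    smiles = c("CC(=O)O.[Na+]", "CCN", "c1ccccc1-c1nnn[nH]1",
               "Nc1ccccc1")), path, row.names = FALSE)
  mset <- standardizeMolecules(loadCompoundTable(path))
  expect_equal(mset[["na_acetate"]]$smiles, "CC(=O)[O-]")  # salt gone, anion
  expect_match(mset[["amine"]]$smiles, "NH3\\+")           # ammonium
  expect_match(mset[["tetrazole"]]$smiles, "n-|\\[n-\\]")  # tetrazolate
  expect_false(grepl("\\+", mset[["aniline"]]$smiles))     # aniline neutral
})

test_that("specified chirality is retained and unspecified centres enumerated", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("spec", "unspec", "achiral"),
                              smiles = c("C[C@H](O)CC", "CC(F)C(Cl)C",
                                         "CCO")),
                   path, row.names = FALSE)
  mset <- standardizeMolecules(loadCompoundTable(path))
  recs <- records(mset)
  fromSpec <- recs[vapply(recs, function(r) r$parentId == "spec", logical(1))]
  expect_length(fromSpec, 1L)
  expect_match(fromSpec[[1]]$smiles, "@")
  fromUnspec <- recs[vapply(recs, function(r) r$parentId == "unspec",
                            logical(1))]
  expect_length(fromUnspec, 4L)  # two unspecified centres -> 4 isomers
  expect_true(all(grepl("_s[0-9]$",
                        vapply(fromUnspec, function(r) r$id, character(1)))))
  fromAchiral <- recs[vapply(recs, function(r) r$parentId == "achiral",
                             logical(1))]
  expect_length(fromAchiral, 1L)
  expect_equal(fromAchiral[[1]]$id, "achiral")
})

test_that("conformer ensembles satisfy the caps, energy window and RMSD contract", {
  mset <- preparedTestSet()
  for (id in moleculeIds(mset)) {
    r <- mset[[id]]
    nCap <- min(100L, 10L * max(1L, r$rotatableBonds))
    n <- length(r$conformers)
    expect_gte(n, 1L)
    expect_lte(n, nCap)
    rel <- vapply(r$conformers, function(cf) cf$relEnergy, numeric(1))
    expect_true(all(rel >= 0 & rel <= 10.0))
    heavy <- which(r$atoms$element != "H")
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          expect_gte(bestFitRMSD(r$conformers[[i]]$coords[heavy, ],
                                 r$conformers[[j]]$coords[heavy, ]), 1.0)
        }
      }
    }
  }
  # rigid molecule: small ensemble under the per-rotatable-bond floor
  expect_lte(length(mset[["benzene"]]$conformers), 10L)
})

test_that("conformer deduplication keeps one of two near-duplicates", {
  set.seed(9)
  base <- matrix(rnorm(24), 8, 3)
  near <- base + matrix(rnorm(24, 0, 0.1), 8, 3)     # ~0.1-0.5 A away
  far <- applyRigid(base, testRotation(2)) + 5 * matrix(runif(24), 8, 3)
  kept <- dedupConformers(list(base, near, far), c(0, 0.5, 1),
                          heavyIdx = 1:8, energyWindow = 10, rmsdCutoff = 1)
  expect_equal(kept[1], 1L)                    # lowest energy always kept
  expect_false(2L %in% kept)                   # near-duplicate removed
  expect_true(bestFitRMSD(base, far) < 1 || 3L %in% kept)
  # energy window excludes high-energy conformers
  kept2 <- dedupConformers(list(base, far), c(0, 12), 1:8,
                           energyWindow = 10, rmsdCutoff = 1)
  expect_equal(kept2, 1L)
})

test_that("conformer generation is deterministic for a fixed seed and config", {
  tab <- data.frame(id = "m", smiles = "CCOc1ccccc1")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  run <- function() {
    mset <- prepareMolecules(loadCompoundTable(path),
                             prepConfig(randomSeed = 17))
    mset[["m"]]$conformers
  }
  c1 <- run(); c2 <- run()
  expect_identical(c1, c2)
})

test_that("SDF round trip preserves coordinates to 1e-4 Angstrom", {
  mset <- preparedTestSet()
  sub <- mset[c("phenol", "caffeine")]
  path <- tempfile(fileext = ".sdf")
  writeConformersSDF(sub, path)
  back <- readConformersSDF(path)
  expect_setequal(moleculeIds(back), c("phenol", "caffeine"))
  for (id in moleculeIds(back)) {
    orig <- sub[[id]]$conformers
    got <- back[[id]]$conformers
    expect_equal(length(got), length(orig))
    for (i in seq_along(orig)) {
      expect_equal(got[[i]]$coords, orig[[i]]$coords, tolerance = 1e-4,
                   ignore_attr = TRUE)
      expect_equal(got[[i]]$relEnergy, orig[[i]]$relEnergy,
                   tolerance = 1e-6)
    }
  }
})

test_that("the preparation report covers retained and excluded molecules", {
  mset <- preparedTestSet()
  rep_ <- prepReport(mset)
  expect_true(all(moleculeIds(mset) %in% rep_$id))
  expect_true(all(rep_$nConformers[rep_$reason == ""] >= 1L))
})
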