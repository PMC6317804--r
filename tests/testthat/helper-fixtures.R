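# Shared fixtures. Chemistry-backed objects are prepared once per test run
# and cached, since conformer embedding is the expensive step.

.fixtureCache <- new.env(parent = emptyenv())

# A small prepared molecule set covering the perception and atom-class
# test cases: an aromatic ring, a phenol, methane, an acetate salt, an
# amide, a chiral alcohol and a rigid xanthine.
testMoleculeTable <- function() {
  data.frame(
    id = c("benzene", "phenol", "methane", "na_acetate", "benzamide",
           "chiralol", "caffeine"),
    smiles = c("c1ccccc1", "Oc1ccccc1", "C", "CC(=O)O.[Na+]",
               "NC(=O)c1ccccc1", "C[C@H](O)CC", "Cn1cnc2c1c(=O)n(C)c(=O)n2C"),
    pIC50 = c(NA, 4.2, NA, 5.5, 6.1, NA, 5.9),
    stringsAsFactors = FALSE)
}

preparedTestSet <- function() {
  if (!is.null(.fixtureCache$prepared)) return(.fixtureCache$prepared)
  tab <- testMoleculeTable()
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  mset <- loadCompoundTable(path, config = prepConfig(randomSeed = 42))
  mset <- prepareMolecules(mset, prepConfig(randomSeed = 42))
  .fixtureCache$prepared <- mset
  mset
}

testSiteSets <- function() {
  if (!is.null(.fixtureCache$siteSets)) return(.fixtureCache$siteSets)
  .fixtureCache$siteSets <- perceiveSites(preparedTestSet())
  .fixtureCache$siteSets
}

# Noise-free planted geometry fixture: actives are exact copies of the
# planted sites under random rigid motions.
plantedExactFixture <- function(nActives = 5, seed = 3) {
  spec <- plantedPharmacophoreSpec(jitterSD = 0, nExtraSites = c(0, 0))
  generatePlantedSiteSets(spec, nActives = nActives, nDecoys = 0, seed = seed)
}

# Random rotation helper with reproducible seed.
testRotation <- function(seed = 1) {
  set.seed(seed)
  PharmSafe3D:::randomRotation()
}
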