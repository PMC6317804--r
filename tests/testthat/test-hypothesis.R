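test_that("a planted common pharmacophore is recovered from exact actives", {
  fx <- plantedExactFixture(nActives = 5, seed = 3)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  expect_gte(length(hyps), 1L)
  best <- hyps[[1]]
  expect_equal(variantCode(best), "AAAR")
  expect_equal(best@nMatchingActives, 5L)
  # oracle cross-check: every active's site set contains the planted
  # quadruplet by brute-force enumeration
  for (id in names(fx$siteSets)) {
    expect_true(bruteForcePlantedMatch(fx$spec$types, fx$spec$sitePositions,
                                       sites(fx$siteSets[[id]][[1]]),
                                       fx$spec$matchTolerance))
  }
})

test_that("actives sharing no common geometry yield an empty hypothesis list", {
  set.seed(21)
  ss <- lapply(1:4, function(i) {
    pos <- matrix(runif(12, 0, 18), 4, 3) + (i - 1) * 40
    tab <- data.frame(type = c("A", "A", "A", "R"),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      dx = NA_real_, dy = NA_real_, dz = NA_real_)
    tab$sourceAtoms <- I(as.list(1:4))
    list(newSiteSet(paste0("m", i), 1L, tab))
  })
  names(ss) <- paste0("m", 1:4)
  expect_warning(hyps <- enumerateCommonPharmacophores(
    ss, k = 4, minActiveFraction = 0.9), "no")
  expect_length(hyps, 0L)
})

test_that("variant codes are the sorted type letters", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 3))
  h <- newHypothesis(c("R", "A", "A", "A"), pos)
  expect_equal(variantCode(h), "AAAR")
  expect_equal(h@siteTypes, c("A", "A", "A", "R"))
  D <- intersiteDistances(h)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("matching the reference conformer onto its own hypothesis is exact", {
  fx <- plantedExactFixture(nActives = 3, seed = 5)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  best <- hyps[[1]]
  ref <- fx$siteSets[[best@referenceLigandId]][[best@referenceConfId]]
  m <- matchSitesToHypothesis(ref, best, minSites = 4)
  expect_equal(m$nMatched, 4L)
  expect_lt(m$rmsd, 1e-9)
})

test_that("matching recovers an applied rigid motion to 1e-6", {
  fx <- plantedExactFixture(nActives = 3, seed = 6)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  best <- hyps[[1]]
  ref <- fx$siteSets[[best@referenceLigandId]][[best@referenceConfId]]
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- transformSiteSet(ref, R, c(5, 5, 5))
  m <- matchSitesToHypothesis(moved, best, minSites = 3)
  expect_equal(m$nMatched, 4L)
  expect_lt(m$rmsd, 1e-6)
  # match quality is invariant to further rigid motions
  m2 <- matchSitesToHypothesis(
    transformSiteSet(moved, testRotation(8), c(-2, 9, 4)), best, 3)
  expect_equal(m2$rmsd, m$rmsd, tolerance = 1e-6)
})

test_that("too few type-compatible sites produce no match", {
  h <- newHypothesis(c("A", "A", "R"), rbind(c(0, 0, 0), c(3, 0, 0),
                                             c(0, 3, 0)))
  tab <- data.frame(type = c("A", "R"), x = c(0, 3), y = c(0, 0),
                    z = c(0, 0), dx = NA_real_, dy = NA_real_,
                    dz = NA_real_)
  tab$sourceAtoms <- I(as.list(1:2))
  expect_null(matchSitesToHypothesis(newSiteSet("q", 1L, tab), h, 3))
  expect_null(matchSitesToHypothesis(newSiteSet("q", 1L, emptySiteTable()),
                                     h, 3))
})

test_that("self-scoring gives unit components and no penalty without inactives", {
  fx <- plantedExactFixture(nActives = 2, seed = 9)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  best <- hyps[[1]]
  refId <- best@referenceLigandId
  scored <- scoreHypothesis(best, fx$siteSets[refId],
                            structures = fx$structures[refId])
  sc <- scored@score
  expect_equal(unname(sc["site"]), 1, tolerance = 1e-9)
  expect_equal(unname(sc["vector"]), 1, tolerance = 1e-9)
  expect_equal(unname(sc["volume"]), 1, tolerance = 1e-9)
  expect_equal(unname(sc["inactivePenalty"]), 0)
  expect_equal(unname(sc["adjusted"]), unname(sc["active"]))
  # determinism: scoring twice gives the same breakdown
  scored2 <- scoreHypothesis(best, fx$siteSets[refId],
                             structures = fx$structures[refId])
  expect_identical(scored@score, scored2@score)
  # zero matching actives is an upstream error
  far <- newHypothesis(c("P", "P", "P"),
                       rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0)))
  expect_error(scoreHypothesis(far, fx$siteSets), "zero actives|zero")
})

test_that("every emitted hypothesis meets the active-fraction floor", {
  gen <- generatePlantedSiteSets(nActives = 10, nDecoys = 0, seed = 13)
  hyps <- enumerateCommonPharmacophores(gen$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  for (h in hyps) expect_gte(h@nMatchingActives, ceiling(0.5 * 10))
})

test_that("survival filtering keeps the top fraction per variant", {
  fx <- plantedExactFixture(nActives = 4, seed = 15)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  scored <- scoreHypotheses(hyps, fx$siteSets, structures = fx$structures)
  kept <- filterTopHypotheses(scored, fraction = 0.2)
  expect_gte(length(kept), 1L)
  expect_lte(length(kept), length(scored))
  expect_equal(adjustedScore(kept[[1]]), adjustedScore(scored[[1]]))
})

test_that("hypotheses survive a JSON round trip", {
  fx <- plantedExactFixture(nActives = 3, seed = 17)
  hyps <- enumerateCommonPharmacophores(fx$siteSets, k = 4,
                                        minActiveFraction = 0.5)
  hyps <- scoreHypotheses(hyps, fx$siteSets, structures = fx$structures)
  path <- tempfile(fileext = ".json")
  writeHypothesesJSON(hyps, path)
  back <- readHypothesesJSON(path)
  expect_length(back, length(hyps))
  expect_equal(back[[1]]@sitePositions, hyps[[1]]@sitePositions,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(adjustedScore(back[[1]]), adjustedScore(hyps[[1]]),
               tolerance = 1e-12)
  expect_equal(back[[1]]@variant, hyps[[1]]@variant)
})
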