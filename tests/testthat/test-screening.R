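# Screening tests run on the geometry tier: a planted-pharmacophore model
# fitted on synthetic site sets, then applied to small libraries.

screenFixture <- function() {
  if (!is.null(.fixtureCache$screen)) return(.fixtureCache$screen)
  gen <- generatePlantedSiteSets(nActives = 12, nDecoys = 12, seed = 23)
  act <- assignSyntheticActivities(gen$labels, intercept = 4.2, bonus = 1.5,
                                   noiseSD = 0.3, seed = 23)
  hyps <- enumerateCommonPharmacophores(gen$siteSets[gen$labels], k = 4,
                                        minActiveFraction = 0.5)
  hyp <- hyps[[1]]
  ids <- names(gen$siteSets)
  matches <- lapply(ids, function(id)
    bestConformerMatch(gen$siteSets[[id]], hyp, 3L))
  names(matches) <- ids
  matched <- ids[!vapply(matches, is.null, logical(1))]
  posed <- lapply(matched, function(id) {
    m <- matches[[id]]
    st <- gen$structures[[id]][[m$confId]]
    list(coords = applyRigid(st$coords, m$rotation, m$translation),
         classes = st$classes, radii = st$radii)
  })
  names(posed) <- matched
  desc <- buildOccupancyDescriptors(posed,
                                    gridFrom = which(matched %in%
                                                       ids[gen$labels]))
  y <- stats::setNames(act$pIC50, ids)[matched]
  model <- fitQSAR(desc, y, factors = 3, hypothesisId = "AAAR.test")
  library_ <- lapply(ids, function(id)
    list(siteSets = gen$siteSets[[id]], structures = gen$structures[[id]]))
  names(library_) <- ids
  .fixtureCache$screen <- list(gen = gen, act = act, hyp = hyp,
                               model = model, library = library_,
                               fitted = stats::setNames(
                                 nipalsPLS(desc$X, y, 3)$fitted, matched))
  .fixtureCache$screen
}

test_that("screening preserves order, partitions matched/unmatched and calls hits at the threshold", {
  fx <- screenFixture()
  res <- screenLibrary(fx$library, fx$model, fx$hyp, minSites = 3,
                       threshold = 5.0)
  expect_equal(res$moleculeId, names(fx$library))
  expect_equal(res$rawOrder, seq_along(fx$library))
  # partition: matched-with-prediction + non-matched = library size
  expect_equal(sum(res$matched & is.finite(res$predictedPIC50)) +
                 sum(!res$matched), nrow(res))
  expect_true(all(!res$isHit[!res$matched]))
  expect_true(all(is.na(res$predictedPIC50[!res$matched])))
  # hits are exactly the matched molecules predicted at or above threshold
  expect_equal(res$isHit,
               res$matched & !is.na(res$predictedPIC50) &
                 res$predictedPIC50 >= 5.0)
  # pIC50 / IC50 duality
  ok <- res$matched
  expect_equal(res$predictedIC50M[ok], 10^(-res$predictedPIC50[ok]),
               tolerance = 1e-12)
  expect_error(screenLibrary(list(), fx$model, fx$hyp), "empty")
})

test_that("the model's reference ligand screens at its fitted value", {
  fx <- screenFixture()
  refId <- fx$hyp@referenceLigandId
  res <- screenLibrary(fx$library[refId], fx$model, fx$hyp, minSites = 3)
  expect_true(res$matched)
  expect_equal(res$predictedPIC50, unname(fx$fitted[refId]),
               tolerance = 1e-6)
  expect_equal(res$isHit, res$predictedPIC50 >= 5.0)
})

test_that("a molecule with no sites is a non hit", {
  fx <- screenFixture()
  lib <- list(empty = list(
    siteSets = list(newSiteSet("empty", 1L, emptySiteTable())),
    structures = list(list(coords = matrix(0, 1, 3), classes = "H",
                           radii = 1.7))))
  res <- screenLibrary(lib, fx$model, fx$hyp)
  expect_false(res$matched)
  expect_false(res$isHit)
})

test_that("raising the threshold never increases the hit count", {
  fx <- screenFixture()
  counts <- vapply(c(3, 4, 5, 6, 7), function(th) {
    computeHitRate(screenLibrary(fx$library, fx$model, fx$hyp,
                                 threshold = th))$hitCount
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("a prediction exactly at the threshold is a hit (>= convention)", {
  fx <- screenFixture()
  # force a model whose prediction for an off-grid pose is exactly the
  # threshold: zero coefficients, intercept 5.0
  m <- fx$model
  m@coefficients <- rep(0, length(m@coefficients))
  m@intercept <- 5.0
  refId <- fx$hyp@referenceLigandId
  res <- screenLibrary(fx$library[refId], m, fx$hyp, threshold = 5.0)
  expect_equal(res$predictedPIC50, 5.0, tolerance = 1e-12)
  expect_true(res$isHit)
})

test_that("hit rates reproduce printed-percentage arithmetic", {
  mk <- function(nHits, n) data.frame(isHit = seq_len(n) <= nHits)
  expect_equal(computeHitRate(mk(168, 1897))$hitRatePercent, 8.9)
  expect_equal(computeHitRate(mk(115, 1897))$hitRatePercent, 6.1)
  expect_equal(computeHitRate(mk(0, 500))$hitRatePercent, 0.0)
})

test_that("ranked results sort by prediction with unmatched molecules last", {
  fx <- screenFixture()
  res <- rankScreenResults(screenLibrary(fx$library, fx$model, fx$hyp))
  p <- res$predictedPIC50
  p[!is.finite(p)] <- min(p, na.rm = TRUE) - 1
  expect_true(all(diff(p) <= 1e-12))
  path <- tempfile(fileext = ".csv")
  writeScreenCSV(res, path)
  txt <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_true(all(txt$predictedIC50M[!txt$matched] == "non hit"))
})
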