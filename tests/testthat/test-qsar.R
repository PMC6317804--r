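test_that("atom classes follow the P > N > D > W > H > X precedence", {
  mset <- preparedTestSet()
  # carboxylate: both oxygens negative-ionic
  ac <- mset[["na_acetate"]]
  cls <- assignAtomClasses(ac)
  oIdx <- which(ac$atoms$element[as.integer(names(cls))] == "O")
  expect_true(all(cls[oIdx] == "N"))
  # amide N-H nitrogen is a donor
  bz <- mset[["benzamide"]]
  clsB <- assignAtomClasses(bz)
  nIdx <- which(bz$atoms$element[as.integer(names(clsB))] == "N")
  expect_equal(unname(clsB[nIdx]), "D")
  # benzene carbons are hydrophobic
  be <- mset[["benzene"]]
  expect_true(all(assignAtomClasses(be) == "H"))
  expect_true(all(unlist(lapply(moleculeIds(mset), function(id)
    assignAtomClasses(mset[[id]]))) %in% c("D", "H", "N", "P", "W", "X")))
})

test_that("cube occupancy follows the centre-within-radius rule", {
  # one carbon at the centre of a cube: that cube's bit set, a cube 3 A
  # away not set
  st <- list(coords = matrix(c(0, 0, 0), 1, 3), classes = "H", radii = 1.7)
  grid <- list(origin = c(-3.5, -0.5, -0.5), spacing = 1, dims = c(7L, 1L, 1L))
  keys <- PharmSafe3D:::.occupiedKeys(st, grid)
  cols <- PharmSafe3D:::.columnTable(keys, grid)
  expect_true(all(cols$class == "H"))
  expect_true(any(abs(cols$x) < 1e-9))            # centre cube occupied
  expect_true(all(abs(cols$x) <= 1.7))            # nothing beyond the radius
  expect_false(any(abs(cols$x - 3) < 1e-9))
})

test_that("descriptors are binary, identical molecules give identical rows, and translation is covariant", {
  qs <- generateSyntheticQSARSet(nTrain = 20, nTest = 5, seed = 2)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  expect_true(all(desc$X %in% c(0L, 1L)))
  dup <- c(qs$train$structures[1], qs$train$structures[1])
  d2 <- buildOccupancyDescriptors(dup, dropConstant = FALSE)
  expect_identical(d2$X[1, ], d2$X[2, ])
  # translating structures and grid together leaves the matrix unchanged
  shift <- c(5, -3, 2)
  moved <- lapply(qs$train$structures, function(s) {
    s$coords <- sweep(s$coords, 2, -shift)
    s
  })
  g2 <- desc$grid
  g2$origin <- g2$origin + shift
  descMoved <- buildOccupancyDescriptors(moved, grid = g2,
                                         dropConstant = FALSE)
  descFix <- buildOccupancyDescriptors(qs$train$structures, grid = desc$grid,
                                       dropConstant = FALSE)
  expect_identical(unname(descMoved$X), unname(descFix$X))
})

test_that("a pose outside the grid yields an all-zero row with a warning", {
  st <- list(list(coords = matrix(0, 1, 3), classes = "H", radii = 1.7),
             list(coords = matrix(100, 1, 3), classes = "H", radii = 1.7))
  grid <- list(origin = c(-2, -2, -2), spacing = 1, dims = c(4L, 4L, 4L))
  expect_warning(d <- buildOccupancyDescriptors(st, grid = grid,
                                                dropConstant = FALSE),
                 "no grid cube")
  expect_true(all(d$X[2, ] == 0L))
})

test_that("a noiseless linear combination of three columns is fit exactly", {
  set.seed(4)
  repeat {
    X <- matrix(rbinom(90, 1, 0.5), 30, 3)
    if (qr(cbind(1, X))$rank == 4L) break
  }
  y <- 1.2 * X[, 1] - 0.7 * X[, 2] + 0.4 * X[, 3] + 5
  model <- fitQSAR(X, y, factors = 3)
  st <- modelStats(model)
  expect_equal(st$R2, 1, tolerance = 1e-9)
  expect_lt(sum((y - predict(model, X))^2), 1e-9)
})

test_that("PLS at full rank reproduces ordinary least squares", {
  set.seed(42)
  repeat {
    X <- matrix(rbinom(100, 1, 0.5), 20, 5)
    if (qr(cbind(1, X))$rank == 6L) break
  }
  y <- rnorm(20)
  fit <- nipalsPLS(X, y, factors = 5)
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-8)
  expect_lt(abs(fit$intercept - ols[1]), 1e-8)
  expect_equal(fit$fitted, as.numeric(cbind(1, X) %*% ols),
               tolerance = 1e-8)
})

test_that("training SSE is non-increasing in the number of PLS factors", {
  qs <- generateSyntheticQSARSet(nTrain = 60, nTest = 5, seed = 6)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  sse <- vapply(1:5, function(a) {
    f <- nipalsPLS(desc$X, qs$train$y, a)
    sum((qs$train$y - f$fitted)^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("fit statistics satisfy their defining identities", {
  qs <- generateSyntheticQSARSet(nTrain = 50, nTest = 5, seed = 8)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  model <- fitQSAR(desc, qs$train$y, factors = 3)
  st <- modelStats(model)
  n <- st$n
  fitted <- predict(model, desc$X)
  sse <- sum((qs$train$y - fitted)^2)
  sst <- sum((qs$train$y - mean(qs$train$y))^2)
  expect_equal(st$R2 + sse / sst, 1, tolerance = 1e-9)
  expect_equal(st$F, (st$R2 / 3) / ((1 - st$R2) / (n - 3 - 1)),
               tolerance = 1e-9)
  expect_equal(st$SD, sqrt(sse / (n - 3 - 1)), tolerance = 1e-9)
  expect_equal(st$p, pf(st$F, 3, n - 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fitQSAR(desc, rep(1, nrow(desc$X)), factors = 3),
               "zero variance")
  expect_error(fitQSAR(desc, qs$train$y, factors = nrow(desc$X)),
               "factors")
})

test_that("training molecules are re-predicted at their fitted values", {
  qs <- generateSyntheticQSARSet(nTrain = 30, nTest = 5, seed = 10)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  model <- fitQSAR(desc, qs$train$y, factors = 3)
  fit <- nipalsPLS(desc$X, qs$train$y, 3)
  rows <- t(vapply(qs$train$structures, function(s) descriptorRow(model, s),
                   integer(nrow(model@columns))))
  expect_equal(predict(model, rows), fit$fitted, tolerance = 1e-9)
  # an aligned structure occupying no retained cube predicts the intercept
  emptyRow <- rep(0L, nrow(model@columns))
  expect_equal(predict(model, emptyRow), model@intercept, tolerance = 1e-12)
})

test_that("test statistics match hand-computed values on a 4-point set", {
  obs <- c(5.0, 6.0, 7.0, 8.0)
  pred <- c(5.2, 5.8, 7.4, 7.9)
  st <- qsarTestStats(obs, pred)
  expect_equal(st$RMSE, sqrt(mean((obs - pred)^2)), tolerance = 1e-12)
  expect_equal(st$Q2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_equal(st$pearsonR, cor(obs, pred), tolerance = 1e-12)
  # perfect predictions and constant shifts
  exact <- qsarTestStats(obs, obs)
  expect_equal(exact$RMSE, 0)
  expect_equal(exact$Q2, 1)
  expect_equal(exact$pearsonR, 1)
  shifted <- qsarTestStats(obs, obs + 0.5)
  expect_equal(shifted$pearsonR, 1, tolerance = 1e-12)
  expect_equal(shifted$RMSE, 0.5, tolerance = 1e-12)
  expect_error(qsarTestStats(obs[1:2], pred[1:2]), "at least 3")
})

test_that("stability is 1 for exact linear responses and seeded/deterministic", {
  set.seed(12)
  repeat {
    X <- matrix(rbinom(120, 1, 0.5), 40, 3)
    if (qr(cbind(1, X))$rank == 4L) break
  }
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] + 5  # exactly linear, full rank
  model <- fitQSAR(X, y, factors = 3)
  st <- estimateStability(model, X, y, rounds = 5, seed = 31)
  expect_equal(as.numeric(st), 1, tolerance = 1e-6)
  # seeding contract: the first rounds of a longer run repeat a shorter one
  s2 <- estimateStability(model, X, y, rounds = 2, seed = 7)
  s5 <- estimateStability(model, X, y, rounds = 5, seed = 7)
  expect_equal(attr(s2, "roundCorrelations"),
               attr(s5, "roundCorrelations")[1:2], tolerance = 1e-12)
  # pure-noise response on a wide binary design: clearly below 1
  qs <- generateSyntheticQSARSet(nTrain = 40, nTest = 5, seed = 12)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  set.seed(99)
  yNoise <- rnorm(nrow(desc$X))
  mN <- fitQSAR(desc, yNoise, factors = 3)
  expect_lt(as.numeric(estimateStability(mN, desc$X, yNoise, rounds = 8,
                                         seed = 5)), 0.95)
})

test_that("coefficient maps filter by class and round trip at full precision", {
  qs <- generateSyntheticQSARSet(nTrain = 30, nTest = 5, seed = 14)
  desc <- buildOccupancyDescriptors(qs$train$structures)
  model <- fitQSAR(desc, qs$train$y, factors = 3)
  map <- exportCoefficientMap(model)
  expect_equal(nrow(map), length(coef(model)))
  expect_equal(sum(map$coefficient), sum(coef(model)), tolerance = 1e-12)
  mapD <- exportCoefficientMap(model, byClass = "D")
  expect_true(all(mapD$class == "D"))
  expect_error(exportCoefficientMap(model, byClass = "Q"), "unknown")
  expect_true(all(map$sign[map$coefficient > 0] == "positive"))
  path <- tempfile(fileext = ".csv")
  writeCoefficientMap(map, path)
  back <- readCoefficientMap(path)
  expect_equal(back$coefficient, map$coefficient, tolerance = 1e-12)
  # model JSON round trip
  mpath <- tempfile(fileext = ".json")
  writeModelJSON(model, mpath)
  m2 <- readModelJSON(mpath)
  expect_equal(coef(m2), coef(model), tolerance = 1e-12)
  expect_equal(m2@intercept, model@intercept, tolerance = 1e-12)
  expect_equal(m2@gridDims, model@gridDims)
})
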