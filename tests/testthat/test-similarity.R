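test_that("radial fingerprints are deterministic and canonical", {
  fps <- radialFingerprint(c(a = "c1ccccc1O", b = "Oc1ccccc1",
                             c = "C", d = "c1ccccc1"))
  expect_identical(fps$a$bits, fps$b$bits)  # atom-order independent
  expect_lt(tanimotoSimilarity(fps$c, fps$d), 1)
  expect_gte(length(fps$c$bits), 1L)        # any molecule sets >= 1 bit
  fps2 <- radialFingerprint(c(a = "c1ccccc1O"))
  expect_identical(fps2$a$bits, fps$a$bits)
})

test_that("Tanimoto similarity follows set arithmetic", {
  expect_equal(tanimotoSimilarity(makeFingerprint(c(1, 3)),
                                  makeFingerprint(c(1, 2, 3))), 2 / 3)
  f <- makeFingerprint(c(5, 9, 100))
  expect_equal(tanimotoSimilarity(f, f), 1)
  expect_equal(tanimotoSimilarity(makeFingerprint(1:4),
                                  makeFingerprint(5:8)), 0)
  expect_error(tanimotoSimilarity(makeFingerprint(1, nBits = 64),
                                  makeFingerprint(1, nBits = 128)),
               "lengths differ")
  expect_error(tanimotoSimilarity(makeFingerprint(integer()),
                                  makeFingerprint(integer())), "empty")
  # symmetry, bounds and brute-force equality on random vectors
  set.seed(33)
  for (i in 1:25) {
    a <- makeFingerprint(sample(64, sample(1:20, 1)), nBits = 64)
    b <- makeFingerprint(sample(64, sample(1:20, 1)), nBits = 64)
    t1 <- tanimotoSimilarity(a, b)
    expect_equal(t1, tanimotoSimilarity(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    va <- seq_len(64) %in% a$bits
    vb <- seq_len(64) %in% b$bits
    expect_equal(t1, sum(va & vb) / sum(va | vb))
  }
})

test_that("pairwise similarity matrices carry correct summaries", {
  set.seed(7)
  fps <- lapply(1:5, function(i)
    makeFingerprint(sample(128, 10), nBits = 128, moleculeId = paste0("m", i)))
  M <- pairwiseSimilarityMatrix(fps, fps)
  expect_equal(unname(diag(M)), rep(1, 5))
  expect_equal(M, t(M), ignore_attr = TRUE)
  sm <- attr(M, "summary")
  expect_equal(unname(sm["max"]), max(M))
  expect_equal(unname(sm["min"]), min(M))
  one <- pairwiseSimilarityMatrix(fps[1], fps[2])
  expect_equal(as.numeric(one), tanimotoSimilarity(fps[[1]], fps[[2]]))
})

test_that("leader clustering handles degenerate and structured inputs", {
  same <- lapply(1:6, function(i)
    makeFingerprint(c(1, 5, 9), nBits = 32, moleculeId = paste0("m", i)))
  expect_equal(leaderCluster(same, 0.7)$k, 1L)
  disjoint <- lapply(1:5, function(i)
    makeFingerprint((i - 1) * 6 + 1:5, nBits = 64,
                    moleculeId = paste0("d", i)))
  expect_equal(leaderCluster(disjoint, 0.2)$k, 5L)
  # three planted groups: members share most bits within a group
  groups <- list(1:8, 20:27, 40:47)
  fps <- list()
  set.seed(5)
  for (g in seq_along(groups)) {
    for (j in 1:4) {
      bits <- c(groups[[g]], sample(55:64, 2))
      fps[[length(fps) + 1L]] <-
        makeFingerprint(bits, nBits = 64, moleculeId = paste0(g, "_", j))
    }
  }
  cl <- leaderCluster(fps, 0.5)
  expect_equal(cl$k, 3L)
  expect_equal(cl$assignment, rep(1:3, each = 4))
  # centroid maximizes mean within-cluster similarity (brute force)
  for (ci in 1:3) {
    members <- which(cl$assignment == ci)
    meanSim <- vapply(members, function(m) mean(vapply(members, function(o)
      tanimotoSimilarity(fps[[m]], fps[[o]]), numeric(1))), numeric(1))
    expect_equal(cl$centroids[ci],
                 fps[[members[which.max(meanSim)]]]$moleculeId)
  }
  expect_error(leaderCluster(list(), 0.5), "empty")
})

test_that("raising the leader threshold never reduces the cluster count", {
  set.seed(17)
  fps <- lapply(1:20, function(i)
    makeFingerprint(sample(64, 12), nBits = 64, moleculeId = paste0("m", i)))
  ks <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
               function(th) leaderCluster(fps, th)$k, integer(1))
  expect_true(all(diff(ks) >= 0L))
  found <- findClusterThreshold(fps, targetClusters = ks[3])
  expect_equal(found$k, ks[3])
})

test_that("splits partition the compounds under every strategy", {
  ids <- sprintf("c%03d", 1:268)
  sp <- makeSplit(ids, "random", seed = 1, trainSize = 141)
  expect_length(sp$train, 141L)
  expect_length(sp$test, 127L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(makeSplit(ids, "random", seed = 1, trainSize = 141), sp)

  all_ <- makeSplit(ids, "all_train")
  expect_length(all_$test, 0L)
  expect_setequal(all_$train, ids)

  actives <- ids[1:97]
  centroids <- ids[seq(1, 268, by = 5)]
  cc <- makeSplit(ids, "cluster_centroid", seed = 2, centroids = centroids,
                  activeIds = actives, nExtraActives = 27)
  expect_setequal(c(cc$train, cc$test), ids)
  expect_length(intersect(cc$train, cc$test), 0L)
  expect_length(cc$train, length(centroids) + 27L)
  expect_true(all(centroids %in% cc$train))
  expect_error(makeSplit(ids, "cluster_centroid", centroids = centroids,
                         activeIds = ids[1:5], nExtraActives = 27),
               "available")
  # seeded partition property across strategies and seeds
  for (seed in 1:5) {
    s <- makeSplit(ids, "random", seed = seed, trainFraction = 0.3)
    expect_setequal(c(s$train, s$test), ids)
    expect_length(intersect(s$train, s$test), 0L)
  }
})

test_that("confusion statistics and their complement identities hold", {
  st <- confusionStats(c(TP = 5, TN = 38, FP = 11, FN = 2))
  expect_equal(st$sensitivity, 100 * 5 / 7, tolerance = 1e-12)
  expect_equal(st$specificity, 100 * 38 / 49, tolerance = 1e-12)
  expect_equal(round(st$sensitivity, 1), 71.4)
  expect_equal(round(st$specificity, 1), 77.6)
  expect_equal(confusionStats(c(TP = 1, TN = 1, FP = 0, FN = 0)),
               list(sensitivity = 100, specificity = 100, FPR = 0, FNR = 0))
  expect_equal(confusionStats(c(TP = 0, TN = 3, FP = 2, FN = 5))$sensitivity,
               0)
  # undefined metrics are NA, never zero
  und <- confusionStats(c(TP = 0, TN = 4, FP = 1, FN = 0))
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$FNR))
  # property: identities over random non-degenerate draws
  set.seed(8)
  for (i in 1:1000) {
    cc <- c(TP = sample(1:50, 1), TN = sample(1:50, 1),
            FP = sample(0:50, 1), FN = sample(0:50, 1))
    st <- confusionStats(cc)
    expect_equal(st$sensitivity + st$FNR, 100, tolerance = 1e-9)
    expect_equal(st$specificity + st$FPR, 100, tolerance = 1e-9)
  }
})

test_that("confusion counts aggregate predicted/observed labels", {
  cc <- confusionCounts(c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(cc), c(1L, 1L, 1L, 1L))
})

test_that("similarity banding partitions records and flags follow-ups", {
  df <- data.frame(moleculeId = paste0("q", 1:6),
                   predicted = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                   observed = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
                   maxSimilarity = c(0.25, 0.05, 0.50, 0.12, 0.18, 0.31))
  out <- stratifyBySimilarity(df)
  expect_equal(out$perRecord$band[1], "[0.22, 0.29)")
  expect_equal(out$perRecord$band[3], ">= 0.29")
  expect_equal(out$perRecord$band[2], "< 0.1")
  # low-similarity positive and high-similarity negative get follow-up flags
  expect_true(out$perRecord$followUp[2])
  expect_true(out$perRecord$followUp[3])
  expect_false(out$perRecord$followUp[1])
  expect_equal(sum(out$perBand$n), nrow(df))      # banding is a partition
  expect_equal(sum(out$perBand$TP + out$perBand$TN + out$perBand$FP +
                     out$perBand$FN), nrow(df))
  expect_error(stratifyBySimilarity(transform(df, maxSimilarity = 1.2)),
               "\\[0, 1\\]")
  # every similarity value lands in exactly one band
  set.seed(3)
  many <- data.frame(moleculeId = paste0("r", 1:200),
                     predicted = rep(c(TRUE, FALSE), 100),
                     observed = rep(c(TRUE, FALSE), each = 100),
                     maxSimilarity = runif(200))
  outM <- stratifyBySimilarity(many)
  expect_equal(sum(outM$perBand$n), 200L)
})
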