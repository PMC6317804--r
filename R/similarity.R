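# Radial (circular) binary fingerprints, Tanimoto similarity, leader
# clustering, train/test split strategies, confusion statistics and
# similarity-banded confidence stratification.

#' Radial binary fingerprints
#'
#' Circular atom-environment fingerprints (Morgan algorithm) hashed to a
#' fixed-length bit vector; canonicalization makes the fingerprint
#' independent of input atom ordering.
#'
#' @param smiles Character vector of SMILES (or a
#'   \linkS4class{MoleculeSet}).
#' @param radius Environment radius in bonds (default 2).
#' @param nBits Bit-vector length (default 1024).
#' @return List of fingerprint objects: \code{moleculeId}, sorted integer
#'   \code{bits} (1-based set-bit positions), \code{nBits}, \code{radius}.
#' @export
radialFingerprint <- function(smiles, radius = 2, nBits = 1024) {
  ids <- NULL
  if (is(smiles, "MoleculeSet")) {
    ids <- moleculeIds(smiles)
    smiles <- vapply(records(smiles), function(r) r$smiles, character(1))
  }
  if (!length(smiles)) stop("no molecules to fingerprint")
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  res <- chemBackend("fingerprint", list(smiles = as.list(unname(smiles)),
                                         radius = radius, n_bits = nBits))
  out <- lapply(seq_along(res$results), function(i) {
    ri <- res$results[[i]]
    if (!isTRUE(ri$ok))
      stop("fingerprint failed for '", ids[i], "': ", ri$error)
    list(moleculeId = ids[i], bits = sort(as.integer(unlist(ri$bits))),
         nBits = nBits, radius = radius)
  })
  names(out) <- ids
  out
}

#' Construct a fingerprint object from set bits
#'
#' Useful for descriptor-derived binary profiles (e.g. occupancy rows) and
#' for tests.
#'
#' @param bits Integer vector of 1-based set-bit positions.
#' @param nBits Bit-vector length.
#' @param moleculeId Identifier.
#' @return A fingerprint object as in \code{\link{radialFingerprint}}.
#' @export
makeFingerprint <- function(bits, nBits = 1024, moleculeId = "") {
  stopifnot(all(bits >= 1), all(bits <= nBits))
  list(moleculeId = moleculeId, bits = sort(unique(as.integer(bits))),
       nBits = nBits, radius = NA_integer_)
}

#' Tanimoto similarity between two fingerprints
#'
#' \code{|a AND b| / |a OR b|} over the set bits.
#'
#' @param a,b Fingerprint objects of equal length.
#' @return Similarity in [0, 1].
#' @examples
#' tanimotoSimilarity(makeFingerprint(c(1, 3)), makeFingerprint(c(1, 2, 3)))
#' # 2/3
#' @export
tanimotoSimilarity <- function(a, b) {
  if (a$nBits != b$nBits) stop("fingerprint lengths differ")
  u <- length(union(a$bits, b$bits))
  if (u == 0L) stop("both fingerprints are empty")
  length(intersect(a$bits, b$bits)) / u
}

#' Pairwise Tanimoto similarity matrix between two fingerprint sets
#'
#' @param set1,set2 Lists of fingerprint objects.
#' @return Matrix (length(set1) x length(set2)) with a \code{summary}
#'   attribute holding the min and max over all pairs.
#' @export
pairwiseSimilarityMatrix <- function(set1, set2) {
  stopifnot(length(set1) > 0L, length(set2) > 0L)
  M <- matrix(0, length(set1), length(set2),
              dimnames = list(vapply(set1, `[[`, "", "moleculeId"),
                              vapply(set2, `[[`, "", "moleculeId")))
  for (i in seq_along(set1))
    for (j in seq_along(set2))
      M[i, j] <- tanimotoSimilarity(set1[[i]], set2[[j]])
  attr(M, "summary") <- c(min = min(M), max = max(M))
  M
}

#' Leader clustering of fingerprints
#'
#' Single-pass leader algorithm in deterministic input order: each molecule
#' joins the first existing cluster whose leader similarity is at least the
#' threshold, otherwise it founds a new cluster. The reported centroid of a
#' cluster is the member maximizing mean within-cluster similarity. Raising
#' the threshold can only increase the number of clusters.
#'
#' @param fps List of fingerprint objects.
#' @param threshold Similarity threshold in (0, 1).
#' @return List with \code{assignment} (cluster index per molecule),
#'   \code{leaders} and \code{centroids} (molecule ids), and \code{k}.
#' @export
leaderCluster <- function(fps, threshold) {
  if (!length(fps)) stop("empty fingerprint list")
  stopifnot(threshold > 0, threshold < 1)
  leaders <- integer()
  assignment <- integer(length(fps))
  for (i in seq_along(fps)) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (tanimotoSimilarity(fps[[i]], fps[[leaders[ci]]]) >= threshold) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      assignment[i] <- length(leaders)
    }
  }
  centroids <- vapply(seq_along(leaders), function(ci) {
    members <- which(assignment == ci)
    if (length(members) == 1L) return(members)
    meanSim <- vapply(members, function(m) {
      mean(vapply(members, function(o)
        tanimotoSimilarity(fps[[m]], fps[[o]]), numeric(1)))
    }, numeric(1))
    members[which.max(meanSim)]
  }, integer(1))
  ids <- vapply(fps, `[[`, "", "moleculeId")
  list(assignment = assignment, leaders = ids[leaders],
       centroids = ids[centroids], k = length(leaders))
}

#' Search the clustering threshold yielding a target cluster count
#'
#' Scans thresholds on a grid and returns the one whose leader clustering
#' gives the cluster count closest to the target (ties to the lower
#' threshold).
#'
#' @param fps List of fingerprint objects.
#' @param targetClusters Desired number of clusters.
#' @param grid Candidate thresholds (default \code{seq(0.05, 0.95, 0.01)}).
#' @return List with \code{threshold}, \code{k} and the \code{clustering}.
#' @export
findClusterThreshold <- function(fps, targetClusters,
                                 grid = seq(0.05, 0.95, by = 0.01)) {
  best <- NULL
  for (th in grid) {
    cl <- leaderCluster(fps, th)
    if (is.null(best) || abs(cl$k - targetClusters) <
        abs(best$k - targetClusters)) {
      best <- list(threshold = th, k = cl$k, clustering = cl)
    }
    if (cl$k >= targetClusters && !is.null(best) &&
        best$k == targetClusters) break
  }
  best
}

#' Split compounds into training and test sets
#'
#' Three strategies: \code{"random"} (seeded shuffle split at a given
#' training-set size or fraction), \code{"cluster_centroid"} (training set =
#' the cluster centroids plus a stated number of randomly selected
#' additional actives; everything else is test) and \code{"all_train"}
#' (empty test set). The result is always a partition.
#'
#' @param ids Character vector of molecule ids.
#' @param strategy One of \code{"random"}, \code{"cluster_centroid"},
#'   \code{"all_train"}.
#' @param seed Integer seed.
#' @param trainSize Training-set size (random strategy; alternatively use
#'   \code{trainFraction}).
#' @param trainFraction Training fraction (random strategy, default 0.5).
#' @param centroids Centroid ids (cluster_centroid strategy).
#' @param activeIds Ids of active compounds (cluster_centroid strategy).
#' @param nExtraActives Number of additional actives to add to the training
#'   set (cluster_centroid strategy).
#' @return List with character vectors \code{train} and \code{test}.
#' @export
makeSplit <- function(ids, strategy = c("random", "cluster_centroid",
                                        "all_train"),
                      seed = 1, trainSize = NULL, trainFraction = 0.5,
                      centroids = NULL, activeIds = NULL,
                      nExtraActives = 0) {
  strategy <- match.arg(strategy)
  ids <- as.character(ids)
  if (strategy == "all_train")
    return(list(train = ids, test = character()))
  set.seed(seed)
  if (strategy == "random") {
    if (is.null(trainSize)) trainSize <- round(trainFraction * length(ids))
    stopifnot(trainSize >= 1, trainSize <= length(ids))
    train <- sort(sample(ids, trainSize))
    return(list(train = train, test = setdiff(ids, train)))
  }
  # cluster_centroid
  stopifnot(!is.null(centroids))
  centroids <- intersect(as.character(centroids), ids)
  pool <- setdiff(intersect(as.character(activeIds), ids), centroids)
  if (nExtraActives > length(pool))
    stop("requested ", nExtraActives, " additional actives but only ",
         length(pool), " available")
  extra <- if (nExtraActives > 0) sort(sample(pool, nExtraActives))
           else character()
  train <- sort(unique(c(centroids, extra)))
  list(train = train, test = setdiff(ids, train))
}

#' Confusion statistics
#'
#' Sensitivity, specificity, false positive rate and false negative rate
#' (in percent) from confusion counts. The complement identities
#' \code{sensitivity + FNR = 100} and \code{specificity + FPR = 100} hold
#' exactly. A zero denominator yields \code{NA} (undefined), never 0.
#'
#' @param counts Named list or vector with \code{TP}, \code{TN}, \code{FP},
#'   \code{FN}.
#' @return Named list with \code{sensitivity}, \code{specificity},
#'   \code{FPR}, \code{FNR} (percent).
#' @examples
#' confusionStats(c(TP = 5, TN = 38, FP = 11, FN = 2))
#' @export
confusionStats <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero")
  posDen <- tp + fn
  negDen <- tn + fp
  list(sensitivity = if (posDen > 0) 100 * tp / posDen else NA_real_,
       specificity = if (negDen > 0) 100 * tn / negDen else NA_real_,
       FPR = if (negDen > 0) 100 * fp / negDen else NA_real_,
       FNR = if (posDen > 0) 100 * fn / posDen else NA_real_)
}

#' Confusion counts from predicted and observed labels
#'
#' @param predicted,observed Logical vectors (TRUE = active/positive).
#' @return Named vector TP, TN, FP, FN.
#' @export
confusionCounts <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  c(TP = sum(predicted & observed), TN = sum(!predicted & !observed),
    FP = sum(predicted & !observed), FN = sum(!predicted & observed))
}

#' Default similarity confidence bands
#'
#' Band edges 0.10 / 0.14 / 0.22 / 0.29 partition [0, 1] into five bands
#' used to stratify prediction confidence by the query compound's maximum
#' similarity to the training set.
#'
#' @return Numeric vector of band edges.
#' @export
defaultSimilarityBands <- function() c(0.10, 0.14, 0.22, 0.29)

#' Stratify screening results by similarity to the training set
#'
#' Assigns every query compound to exactly one similarity band (left-closed,
#' right-open intervals between the edges) and computes per-band confusion
#' counts. Interpretation notes follow safety-screening practice: positive
#' predictions in the high-similarity bands are trustworthy, negative
#' predictions in the lowest band are trustworthy, and in vitro follow-up is
#' recommended when a positive is predicted at low similarity or a negative
#' is predicted at high similarity.
#'
#' @param results Data frame with columns \code{moleculeId},
#'   \code{predicted} (logical), \code{observed} (logical) and
#'   \code{maxSimilarity} (in [0, 1]).
#' @param bands Band edges (strictly increasing, default
#'   \code{\link{defaultSimilarityBands}}).
#' @param lowSimilarity Edge below which predicted positives are flagged for
#'   follow-up (default 0.14).
#' @param highSimilarity Edge at or above which predicted negatives are
#'   flagged for follow-up (default 0.22).
#' @return List with \code{perRecord} (band label and follow-up flag per
#'   compound) and \code{perBand} (confusion counts and confidence note per
#'   band).
#' @export
stratifyBySimilarity <- function(results, bands = defaultSimilarityBands(),
                                 lowSimilarity = 0.14,
                                 highSimilarity = 0.22) {
  stopifnot(all(diff(bands) > 0), all(bands >= 0), all(bands <= 1))
  s <- results$maxSimilarity
  if (any(s < 0 | s > 1))
    stop("similarity values must lie in [0, 1]")
  edges <- c(0, bands, 1 + 1e-9)
  bandIdx <- findInterval(s, edges, rightmost.closed = FALSE)
  labels <- c(paste0("< ", bands[1]),
              paste0("[", utils::head(bands, -1), ", ",
                     utils::tail(bands, -1), ")"),
              paste0(">= ", utils::tail(bands, 1)))
  perRecord <- results
  perRecord$band <- labels[bandIdx]
  perRecord$followUp <-
    (results$predicted & s < lowSimilarity) |
    (!results$predicted & s >= highSimilarity)
  perBand <- do.call(rbind, lapply(seq_along(labels), function(b) {
    inB <- bandIdx == b
    cc <- confusionCounts(results$predicted[inB], results$observed[inB])
    note <- if (b >= length(labels) - 1L)
      "positive predictions high confidence"
    else if (b == 1L) "negative predictions high confidence"
    else "intermediate similarity: expect false calls"
    data.frame(band = labels[b], n = sum(inB), TP = cc["TP"], TN = cc["TN"],
               FP = cc["FP"], FN = cc["FN"], note = note,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(perRecord = perRecord, perBand = perBand)
}
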