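# Virtual screening of a prepared library against a hypothesis + QSAR
# model, with activity-threshold hit calling.

#' Screen a library against a hypothesis and QSAR model
#'
#' Each library molecule is matched against the hypothesis over all its
#' conformers; matching molecules (at least \code{minSites} matched sites)
#' are posed into the hypothesis frame and their pIC50 predicted with the
#' model. Compounds predicted at or above the threshold are labeled hits.
#' Non-matching molecules carry no prediction and are never hits
#' ("non hit" convention).
#'
#' @param library Named list (molecule id) with elements \code{siteSets}
#'   (list of per-conformer \linkS4class{SiteSet}) and \code{structures}
#'   (list of per-conformer structures), as produced by
#'   \code{\link{screenInput}} or the synthetic generator.
#' @param model A \linkS4class{CubeQSARModel}.
#' @param hyp The aligning \linkS4class{PharmHypothesis}.
#' @param minSites Minimum matched sites (default 3).
#' @param threshold Hit-calling threshold on the pIC50 scale (default 5.0;
#'   hits are \code{predicted >= threshold}).
#' @return Data frame in library order with columns \code{moleculeId},
#'   \code{rawOrder}, \code{matched}, \code{nMatchedSites},
#'   \code{predictedPIC50}, \code{predictedIC50M} (\code{10^-pIC50}, molar)
#'   and \code{isHit}.
#' @export
screenLibrary <- function(library, model, hyp, minSites = 3L,
                          threshold = 5.0) {
  if (!length(library)) stop("empty screening library")
  rows <- lapply(seq_along(library), function(i) {
    entry <- library[[i]]
    pr <- predictActivity(model, entry$siteSets, entry$structures, hyp,
                          minSites)
    data.frame(moleculeId = names(library)[i] %||% as.character(i),
               rawOrder = i, matched = pr$matched,
               nMatchedSites = pr$nMatched,
               predictedPIC50 = pr$predicted,
               predictedIC50M = 10^(-pr$predicted),
               isHit = isTRUE(pr$matched) && is.finite(pr$predicted) &&
                 pr$predicted >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hit count and hit rate of screening results
#'
#' @param results Data frame from \code{\link{screenLibrary}} (or any data
#'   frame with a logical \code{isHit} column).
#' @return List with \code{hitCount} and \code{hitRatePercent}
#'   (\code{100 * hits / n}, reported to one decimal).
#' @examples
#' res <- data.frame(isHit = c(TRUE, FALSE, FALSE, TRUE))
#' computeHitRate(res)  # 2 hits, 50.0 %
#' @export
computeHitRate <- function(results) {
  if (!nrow(results)) stop("empty screening results")
  hits <- sum(results$isHit)
  list(hitCount = as.integer(hits),
       hitRatePercent = round(100 * hits / nrow(results), 1))
}

#' Rank screening results
#'
#' Sorted by predicted pIC50 descending with a stable tie-break on molecule
#' id; non-matching compounds sort last. The original library order is
#' preserved in \code{rawOrder}.
#'
#' @param results Data frame from \code{\link{screenLibrary}}.
#' @return The re-ordered data frame.
#' @export
rankScreenResults <- function(results) {
  key <- results$predictedPIC50
  key[!is.finite(key)] <- -Inf
  results[order(-key, results$moleculeId), , drop = FALSE]
}

#' Write screening results in reporting form
#'
#' Non-matching molecules are rendered as \code{"non hit"} in the predicted
#' IC50 column.
#'
#' @param results Data frame from \code{\link{screenLibrary}}.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
writeScreenCSV <- function(results, path) {
  out <- results
  out$predictedIC50M <- ifelse(out$matched,
                               formatC(out$predictedIC50M, format = "e",
                                       digits = 4),
                               "non hit")
  out$predictedPIC50 <- ifelse(out$matched,
                               formatC(out$predictedPIC50, format = "f",
                                       digits = 4),
                               "non hit")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assemble screening input from perception output
#'
#' @param mset A prepared \linkS4class{MoleculeSet}.
#' @param siteSets Output of \code{\link{perceiveSites}} on \code{mset}.
#' @return Named list suitable for \code{\link{screenLibrary}}.
#' @export
screenInput <- function(mset, siteSets) {
  out <- lapply(moleculeIds(mset), function(id) {
    r <- mset[[id]]
    list(siteSets = siteSets[[id]],
         structures = lapply(r$conformers,
                             function(cf) atomStructure(r, cf$confId)))
  })
  names(out) <- moleculeIds(mset)
  out
}
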