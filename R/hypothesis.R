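# Common-pharmacophore hypothesis engine.
#
# Enumeration canonicalizes every k-site combination of every active
# conformer as (variant code, sorted intersite-distance vector), then groups
# the signatures per variant with a deterministic leader pass in distance
# space (Chebyshev radius 1.5 x the bin width; a combination may support
# several nearby leaders, which makes the grouping robust to combinations
# straddling a partition boundary). A group survives when it covers at least
# the configured fraction of active molecules; its representative geometry
# is the member combination nearest the group mean, so each hypothesis is
# instantiated from a real conformer (its reference ligand). A final pass
# verifies, with the production matcher, that enough actives attain a full
# k-site match within tolerance.

#' Enumerate common pharmacophore hypotheses from actives
#'
#' @param activeSiteSets Named list (molecule id) of lists of
#'   \linkS4class{SiteSet} objects (one per conformer), as returned by
#'   \code{\link{perceiveSites}} or the synthetic generator.
#' @param k Number of hypothesis sites (3 to 7).
#' @param minActiveFraction Minimum fraction of active molecules a
#'   hypothesis must match on all k sites (default 0.5).
#' @param matchTolerance Per-site tolerance in Angstrom after superposition
#'   (default 2.0).
#' @param distRange Admissible intersite distance range in Angstrom
#'   (default c(2, 20)).
#' @param binWidth Distance binning resolution in Angstrom (default 1).
#' @param maxSitesPerConf Cap on sites considered per conformer (first
#'   sites in perception order; default 12).
#' @param maxConfPerMolecule Cap on conformers considered per molecule
#'   (default 5).
#' @param maxCandidates Cap on candidate bin cells verified with the full
#'   matcher, strongest coverage first (default 60).
#' @param maxHypotheses Cap on returned hypotheses (default 25).
#' @return A list of \linkS4class{PharmHypothesis} objects ordered by number
#'   of matching actives (descending), then variant code, then reference
#'   ligand id. Empty, with a warning, when no candidate survives.
#' @export
enumerateCommonPharmacophores <- function(activeSiteSets, k = 4,
                                          minActiveFraction = 0.5,
                                          matchTolerance = 2.0,
                                          distRange = c(2, 20),
                                          binWidth = 1,
                                          maxSitesPerConf = 12,
                                          maxConfPerMolecule = 5,
                                          maxCandidates = 60,
                                          maxHypotheses = 25) {
  stopifnot(k >= 3, k <= 7, minActiveFraction > 0, minActiveFraction <= 1)
  if (length(activeSiteSets) < 2L)
    stop("at least 2 active molecules are required")
  nActives <- length(activeSiteSets)
  need <- ceiling(minActiveFraction * nActives)

  combos <- list()   # each: molecule, confIdx, siteIdx, code, sig
  for (mol in names(activeSiteSets)) {
    confs <- utils::head(activeSiteSets[[mol]], maxConfPerMolecule)
    for (ci in seq_along(confs)) {
      ss <- confs[[ci]]
      s <- sites(ss)
      if (nrow(s) > maxSitesPerConf) s <- s[seq_len(maxSitesPerConf), ]
      if (nrow(s) < k) next
      pos <- as.matrix(s[, c("x", "y", "z")])
      D <- as.matrix(stats::dist(pos))
      idxCombos <- utils::combn(nrow(s), k, simplify = FALSE)
      for (cmb in idxCombos) {
        d <- D[cmb, cmb][upper.tri(diag(k))]
        if (any(d < distRange[1]) || any(d > distRange[2])) next
        combos[[length(combos) + 1L]] <- list(
          molecule = mol, confIdx = ci, siteIdx = cmb,
          code = paste(sort(s$type[cmb]), collapse = ""),
          sig = sort(d))
      }
    }
  }
  if (!length(combos)) {
    warning("no k-site combinations within the distance range")
    return(list())
  }

  codes <- vapply(combos, `[[`, "", "code")
  molsOf <- vapply(combos, `[[`, "", "molecule")
  sigs <- do.call(rbind, lapply(combos, `[[`, "sig"))
  radius <- 1.5 * binWidth

  groups <- list()
  for (code in sort(unique(codes))) {
    idx <- which(codes == code)
    S <- sigs[idx, , drop = FALSE]
    # leader pass: a combination founds a new leader when it is farther
    # than the radius (Chebyshev) from every existing leader
    leaderRows <- integer()
    for (j in seq_len(nrow(S))) {
      if (!length(leaderRows)) {
        leaderRows <- j
        next
      }
      dmax <- apply(abs(S[leaderRows, , drop = FALSE] -
                          matrix(S[j, ], length(leaderRows), ncol(S),
                                 byrow = TRUE)), 1L, max)
      if (all(dmax > radius)) leaderRows <- c(leaderRows, j)
    }
    # membership: every combination within the radius of a leader supports
    # that leader (multi-assignment)
    for (lr in leaderRows) {
      dmax <- apply(abs(S - matrix(S[lr, ], nrow(S), ncol(S), byrow = TRUE)),
                    1L, max)
      groups[[paste(code, lr)]] <- idx[dmax <= radius]
    }
  }
  coverage <- vapply(groups, function(m) length(unique(molsOf[m])),
                     integer(1))
  groups <- groups[coverage >= need]
  if (!length(groups)) {
    warning("no hypothesis reached the active-fraction threshold")
    return(list())
  }
  groups <- groups[order(-coverage[coverage >= need], names(groups))]

  hyps <- list()
  seenRep <- character()
  nVerified <- 0L
  for (members in groups) {
    if (nVerified >= maxCandidates || length(hyps) >= maxHypotheses) break
    meanSig <- colMeans(sigs[members, , drop = FALSE])
    devs <- apply(sigs[members, , drop = FALSE], 1L,
                  function(sg) sqrt(sum((sg - meanSig)^2)))
    rep_ <- combos[[members[which.min(devs)]]]
    repKey <- paste(rep_$molecule, rep_$confIdx,
                    paste(rep_$siteIdx, collapse = ","))
    if (repKey %in% seenRep) next
    seenRep <- c(seenRep, repKey)
    ss <- activeSiteSets[[rep_$molecule]][[rep_$confIdx]]
    s <- sites(ss)[rep_$siteIdx, , drop = FALSE]
    hyp <- newHypothesis(
      siteTypes = s$type,
      sitePositions = as.matrix(s[, c("x", "y", "z")]),
      siteDirections = as.matrix(s[, c("dx", "dy", "dz")]),
      referenceLigandId = ss@moleculeId,
      referenceConfId = ss@confId,
      matchTolerance = matchTolerance)
    nVerified <- nVerified + 1L
    nMatch <- sum(vapply(activeSiteSets, function(confs) {
      any(vapply(confs, function(cs)
        !is.null(matchSitesToHypothesis(cs, hyp, minSites = k)),
        logical(1)))
    }, logical(1)))
    if (nMatch < need) next
    hyp@nMatchingActives <- as.integer(nMatch)
    hyps[[length(hyps) + 1L]] <- hyp
  }
  if (!length(hyps)) {
    warning("no hypothesis reached the active-fraction threshold")
    return(list())
  }
  ord <- order(-vapply(hyps, function(h) h@nMatchingActives, integer(1)),
               vapply(hyps, function(h) h@variant, character(1)),
               vapply(hyps, function(h) h@referenceLigandId, character(1)))
  hyps[ord]
}

#' Match a site set onto a hypothesis
#'
#' Finds the type-compatible partial assignment of hypothesis sites to query
#' sites with at least \code{minSites} matched sites that minimizes the RMSD
#' after rigid (Kabsch) superposition, subject to every matched pair lying
#' within the hypothesis tolerance after the fit. Ties are broken by larger
#' match size, then lower RMSD. Candidate assignments are pruned by pairwise
#' intersite-distance compatibility before any superposition is attempted.
#'
#' @param siteSet A \linkS4class{SiteSet} (the query).
#' @param hyp A \linkS4class{PharmHypothesis}.
#' @param minSites Minimum number of matched sites (>= 3).
#' @return \code{NULL} when no qualifying assignment exists, else a list with
#'   \code{moleculeId}, \code{confId}, \code{assignment} (hypothesis site ->
#'   query site row index, \code{NA} when unmatched), \code{nMatched},
#'   \code{rmsd}, \code{rotation} and \code{translation} mapping query
#'   coordinates into the hypothesis frame.
#' @export
matchSitesToHypothesis <- function(siteSet, hyp, minSites = 3L) {
  k <- length(hyp@siteTypes)
  stopifnot(minSites >= 3L, minSites <= k)
  s <- sites(siteSet)
  if (!nrow(s)) return(NULL)
  qPos <- as.matrix(s[, c("x", "y", "z")])
  qD <- as.matrix(stats::dist(qPos))
  hPos <- hyp@sitePositions
  hD <- as.matrix(stats::dist(hPos))
  tol <- hyp@matchTolerance
  candidates <- lapply(hyp@siteTypes, function(tp) which(s$type == tp))

  best <- NULL
  for (m in seq(k, minSites)) {
    subsets <- utils::combn(k, m, simplify = FALSE)
    for (sub in subsets) {
      if (any(lengths(candidates[sub]) == 0L)) next
      assignments <- .enumerateAssignments(sub, candidates, hD, qD, 2 * tol)
      for (asg in assignments) {
        fit <- kabschFit(qPos[asg, , drop = FALSE],
                         hPos[sub, , drop = FALSE])
        posed <- applyRigid(qPos[asg, , drop = FALSE],
                            fit$rotation, fit$translation)
        perSite <- sqrt(rowSums((posed - hPos[sub, , drop = FALSE])^2))
        if (any(perSite > tol)) next
        if (is.null(best) || fit$rmsd < best$rmsd) {
          assignment <- rep(NA_integer_, k)
          assignment[sub] <- asg
          best <- list(moleculeId = siteSet@moleculeId,
                       confId = siteSet@confId,
                       assignment = assignment, nMatched = m,
                       rmsd = fit$rmsd, rotation = fit$rotation,
                       translation = fit$translation)
        }
      }
    }
    if (!is.null(best)) break  # prefer the largest match size
  }
  best
}

# Backtracking enumeration of injective type-compatible assignments with
# pairwise distance pruning: |d_hyp(i,j) - d_query(a_i,a_j)| <= maxDev.
.enumerateAssignments <- function(sub, candidates, hD, qD, maxDev) {
  out <- list()
  m <- length(sub)
  asg <- integer(m)
  recurse <- function(level) {
    if (level > m) {
      out[[length(out) + 1L]] <<- asg
      return(invisible())
    }
    hi <- sub[level]
    for (q in candidates[[hi]]) {
      if (q %in% asg[seq_len(level - 1L)]) next
      okDist <- TRUE
      for (prev in seq_len(level - 1L)) {
        if (abs(hD[sub[prev], hi] - qD[asg[prev], q]) > maxDev) {
          okDist <- FALSE
          break
        }
      }
      if (!okDist) next
      asg[level] <<- q
      recurse(level + 1L)
    }
  }
  recurse(1L)
  out
}

#' Best match over the conformers of one molecule
#'
#' @param confSets List of \linkS4class{SiteSet} objects (one per conformer).
#' @param hyp A \linkS4class{PharmHypothesis}.
#' @param minSites Minimum matched sites.
#' @return The best match (max matched sites, then min RMSD) or \code{NULL}.
#' @export
bestConformerMatch <- function(confSets, hyp, minSites = 3L) {
  best <- NULL
  for (cs in confSets) {
    m <- matchSitesToHypothesis(cs, hyp, minSites)
    if (is.null(m)) next
    if (is.null(best) || m$nMatched > best$nMatched ||
        (m$nMatched == best$nMatched && m$rmsd < best$rmsd))
      best <- m
  }
  best
}

#' Score a hypothesis against actives and inactives
#'
#' The active score is the weighted sum of three components, each averaged
#' over the active molecules that match the hypothesis on all k sites:
#' a site score \code{1 - RMSD / tolerance} (clamped to [0, 1]), a vector
#' score (cosine alignment of matched directed sites mapped to [0, 1];
#' absolute cosine for axial ring normals), and a van-der-Waals
#' volume-overlap Tanimoto against the reference pose. Hypotheses that also
#' match inactive molecules are penalized by the analogous score over
#' matching inactives:
#' \code{adjusted = active - w_inactive * inactivePenalty}.
#'
#' @param hyp A \linkS4class{PharmHypothesis}.
#' @param activeSiteSets,inactiveSiteSets Named lists (molecule id) of lists
#'   of \linkS4class{SiteSet} objects.
#' @param structures Optional named list (molecule id) of lists (one per
#'   conformer) of structures (\code{coords}, \code{radii}) used for the
#'   volume term; when absent, site positions with a 2.0 Angstrom radius
#'   stand in.
#' @param weights Named numeric weights \code{site}, \code{vector},
#'   \code{volume}, \code{inactive} (all default 1, the standard setting).
#' @return The hypothesis with its \code{score} slot filled: components
#'   \code{site}, \code{vector}, \code{volume} in [0, 1], \code{active},
#'   \code{inactivePenalty} and \code{adjusted}.
#' @export
scoreHypothesis <- function(hyp, activeSiteSets, inactiveSiteSets = list(),
                            structures = NULL,
                            weights = c(site = 1, vector = 1, volume = 1,
                                        inactive = 1)) {
  k <- length(hyp@siteTypes)
  matchSide <- function(siteSets) {
    ms <- lapply(names(siteSets), function(mol)
      bestConformerMatch(siteSets[[mol]], hyp, minSites = k))
    names(ms) <- names(siteSets)
    ms[!vapply(ms, is.null, logical(1))]
  }
  actMatches <- matchSide(activeSiteSets)
  if (!length(actMatches))
    stop("hypothesis matches zero actives; filter upstream")
  inactMatches <- matchSide(inactiveSiteSets)
  refPose <- .posedStructure(hyp@referenceLigandId, hyp@referenceConfId,
                             activeSiteSets, structures, hyp)
  scoreSide <- function(siteSets, matches) {
    comp <- matrix(numeric(0), ncol = 3)
    for (mol in names(matches)) {
      m <- matches[[mol]]
      ss <- siteSets[[mol]][[m$confId]]
      siteScore <- max(0, min(1, 1 - m$rmsd / hyp@matchTolerance))
      vecScore <- .vectorScore(hyp, ss, m)
      volScore <- .volumeScore(mol, m, siteSets, structures, refPose)
      comp <- rbind(comp, c(siteScore, vecScore, volScore))
    }
    comp
  }
  act <- scoreSide(activeSiteSets, actMatches)
  inact <- scoreSide(inactiveSiteSets, inactMatches)
  actMeans <- colMeans(act)
  activeScore <- sum(weights[c("site", "vector", "volume")] * actMeans)
  inactPenalty <- if (nrow(inact))
    sum(weights[c("site", "vector", "volume")] * colMeans(inact)) else 0
  hyp@score <- c(site = actMeans[[1]], vector = actMeans[[2]],
                 volume = actMeans[[3]], active = activeScore,
                 inactivePenalty = inactPenalty,
                 adjusted = activeScore -
                   unname(weights["inactive"]) * inactPenalty)
  hyp
}

.vectorScore <- function(hyp, siteSet, m) {
  s <- sites(siteSet)
  vals <- numeric()
  for (i in which(!is.na(m$assignment))) {
    hDir <- hyp@siteDirections[i, ]
    if (any(is.na(hDir))) next
    q <- m$assignment[i]
    qDir <- as.numeric(s[q, c("dx", "dy", "dz")])
    if (any(is.na(qDir))) next
    qDirPosed <- as.numeric(m$rotation %*% qDir)
    cosv <- sum(qDirPosed * hDir)
    vals <- c(vals, if (hyp@siteTypes[i] == "R") abs(cosv)
              else (cosv + 1) / 2)
  }
  if (!length(vals)) return(1)
  mean(pmax(0, pmin(1, vals)))
}

.posedStructure <- function(mol, confId, siteSets, structures, hyp = NULL) {
  if (!is.null(structures) && !is.null(structures[[mol]])) {
    st <- structures[[mol]][[confId]]
    return(list(coords = st$coords, radii = st$radii %||% 1.7))
  }
  if (!is.null(siteSets[[mol]]))
    return(list(coords = sitePositions(siteSets[[mol]][[confId]]),
                radii = 2.0))
  # reference ligand absent from the scored sets: the hypothesis's own
  # site geometry stands in as the reference pose
  list(coords = hyp@sitePositions, radii = 2.0)
}

.volumeScore <- function(mol, m, siteSets, structures, refPose) {
  st <- .posedStructure(mol, m$confId, siteSets, structures, NULL)
  posed <- applyRigid(st$coords, m$rotation, m$translation)
  volumeOverlapTanimoto(posed, refPose$coords, st$radii, refPose$radii)
}

#' Score a list of hypotheses
#'
#' @inheritParams scoreHypothesis
#' @param hyps List of \linkS4class{PharmHypothesis} objects.
#' @return The list with scores filled, ordered by adjusted score
#'   (descending, ties by variant then reference id).
#' @export
scoreHypotheses <- function(hyps, activeSiteSets, inactiveSiteSets = list(),
                            structures = NULL,
                            weights = c(site = 1, vector = 1, volume = 1,
                                        inactive = 1)) {
  scored <- lapply(hyps, scoreHypothesis, activeSiteSets = activeSiteSets,
                   inactiveSiteSets = inactiveSiteSets,
                   structures = structures, weights = weights)
  ord <- order(-vapply(scored, adjustedScore, numeric(1)),
               vapply(scored, variantCode, character(1)),
               vapply(scored, function(h) h@referenceLigandId, character(1)))
  scored[ord]
}

#' Keep the top fraction of scored hypotheses per variant
#'
#' Survival filtering: within each variant code, only the best-scoring
#' 10--20 percent of hypotheses (at least one) move forward to QSAR
#' modeling.
#'
#' @param hyps Scored hypotheses.
#' @param fraction Fraction to keep per variant (default 0.2).
#' @return The surviving hypotheses, ordered as in
#'   \code{\link{scoreHypotheses}}.
#' @export
filterTopHypotheses <- function(hyps, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  codes <- vapply(hyps, variantCode, character(1))
  keep <- logical(length(hyps))
  for (code in unique(codes)) {
    idx <- which(codes == code)
    scoresHere <- vapply(hyps[idx], adjustedScore, numeric(1))
    nKeep <- max(1L, ceiling(fraction * length(idx)))
    keep[idx[order(-scoresHere)[seq_len(nKeep)]]] <- TRUE
  }
  hyps[keep]
}

#' Serialize hypotheses to JSON
#'
#' @param hyps List of \linkS4class{PharmHypothesis} objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeHypothesesJSON <- function(hyps, path) {
  payload <- lapply(hyps, function(h) list(
    variant = h@variant, siteTypes = h@siteTypes,
    sitePositions = h@sitePositions, siteDirections = h@siteDirections,
    referenceLigandId = h@referenceLigandId,
    referenceConfId = h@referenceConfId,
    matchTolerance = h@matchTolerance,
    score = as.list(h@score), nMatchingActives = h@nMatchingActives))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Read hypotheses from JSON
#' @param path Path written by \code{\link{writeHypothesesJSON}}.
#' @return List of \linkS4class{PharmHypothesis} objects.
#' @export
readHypothesesJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(pl) {
    asMat <- function(x) do.call(rbind, lapply(x, function(r)
      as.numeric(unlist(lapply(r, function(v) if (is.null(v)) NA else v)))))
    h <- newHypothesis(
      siteTypes = as.character(unlist(pl$siteTypes)),
      sitePositions = asMat(pl$sitePositions),
      siteDirections = asMat(pl$siteDirections),
      referenceLigandId = pl$referenceLigandId,
      referenceConfId = pl$referenceConfId,
      matchTolerance = pl$matchTolerance)
    if (length(pl$score))
      h@score <- unlist(pl$score)
    h@nMatchingActives <- as.integer(pl$nMatchingActives)
    h
  })
}
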