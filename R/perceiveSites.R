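# Pharmacophore site perception: typed, positioned, optionally directed
# feature points derived from SMARTS matches on each conformer.
#
# Placement rules:
#   atom           - the site sits on the first atom of the pattern match
#   group_centroid - the site sits at the centroid of the matched atoms;
#                    hydrophobe (H) matches are additionally merged into
#                    contiguous groups within 2 bonds before the centroid
#   ring_centroid  - the site sits at the aromatic ring centroid
# Direction rules:
#   D - one site per donated hydrogen, direction along the X-H bond
#   A - a single idealized lone-pair bisector (the negative resultant of
#       the bond vectors); axially symmetric acceptors get no direction
#   R - the ring plane normal (axial: defined up to sign; a deterministic
#       sign convention keeps perception idempotent)

#' Perceive pharmacophore sites on prepared molecules
#'
#' Runs the feature-definition SMARTS over each molecule and converts
#' matches into typed 3D sites on every conformer.
#'
#' @param mset A prepared \linkS4class{MoleculeSet} (conformers present).
#' @param defs Feature definitions from
#'   \code{\link{defaultFeatureDefinitions}} or
#'   \code{\link{loadFeatureDefinitions}}.
#' @return A named list (molecule id) of lists of \linkS4class{SiteSet}
#'   objects, one per conformer. Molecules with zero sites yield empty
#'   SiteSets, not errors.
#' @export
perceiveSites <- function(mset, defs = defaultFeatureDefinitions()) {
  if (!length(mset)) return(list())
  smartsMap <- as.list(defs$smarts)
  names(smartsMap) <- paste0("f", seq_len(nrow(defs)))
  smartsMap <- lapply(smartsMap, list)
  mols <- lapply(records(mset), function(r) list(id = r$id, smiles = r$smiles))
  res <- chemBackend("embed", list(molecules = unname(mols), n_conf = 0,
                                   smarts = smartsMap))$results
  out <- list()
  recs <- records(mset)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    ri <- res[[i]]
    if (!isTRUE(ri$ok))
      stop("site perception failed for '", r$id, "': ", ri$error)
    matches <- lapply(ri$matches, function(m)
      lapply(m, function(v) as.integer(unlist(v))))
    elements <- vapply(ri$atoms, function(a) a$element, character(1))
    bonds <- do.call(rbind, lapply(ri$bonds, function(b)
      c(as.integer(b[[1]]), as.integer(b[[2]]))))
    adj <- .adjacencyList(length(elements), bonds)
    confSets <- lapply(r$conformers, function(cf) {
      tab <- .sitesForConformer(cf$coords, elements, adj, defs, matches)
      newSiteSet(r$id, cf$confId, tab)
    })
    out[[r$id]] <- confSets
  }
  out
}

.adjacencyList <- function(nAtoms, bonds) {
  adj <- vector("list", nAtoms)
  if (!is.null(bonds) && nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Merge atom index sets whose members are within `maxBonds` bonds of each
# other (single-linkage over the bond graph).
.mergeWithinBonds <- function(atomSets, adj, maxBonds = 2L) {
  if (length(atomSets) <= 1L) return(atomSets)
  nearby <- function(a, b) {
    # BFS depth cap from each atom of a
    for (start in a) {
      depth <- stats::setNames(0L, start)
      frontier <- start
      for (d in seq_len(maxBonds)) {
        frontier <- unique(unlist(adj[frontier]))
        frontier <- setdiff(frontier, as.integer(names(depth)))
        if (!length(frontier)) break
        depth <- c(depth, stats::setNames(rep(d, length(frontier)), frontier))
        if (any(frontier %in% b)) return(TRUE)
      }
      if (any(start %in% b)) return(TRUE)
    }
    FALSE
  }
  groups <- lapply(atomSets, identity)
  merged <- TRUE
  while (merged && length(groups) > 1L) {
    merged <- FALSE
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        if (length(intersect(groups[[i]], groups[[j]])) ||
            nearby(groups[[i]], groups[[j]])) {
          groups[[i]] <- sort(unique(c(groups[[i]], groups[[j]])))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  groups
}

.sitesForConformer <- function(coords, elements, adj, defs, matches) {
  rows <- list()
  addSite <- function(type, pos, dir, src) {
    rows[[length(rows) + 1L]] <<- list(type = type, x = pos[1], y = pos[2],
                                       z = pos[3],
                                       dx = dir[1], dy = dir[2], dz = dir[3],
                                       sourceAtoms = sort(unique(src)))
  }
  noDir <- c(NA_real_, NA_real_, NA_real_)

  for (type in .SITE_TYPES) {
    defRows <- which(defs$type == type)
    if (!length(defRows)) next
    hitList <- unlist(lapply(defRows, function(d) matches[[paste0("f", d)]]),
                      recursive = FALSE)
    if (!length(hitList)) next
    placement <- defs$placement[defRows[1]]
    directed <- defs$directed[defRows[1]]

    if (type == "H") {
      atomsHit <- sort(unique(unlist(hitList)))
      groups <- .mergeWithinBonds(as.list(atomsHit), adj, 2L)
      for (g in groups) {
        pos <- colMeans(coords[g, , drop = FALSE])
        addSite("H", pos, noDir, g)
      }
      next
    }

    seen <- character()
    for (hit in hitList) {
      key <- paste(sort(hit), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (placement == "atom") {
        a <- hit[1]
        pos <- coords[a, ]
        if (type == "D") {
          hNbr <- adj[[a]][elements[adj[[a]]] == "H"]
          for (h in hNbr) {
            addSite("D", pos, unitVector(coords[h, ] - pos), c(a, h))
          }
        } else if (directed) {
          nbr <- adj[[a]]
          if (length(nbr)) {
            resultant <- -colSums(t(apply(coords[nbr, , drop = FALSE], 1L,
                                          function(p) unitVector(p - pos))))
            dir <- unitVector(resultant)
            if (sum(dir^2) < 0.5) dir <- noDir
          } else dir <- noDir
          addSite(type, pos, dir, a)
        } else {
          addSite(type, pos, noDir, a)
        }
      } else if (placement == "group_centroid") {
        pos <- colMeans(coords[hit, , drop = FALSE])
        addSite(type, pos, noDir, hit)
      } else { # ring_centroid
        pos <- colMeans(coords[hit, , drop = FALSE])
        centred <- sweep(coords[hit, , drop = FALSE], 2L, pos)
        normal <- svd(centred)$v[, 3]
        pivot <- which.max(abs(normal))
        if (normal[pivot] < 0) normal <- -normal
        addSite(type, pos, unitVector(normal), hit)
      }
    }
  }

  if (!length(rows)) return(emptySiteTable())
  tab <- data.frame(
    type = vapply(rows, `[[`, "", "type"),
    x = vapply(rows, `[[`, 0, "x"), y = vapply(rows, `[[`, 0, "y"),
    z = vapply(rows, `[[`, 0, "z"),
    dx = vapply(rows, `[[`, 0, "dx"), dy = vapply(rows, `[[`, 0, "dy"),
    dz = vapply(rows, `[[`, 0, "dz"),
    stringsAsFactors = FALSE)
  tab$sourceAtoms <- I(lapply(rows, `[[`, "sourceAtoms"))
  # drop duplicate (type, sourceAtoms) sites
  key <- paste(tab$type,
               vapply(tab$sourceAtoms, paste, "", collapse = ","),
               round(tab$dx, 6))
  tab <- tab[!duplicated(key), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Export site sets to a table
#'
#' @param siteSets List of \linkS4class{SiteSet} objects (or the nested list
#'   returned by \code{\link{perceiveSites}}).
#' @return Data frame with columns moleculeId, confId, type, x, y, z,
#'   dx, dy, dz.
#' @export
siteTable <- function(siteSets) {
  flat <- .flattenSiteSets(siteSets)
  do.call(rbind, lapply(flat, function(ss) {
    s <- sites(ss)
    if (!nrow(s)) return(NULL)
    data.frame(moleculeId = ss@moleculeId, confId = ss@confId,
               s[, c("type", "x", "y", "z", "dx", "dy", "dz")],
               stringsAsFactors = FALSE)
  }))
}

.flattenSiteSets <- function(x) {
  if (is(x, "SiteSet")) return(list(x))
  out <- list()
  for (el in x) out <- c(out, .flattenSiteSets(el))
  out
}
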