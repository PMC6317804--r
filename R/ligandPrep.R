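# Ligand preparation: compound table loading, structure standardization
# (salt stripping, rule-based ionization at pH ~7, stereoisomer
# enumeration) and bounded 3D conformer-ensemble generation.

#' Load a compound activity table
#'
#' Reads a CSV/TSV table of compounds (identifier, SMILES, optional pIC50 and
#' set label), validates it and returns a \linkS4class{MoleculeSet}. Rows
#' whose computed molecular weight exceeds the configured cutoff are excluded
#' and recorded in the set's \code{exclusions} slot; duplicate ids and a
#' missing id column are fatal.
#'
#' @param path Path to the table.
#' @param idCol,smilesCol,activityCol,setCol Column names (activity and set
#'   columns are optional; pass \code{NULL} to skip).
#' @param config A \linkS4class{PrepConfig}; supplies the molecular weight
#'   cutoff.
#' @param sep Field separator (default \code{","}).
#' @param onParseError \code{"stop"} (default) to fail on an unparsable
#'   SMILES with its row index, or \code{"drop"} to exclude such rows with a
#'   warning.
#' @return A \linkS4class{MoleculeSet} with one record per retained row.
#' @export
loadCompoundTable <- function(path, idCol = "id", smilesCol = "smiles",
                              activityCol = "pIC50", setCol = NULL,
                              config = prepConfig(), sep = ",",
                              onParseError = c("stop", "drop")) {
  onParseError <- match.arg(onParseError)
  if (!file.exists(path)) stop("compound table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (!idCol %in% names(tab))
    stop("missing id column '", idCol, "' in ", path)
  if (!smilesCol %in% names(tab))
    stop("missing SMILES column '", smilesCol, "' in ", path)
  ids <- as.character(tab[[idCol]])
  if (any(duplicated(ids)))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  act <- if (!is.null(activityCol) && activityCol %in% names(tab))
    as.numeric(tab[[activityCol]]) else rep(NA_real_, nrow(tab))
  if (any(is.infinite(act), na.rm = TRUE))
    stop("pIC50 values must be finite")
  lab <- if (!is.null(setCol) && setCol %in% names(tab))
    as.character(tab[[setCol]]) else rep("unknown", nrow(tab))
  lab[!lab %in% c("train", "test", "external")] <- "unknown"

  parsed <- chemBackend("parse", list(smiles = as.list(tab[[smilesCol]])))$results
  ok <- vapply(parsed, function(p) isTRUE(p$ok), logical(1))
  if (any(!ok)) {
    bad <- which(!ok)
    if (onParseError == "stop")
      stop("unparsable SMILES at row(s) ", paste(bad, collapse = ", "),
           " (id: ", paste(ids[bad], collapse = ", "), ")")
    warning(length(bad), " row(s) with unparsable SMILES dropped: ",
            paste(ids[bad], collapse = ", "))
  }
  mw <- vapply(parsed, function(p) if (isTRUE(p$ok)) p$mw else NA_real_,
               numeric(1))
  heavyRow <- ok & mw > config@mwCutoff
  if (any(heavyRow))
    message(sum(heavyRow), " compound(s) excluded by the ",
            config@mwCutoff, " Da molecular weight cutoff")
  keep <- ok & !heavyRow
  recs <- lapply(which(keep), function(i) {
    list(id = ids[i], smiles = parsed[[i]]$canonical, pIC50 = act[i],
         setLabel = lab[i], mw = mw[i],
         rotatableBonds = parsed[[i]]$rotatable_bonds,
         parentId = ids[i], conformers = list())
  })
  excl <- data.frame(
    id = ids[!keep],
    reason = ifelse(!ok[!keep], "unparsable SMILES",
                    paste0("molecular weight > ", config@mwCutoff, " Da")),
    stringsAsFactors = FALSE)
  newMoleculeSet(recs, exclusions = excl)
}

#' Standardize molecules
#'
#' Applies the preparation protocol to every record: the largest organic
#' fragment is retained (salt stripping), ionization states are set by a
#' fixed rule table representing the dominant protonation states at the
#' configured pH (carboxylic acids, tetrazoles and acyl sulfonamides
#' deprotonated; aliphatic amines, amidines and guanidines protonated;
#' anilines, amides and phenols left neutral), specified chirality is
#' retained, and unspecified stereocentres are enumerated up to
#' \code{maxIsomers} isomers, each becoming a child record with the parent id
#' plus an \code{_s<i>} suffix.
#'
#' @param mset A \linkS4class{MoleculeSet}.
#' @param config A \linkS4class{PrepConfig}.
#' @return A \linkS4class{MoleculeSet} of standardized records (possibly more
#'   records than the input when stereoisomers were enumerated).
#' @export
standardizeMolecules <- function(mset, config = prepConfig()) {
  if (!length(mset)) return(mset)
  req <- lapply(records(mset), function(r) list(id = r$id, smiles = r$smiles))
  res <- chemBackend("standardize",
                     list(records = unname(req),
                          max_isomers = config@maxIsomers))$results
  out <- list()
  for (i in seq_along(res)) {
    ri <- res[[i]]
    parent <- mset[[i]]
    if (!isTRUE(ri$ok))
      stop("standardization failed for '", ri$id, "': ", ri$error)
    if (isTRUE(ri$truncated))
      warning("stereoisomer enumeration for '", ri$id,
              "' truncated at ", config@maxIsomers, " isomers")
    for (ch in ri$children) {
      rec <- parent
      rec$id <- ch$id
      rec$smiles <- ch$smiles
      rec$mw <- ch$mw
      rec$rotatableBonds <- ch$rotatable_bonds
      rec$parentId <- parent$id
      rec$conformers <- list()
      out[[length(out) + 1L]] <- rec
    }
  }
  newMoleculeSet(out, exclusions = mset@exclusions)
}

#' Generate bounded conformer ensembles
#'
#' Embeds 3D conformers for every record by stochastic distance geometry
#' followed by MMFF94 minimization (single-threaded, seeded, deterministic),
#' then applies the ensemble contract: at most
#' \code{min(maxConfPerLigand, maxConfPerRotBond * max(1, rotatableBonds))}
#' conformers are requested; conformers above the relative energy window are
#' discarded; remaining conformers are deduplicated greedily in ascending
#' energy order so that no two retained conformers are closer than the
#' heavy-atom best-fit RMSD cutoff. Relative energies are stored in
#' kcal/mol above the ensemble minimum.
#'
#' @param mset A standardized \linkS4class{MoleculeSet}.
#' @param config A \linkS4class{PrepConfig}.
#' @return The \linkS4class{MoleculeSet} with \code{atoms}, \code{bonds},
#'   \code{aromaticRings} and non-empty \code{conformers} on every record.
#' @export
generateConformers <- function(mset, config = prepConfig()) {
  if (!length(mset)) return(mset)
  recs <- records(mset)
  mols <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    nReq <- min(config@maxConfPerLigand,
                config@maxConfPerRotBond * max(1L, r$rotatableBonds))
    list(id = r$id, smiles = r$smiles, n_conf = nReq, seed_offset = i - 1L)
  })
  res <- chemBackend("embed", list(molecules = mols,
                                   seed = config@randomSeed))$results
  out <- recs
  for (i in seq_along(res)) {
    ri <- res[[i]]
    if (!isTRUE(ri$ok))
      stop("conformer embedding failed for '", recs[[i]]$id, "': ", ri$error)
    atoms <- data.frame(
      element = vapply(ri$atoms, function(a) a$element, character(1)),
      charge = vapply(ri$atoms, function(a) as.integer(a$charge), integer(1)),
      aromatic = vapply(ri$atoms, function(a) isTRUE(a$aromatic), logical(1)),
      inRing = vapply(ri$atoms, function(a) isTRUE(a$in_ring), logical(1)),
      nH = vapply(ri$atoms, function(a) as.integer(a$n_h), integer(1)),
      stringsAsFactors = FALSE)
    bonds <- do.call(rbind, lapply(ri$bonds, function(b)
      c(as.integer(b[[1]]), as.integer(b[[2]]), as.numeric(b[[3]]))))
    energies <- vapply(ri$conformers, function(cf) cf$energy, numeric(1))
    coordsList <- lapply(ri$conformers, function(cf)
      do.call(rbind, lapply(cf$coords, as.numeric)))
    rel <- energies - min(energies)
    heavy <- which(atoms$element != "H")
    kept <- dedupConformers(coordsList, rel, heavy,
                            energyWindow = config@energyWindow,
                            rmsdCutoff = config@rmsdDedup)
    if (!length(kept))
      stop("no conformers retained for '", recs[[i]]$id,
           "' after filtering")
    conformers <- lapply(seq_along(kept), function(ci) {
      j <- kept[ci]
      list(confId = ci, coords = coordsList[[j]], relEnergy = rel[j])
    })
    out[[i]]$atoms <- atoms
    out[[i]]$bonds <- bonds
    out[[i]]$aromaticRings <- lapply(ri$aromatic_rings,
                                     function(rr) as.integer(unlist(rr)))
    out[[i]]$conformers <- conformers
  }
  newMoleculeSet(out, exclusions = mset@exclusions)
}

#' Energy-window filtering and RMSD deduplication of a conformer ensemble
#'
#' Conformers above the relative energy window are discarded; the remainder
#' are scanned in ascending energy order and a conformer is kept only when
#' its heavy-atom best-fit RMSD to every already-kept conformer is at least
#' the cutoff, so the retained ensemble has all pairwise RMSDs >= cutoff and
#' always contains the minimum-energy conformer.
#'
#' @param coordsList List of full-atom coordinate matrices.
#' @param relEnergies Relative energies (kcal/mol above the minimum).
#' @param heavyIdx Indices of heavy atoms used for the RMSD.
#' @param energyWindow Relative energy window (kcal/mol).
#' @param rmsdCutoff Deduplication cutoff (Angstrom).
#' @return Integer indices of the retained conformers, in ascending energy
#'   order.
#' @export
dedupConformers <- function(coordsList, relEnergies, heavyIdx,
                            energyWindow = 10.0, rmsdCutoff = 1.0) {
  keepE <- which(relEnergies <= energyWindow)
  ordE <- keepE[order(relEnergies[keepE])]
  kept <- integer()
  for (j in ordE) {
    dup <- FALSE
    for (k in kept) {
      if (bestFitRMSD(coordsList[[j]][heavyIdx, , drop = FALSE],
                      coordsList[[k]][heavyIdx, , drop = FALSE]) <
          rmsdCutoff) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, j)
  }
  kept
}

#' Prepare molecules end to end
#'
#' Convenience wrapper: \code{\link{standardizeMolecules}} followed by
#' \code{\link{generateConformers}}.
#'
#' @param mset A \linkS4class{MoleculeSet}.
#' @param config A \linkS4class{PrepConfig}.
#' @return The prepared \linkS4class{MoleculeSet}.
#' @export
prepareMolecules <- function(mset, config = prepConfig()) {
  generateConformers(standardizeMolecules(mset, config), config)
}

#' Preparation report
#'
#' @param mset A prepared \linkS4class{MoleculeSet}.
#' @return Data frame with one row per record (id, parent id, number of
#'   conformers, lowest and highest retained relative energy) followed by
#'   one row per excluded input (zero conformers, exclusion reason).
#' @export
prepReport <- function(mset) {
  recs <- records(mset)
  rep1 <- data.frame(
    id = vapply(recs, function(r) r$id, character(1)),
    parentId = vapply(recs, function(r) r$parentId %||% r$id, character(1)),
    nConformers = vapply(recs, function(r) length(r$conformers), integer(1)),
    maxRelEnergy = vapply(recs, function(r) {
      if (!length(r$conformers)) return(NA_real_)
      max(vapply(r$conformers, function(cf) cf$relEnergy, numeric(1)))
    }, numeric(1)),
    reason = "",
    stringsAsFactors = FALSE)
  if (nrow(mset@exclusions)) {
    rep2 <- data.frame(id = mset@exclusions$id,
                       parentId = mset@exclusions$id, nConformers = 0L,
                       maxRelEnergy = NA_real_,
                       reason = mset@exclusions$reason,
                       stringsAsFactors = FALSE)
    rep1 <- rbind(rep1, rep2)
  }
  rownames(rep1) <- NULL
  rep1
}

#' Write conformer ensembles to an SDF file
#'
#' One V2000 record per conformer, carrying \code{<parent_id>},
#' \code{<conf_id>} and \code{<rel_energy_kcal>} data fields.
#'
#' @param mset A prepared \linkS4class{MoleculeSet}.
#' @param path Output SDF path.
#' @return Invisibly, the path.
#' @export
writeConformersSDF <- function(mset, path) {
  mols <- lapply(records(mset), function(r) {
    list(id = r$id, parent_id = r$parentId %||% r$id, smiles = r$smiles,
         conformers = lapply(r$conformers, function(cf) {
           list(conf_id = cf$confId, rel_energy = cf$relEnergy,
                coords = unname(split(cf$coords, row(cf$coords))))
         }))
  })
  chemBackend("sdf_write", list(path = path, molecules = unname(mols)))
  invisible(path)
}

#' Read conformer ensembles from an SDF file
#'
#' Inverse of \code{\link{writeConformersSDF}}: conformer records sharing a
#' parent id are regrouped into one molecule record each.
#'
#' @param path SDF path.
#' @return A \linkS4class{MoleculeSet} whose records carry \code{elements}
#'   and \code{conformers} (coordinates to the SDF's 1e-4 Angstrom
#'   precision).
#' @export
readConformersSDF <- function(path) {
  res <- chemBackend("sdf_read", list(path = path))$results
  byId <- list()
  for (r in res) {
    if (!isTRUE(r$ok)) stop("failed to read SDF record: ", r$error)
    pid <- r$props$parent_id %||% r$name
    id <- sub("_c[0-9]+$", "", r$name)
    coords <- do.call(rbind, lapply(r$coords, as.numeric))
    cf <- list(confId = as.integer(r$props$conf_id %||% "1"),
               coords = coords,
               relEnergy = as.numeric(r$props$rel_energy_kcal %||% "0"))
    if (is.null(byId[[id]])) {
      byId[[id]] <- list(id = id, smiles = r$smiles, pIC50 = NA_real_,
                         setLabel = "unknown", parentId = pid,
                         elements = unlist(r$elements), conformers = list(cf))
    } else {
      byId[[id]]$conformers <- c(byId[[id]]$conformers, list(cf))
    }
  }
  newMoleculeSet(unname(byId))
}
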