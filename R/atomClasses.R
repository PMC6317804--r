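# Atom-class assignment for the atom-based QSAR descriptors. Every heavy
# atom receives exactly one class by fixed precedence
#   P > N > D > W > H > X
# i.e. charged classes first, then donors, then electron-withdrawing atoms
# (acceptor-type N/O and halogens), then nonpolar carbon, with X as the
# catch-all.

.HALOGENS <- c("F", "Cl", "Br", "I")

#' Assign QSAR atom classes to a prepared molecule
#'
#' @param record A molecule record from a prepared
#'   \linkS4class{MoleculeSet} (fields \code{atoms} and \code{bonds} must be
#'   present).
#' @return Character vector of classes (\code{"D"}, \code{"H"}, \code{"N"},
#'   \code{"P"}, \code{"W"}, \code{"X"}), one per heavy atom, named by the
#'   heavy-atom index in the full (hydrogens included) atom table.
#' @examples
#' \dontrun{
#' mset <- prepareMolecules(syntheticMoleculeSet(n = 1, seed = 1))
#' assignAtomClasses(mset[[1]])
#' }
#' @export
assignAtomClasses <- function(record) {
  atoms <- record$atoms
  bonds <- record$bonds
  if (is.null(atoms) || is.null(bonds))
    stop("record must carry atoms and bonds (run generateConformers first)")
  heavy <- which(atoms$element != "H")
  nbrOf <- .adjacencyList(nrow(atoms), bonds[, 1:2, drop = FALSE])
  # atoms double-bonded to a carbon that carries a negatively charged oxygen
  # (the carbonyl oxygen of a carboxylate) count as negative-ionic too
  negGroupO <- logical(nrow(atoms))
  for (b in seq_len(nrow(bonds))) {
    if (bonds[b, 3] != 2) next
    i <- bonds[b, 1]; j <- bonds[b, 2]
    for (pair in list(c(i, j), c(j, i))) {
      o <- pair[1]; c_ <- pair[2]
      if (atoms$element[o] == "O" &&
          any(atoms$charge[nbrOf[[c_]]] < 0 &
              atoms$element[nbrOf[[c_]]] == "O"))
        negGroupO[o] <- TRUE
    }
  }
  out <- character(length(heavy))
  names(out) <- heavy
  for (k in seq_along(heavy)) {
    a <- heavy[k]
    el <- atoms$element[a]
    nbrs <- nbrOf[[a]]
    heavyNbrEl <- atoms$element[nbrs[atoms$element[nbrs] != "H"]]
    cls <-
      if (atoms$charge[a] > 0) "P"
      else if (atoms$charge[a] < 0 || negGroupO[a]) "N"
      else if (el %in% c("N", "O", "S") && atoms$nH[a] > 0) "D"
      else if (el %in% c("N", "O") || el %in% .HALOGENS) "W"
      else if (el == "C" &&
               !any(heavyNbrEl %in% c("N", "O", "P", "S", .HALOGENS))) "H"
      else "X"
    out[k] <- cls
  }
  out
}

#' Heavy-atom coordinates, classes and radii of a conformer
#'
#' Helper assembling the aligned-structure representation the occupancy
#' descriptors consume.
#'
#' @param record A prepared molecule record.
#' @param confId Conformer id (default first).
#' @return List with \code{coords} (heavy-atom n x 3 matrix),
#'   \code{classes} and \code{radii}.
#' @export
atomStructure <- function(record, confId = 1L) {
  cfIds <- vapply(record$conformers, function(cf) cf$confId, integer(1))
  cf <- record$conformers[[match(confId, cfIds)]]
  heavy <- which(record$atoms$element != "H")
  list(coords = cf$coords[heavy, , drop = FALSE],
       classes = unname(assignAtomClasses(record)),
       radii = vdwRadii(record$atoms$element[heavy]))
}
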