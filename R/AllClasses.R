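#' @import methods
NULL

.SITE_TYPES <- c("A", "D", "H", "N", "P", "R")
.ATOM_CLASSES <- c("D", "H", "N", "P", "W", "X")

# ---------------------------------------------------------------------------
# PrepConfig
# ---------------------------------------------------------------------------

#' Ligand preparation configuration
#'
#' Holds the parameters of structure standardization and conformer-ensemble
#' generation: the ionization pH window, the conformer caps (per rotatable
#' bond and per ligand), the RMSD deduplication cutoff, the relative-energy
#' window, the molecular-weight cutoff, the stereoisomer enumeration cap and
#' the random seed.
#'
#' @slot phCenter Ionization pH centre (default 7.0).
#' @slot phWindow Ionization pH half-window (default 2.0).
#' @slot maxConfPerRotBond Maximum conformers per rotatable bond (default 10).
#' @slot maxConfPerLigand Maximum conformers per ligand (default 100).
#' @slot rmsdDedup Heavy-atom best-fit RMSD deduplication cutoff in Angstrom
#'   (default 1.0).
#' @slot energyWindow Relative energy window in kcal/mol (default 10.0).
#' @slot mwCutoff Molecular weight cutoff in Dalton (default 1000).
#' @slot maxIsomers Cap on enumerated stereoisomers per input (default 8).
#' @slot randomSeed Integer seed for conformer embedding.
#' @export
setClass("PrepConfig",
         representation(phCenter = "numeric", phWindow = "numeric",
                        maxConfPerRotBond = "integer",
                        maxConfPerLigand = "integer",
                        rmsdDedup = "numeric", energyWindow = "numeric",
                        mwCutoff = "numeric", maxIsomers = "integer",
                        randomSeed = "integer"),
         prototype(phCenter = 7.0, phWindow = 2.0,
                   maxConfPerRotBond = 10L, maxConfPerLigand = 100L,
                   rmsdDedup = 1.0, energyWindow = 10.0, mwCutoff = 1000,
                   maxIsomers = 8L, randomSeed = 1L),
         validity = function(object) {
           msg <- character()
           if (object@maxConfPerRotBond < 1L || object@maxConfPerLigand < 1L)
             msg <- c(msg, "conformer caps must be positive")
           if (object@rmsdDedup <= 0)
             msg <- c(msg, "rmsdDedup must be > 0")
           if (object@energyWindow <= 0 || object@mwCutoff <= 0 ||
               object@maxIsomers < 1L)
             msg <- c(msg, "energyWindow, mwCutoff and maxIsomers must be positive")
           if (length(msg)) msg else TRUE
         })

#' Create a ligand preparation configuration
#'
#' @param phCenter,phWindow Ionization pH centre and half-window.
#' @param maxConfPerRotBond,maxConfPerLigand Conformer caps.
#' @param rmsdDedup RMSD deduplication cutoff (Angstrom).
#' @param energyWindow Relative energy window (kcal/mol).
#' @param mwCutoff Molecular weight cutoff (Dalton).
#' @param maxIsomers Stereoisomer enumeration cap.
#' @param randomSeed Integer seed used for conformer embedding.
#' @return A \linkS4class{PrepConfig} object.
#' @examples
#' prepConfig(randomSeed = 17)
#' @export
prepConfig <- function(phCenter = 7.0, phWindow = 2.0,
                       maxConfPerRotBond = 10, maxConfPerLigand = 100,
                       rmsdDedup = 1.0, energyWindow = 10.0,
                       mwCutoff = 1000, maxIsomers = 8, randomSeed = 1) {
  new("PrepConfig", phCenter = phCenter, phWindow = phWindow,
      maxConfPerRotBond = as.integer(maxConfPerRotBond),
      maxConfPerLigand = as.integer(maxConfPerLigand),
      rmsdDedup = rmsdDedup, energyWindow = energyWindow,
      mwCutoff = mwCutoff, maxIsomers = as.integer(maxIsomers),
      randomSeed = as.integer(randomSeed))
}

# ---------------------------------------------------------------------------
# MoleculeSet
# ---------------------------------------------------------------------------

#' A set of compound records
#'
#' Container for compound records as they move through preparation. Each
#' record is a list with elements \code{id}, \code{smiles}, \code{pIC50}
#' (may be \code{NA}), \code{setLabel} (\code{"train"}, \code{"test"},
#' \code{"external"} or \code{"unknown"}), \code{mw}, \code{rotatableBonds},
#' \code{parentId} and, after conformer generation, \code{atoms} (data frame
#' of element/charge/aromaticity per atom, hydrogens included), \code{bonds}
#' (matrix of atom index pairs plus bond order), \code{aromaticRings}
#' (list of atom index vectors) and \code{conformers} (list of lists with
#' \code{confId}, \code{coords} and \code{relEnergy}).
#'
#' @slot records Named list of compound records (names are the ids).
#' @slot exclusions A data frame recording rows excluded during loading
#'   (id, reason).
#' @export
setClass("MoleculeSet",
         representation(records = "list", exclusions = "data.frame"),
         prototype(records = list(),
                   exclusions = data.frame(id = character(),
                                           reason = character())),
         validity = function(object) {
           ids <- vapply(object@records, function(r) r$id, character(1))
           if (length(ids) && any(duplicated(ids)))
             return(paste("duplicate molecule id(s):",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
           if (length(ids) && !identical(unname(names(object@records)), unname(ids)))
             return("records must be named by their ids")
           TRUE
         })

#' Construct a MoleculeSet from records
#' @param records List of compound record lists.
#' @param exclusions Optional data frame of excluded rows.
#' @return A \linkS4class{MoleculeSet}.
#' @keywords internal
newMoleculeSet <- function(records,
                           exclusions = data.frame(id = character(),
                                                   reason = character())) {
  names(records) <- vapply(records, function(r) r$id, character(1))
  new("MoleculeSet", records = records, exclusions = exclusions)
}

#' @describeIn MoleculeSet-class Number of molecules in the set.
#' @param x A \code{MoleculeSet}.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@records))

#' Molecule identifiers
#' @param object A \linkS4class{MoleculeSet}.
#' @return Character vector of ids.
#' @export
setGeneric("moleculeIds", function(object) standardGeneric("moleculeIds"))

#' @rdname moleculeIds
#' @export
setMethod("moleculeIds", "MoleculeSet",
          function(object) unname(names(object@records)))

#' Access the record list of a MoleculeSet
#' @param object A \linkS4class{MoleculeSet}.
#' @return Named list of records.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "MoleculeSet", function(object) object@records)

#' @describeIn MoleculeSet-class Subset by id or index, returning a
#'   \code{MoleculeSet}.
#' @param i Ids or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  newMoleculeSet(x@records[i], x@exclusions)
})

#' @describeIn MoleculeSet-class Extract one record by id or index.
#' @export
setMethod("[[", "MoleculeSet", function(x, i) x@records[[i]])

setMethod("show", "MoleculeSet", function(object) {
  n <- length(object@records)
  nconf <- sum(vapply(object@records,
                      function(r) length(r$conformers %||% list()),
                      integer(1)))
  cat("MoleculeSet with", n, "molecule(s),", nconf, "conformer(s)\n")
  if (n) {
    ids <- moleculeIds(object)
    cat("  ids:", paste(utils::head(ids, 5), collapse = ", "),
        if (n > 5) "..." else "", "\n")
  }
  if (nrow(object@exclusions))
    cat("  ", nrow(object@exclusions), "excluded row(s) during loading\n")
})

# ---------------------------------------------------------------------------
# SiteSet
# ---------------------------------------------------------------------------

#' Pharmacophore sites of one conformer
#'
#' Typed, positioned, optionally directed pharmacophore feature points
#' perceived on a single conformer. Site types follow the six-type
#' convention: hydrogen-bond acceptor (A), hydrogen-bond donor (D),
#' hydrophobe (H), negative ionizable (N), positive ionizable (P) and
#' aromatic ring (R).
#'
#' @slot moleculeId Identifier of the parent molecule.
#' @slot confId Integer conformer identifier.
#' @slot sites Data frame with columns \code{type}, \code{x}, \code{y},
#'   \code{z}, \code{dx}, \code{dy}, \code{dz} (direction components,
#'   \code{NA} for undirected sites) and a list column \code{sourceAtoms}.
#' @export
setClass("SiteSet",
         representation(moleculeId = "character", confId = "integer",
                        sites = "data.frame"),
         validity = function(object) {
           s <- object@sites
           if (nrow(s) == 0L) return(TRUE)
           if (!all(s$type %in% .SITE_TYPES))
             return("site types must be among A, D, H, N, P, R")
           if (!all(is.finite(s$x) & is.finite(s$y) & is.finite(s$z)))
             return("site positions must be finite")
           dir <- as.matrix(s[, c("dx", "dy", "dz")])
           has <- stats::complete.cases(dir)
           if (any(has)) {
             nrm <- sqrt(rowSums(dir[has, , drop = FALSE]^2))
             if (any(abs(nrm - 1) > 1e-9))
               return("site directions must be unit vectors")
           }
           TRUE
         })

#' Construct a SiteSet
#' @param moleculeId Molecule identifier.
#' @param confId Conformer identifier.
#' @param sites Site data frame (see \linkS4class{SiteSet}).
#' @return A \linkS4class{SiteSet}.
#' @export
newSiteSet <- function(moleculeId, confId = 1L, sites = emptySiteTable()) {
  new("SiteSet", moleculeId = as.character(moleculeId),
      confId = as.integer(confId), sites = sites)
}

#' Empty site table with the canonical columns
#' @return Zero-row site data frame.
#' @keywords internal
emptySiteTable <- function() {
  data.frame(type = character(), x = numeric(), y = numeric(), z = numeric(),
             dx = numeric(), dy = numeric(), dz = numeric(),
             sourceAtoms = I(list()), stringsAsFactors = FALSE)
}

#' Site table of a SiteSet
#' @param object A \linkS4class{SiteSet}.
#' @return The site data frame.
#' @export
setGeneric("sites", function(object) standardGeneric("sites"))

#' @rdname sites
#' @export
setMethod("sites", "SiteSet", function(object) object@sites)

#' Site positions as a matrix
#' @param object A \linkS4class{SiteSet} or \linkS4class{PharmHypothesis}.
#' @return n x 3 numeric matrix of positions (Angstrom).
#' @export
setGeneric("sitePositions", function(object) standardGeneric("sitePositions"))

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "SiteSet", function(object) {
  as.matrix(object@sites[, c("x", "y", "z")])
})

#' @describeIn SiteSet-class Number of sites.
#' @param x A \code{SiteSet}.
#' @export
setMethod("length", "SiteSet", function(x) nrow(x@sites))

setMethod("show", "SiteSet", function(object) {
  cat("SiteSet:", object@moleculeId, "conformer", object@confId, "with",
      nrow(object@sites), "site(s)\n")
  if (nrow(object@sites))
    cat("  types:", paste(sort(object@sites$type), collapse = ""), "\n")
})

#' Apply a rigid motion to a SiteSet
#'
#' Transforms site positions and directions by the same rotation and
#' translation, preserving all typing. Used in equivariance checks and by
#' the synthetic-data generator.
#'
#' @param siteSet A \linkS4class{SiteSet}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation.
#' @return The transformed \linkS4class{SiteSet}.
#' @export
transformSiteSet <- function(siteSet, rotation, translation = c(0, 0, 0)) {
  s <- siteSet@sites
  if (nrow(s)) {
    pos <- applyRigid(as.matrix(s[, c("x", "y", "z")]), rotation, translation)
    s$x <- pos[, 1]; s$y <- pos[, 2]; s$z <- pos[, 3]
    dir <- as.matrix(s[, c("dx", "dy", "dz")])
    has <- stats::complete.cases(dir)
    if (any(has)) {
      d2 <- dir[has, , drop = FALSE] %*% t(rotation)
      dir[has, ] <- d2
      s$dx <- dir[, 1]; s$dy <- dir[, 2]; s$dz <- dir[, 3]
    }
  }
  newSiteSet(siteSet@moleculeId, siteSet@confId, s)
}

# ---------------------------------------------------------------------------
# PharmHypothesis
# ---------------------------------------------------------------------------

#' A common pharmacophore hypothesis
#'
#' An ordered k-site pharmacophore: site types, reference-frame positions and
#' optional unit direction vectors, instantiated from one reference conformer
#' of one ligand. The variant code is the sorted string of site type letters
#' (for example \code{"AAAR"} = three acceptors and one aromatic ring).
#'
#' @slot variant Sorted type-letter code.
#' @slot siteTypes Character vector of the k site types (in site order).
#' @slot sitePositions k x 3 matrix of positions (Angstrom).
#' @slot siteDirections k x 3 matrix of unit directions (\code{NA} rows for
#'   undirected sites).
#' @slot referenceLigandId Id of the ligand whose conformer instantiated the
#'   hypothesis.
#' @slot referenceConfId Conformer id within the reference ligand.
#' @slot matchTolerance Per-site match tolerance after superposition
#'   (Angstrom).
#' @slot score Named numeric vector of score components (may be empty before
#'   scoring): \code{site}, \code{vector}, \code{volume}, \code{active},
#'   \code{inactivePenalty}, \code{adjusted}.
#' @slot nMatchingActives Number of active molecules matching all k sites.
#' @export
setClass("PharmHypothesis",
         representation(variant = "character", siteTypes = "character",
                        sitePositions = "matrix", siteDirections = "matrix",
                        referenceLigandId = "character",
                        referenceConfId = "integer",
                        matchTolerance = "numeric", score = "numeric",
                        nMatchingActives = "integer"),
         validity = function(object) {
           k <- length(object@siteTypes)
           if (k < 3L || k > 7L)
             return("a hypothesis must have between 3 and 7 sites")
           if (!all(object@siteTypes %in% .SITE_TYPES))
             return("site types must be among A, D, H, N, P, R")
           code <- paste(sort(object@siteTypes), collapse = "")
           if (!identical(code, object@variant))
             return("variant code must be the sorted site type letters")
           if (nrow(object@sitePositions) != k)
             return("sitePositions must have one row per site")
           if (object@matchTolerance <= 0)
             return("matchTolerance must be > 0")
           D <- as.matrix(stats::dist(object@sitePositions))
           if (max(abs(D - t(D))) > 1e-6)
             return("intersite distances must be symmetric")
           TRUE
         })

#' Construct a pharmacophore hypothesis
#'
#' @param siteTypes Character vector of site types.
#' @param sitePositions k x 3 position matrix.
#' @param siteDirections Optional k x 3 matrix of unit directions (NA rows
#'   for undirected sites).
#' @param referenceLigandId,referenceConfId Reference conformer identity.
#' @param matchTolerance Per-site tolerance in Angstrom (default 2.0).
#' @return A \linkS4class{PharmHypothesis} with sites ordered by type letter.
#' @export
newHypothesis <- function(siteTypes, sitePositions, siteDirections = NULL,
                          referenceLigandId = "", referenceConfId = 1L,
                          matchTolerance = 2.0) {
  sitePositions <- as.matrix(sitePositions)
  k <- length(siteTypes)
  if (is.null(siteDirections))
    siteDirections <- matrix(NA_real_, k, 3)
  ord <- order(siteTypes, seq_len(k))
  new("PharmHypothesis",
      variant = paste(sort(siteTypes), collapse = ""),
      siteTypes = siteTypes[ord],
      sitePositions = sitePositions[ord, , drop = FALSE],
      siteDirections = as.matrix(siteDirections)[ord, , drop = FALSE],
      referenceLigandId = as.character(referenceLigandId),
      referenceConfId = as.integer(referenceConfId),
      matchTolerance = matchTolerance, score = numeric(),
      nMatchingActives = 0L)
}

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "PharmHypothesis",
          function(object) object@sitePositions)

#' Variant code of a hypothesis
#' @param object A \linkS4class{PharmHypothesis}.
#' @return The sorted type-letter code, e.g. \code{"AAAR"}.
#' @export
setGeneric("variantCode", function(object) standardGeneric("variantCode"))

#' @rdname variantCode
#' @export
setMethod("variantCode", "PharmHypothesis", function(object) object@variant)

#' Intersite distance matrix of a hypothesis
#' @param object A \linkS4class{PharmHypothesis}.
#' @return k x k symmetric matrix of Euclidean distances (Angstrom).
#' @export
setGeneric("intersiteDistances",
           function(object) standardGeneric("intersiteDistances"))

#' @rdname intersiteDistances
#' @export
setMethod("intersiteDistances", "PharmHypothesis", function(object) {
  D <- as.matrix(stats::dist(object@sitePositions))
  dimnames(D) <- list(object@siteTypes, object@siteTypes)
  D
})

#' Adjusted score of a scored hypothesis
#' @param object A \linkS4class{PharmHypothesis}.
#' @return The adjusted score (active score minus weighted inactive
#'   penalty), or \code{NA} if the hypothesis has not been scored.
#' @export
setGeneric("adjustedScore", function(object) standardGeneric("adjustedScore"))

#' @rdname adjustedScore
#' @export
setMethod("adjustedScore", "PharmHypothesis", function(object) {
  if (!length(object@score)) NA_real_ else unname(object@score["adjusted"])
})

setMethod("show", "PharmHypothesis", function(object) {
  cat("PharmHypothesis", object@variant, "(k =", length(object@siteTypes),
      ")\n  reference:", object@referenceLigandId, "conformer",
      object@referenceConfId, "\n  tolerance:", object@matchTolerance,
      "A\n")
  if (length(object@score))
    cat("  adjusted score:", signif(object@score["adjusted"], 4),
        " matching actives:", object@nMatchingActives, "\n")
})

# ---------------------------------------------------------------------------
# CubeQSARModel
# ---------------------------------------------------------------------------

#' Atom-based cube-occupancy PLS QSAR model
#'
#' A fitted partial-least-squares regression of pIC50 on binary
#' cube-occupancy descriptors: the grid definition, the retained
#' (cube, atom class) descriptor columns, the PLS state and coefficients,
#' and the training statistics panel.
#'
#' @slot hypothesisId Identifier of the aligning hypothesis.
#' @slot gridOrigin Length-3 grid origin (Angstrom).
#' @slot gridSpacing Cube edge length (Angstrom, default 1.0).
#' @slot gridDims Integer vector of cube counts along x, y, z.
#' @slot columns Data frame describing retained descriptor columns:
#'   \code{ix}, \code{iy}, \code{iz} (1-based cube indices), \code{class}
#'   (atom class: D, H, N, P, W or X) and the column \code{key}.
#' @slot coefficients Regression coefficients over the retained columns.
#' @slot intercept Regression intercept.
#' @slot plsFactors Number of PLS factors used.
#' @slot xMean Column means used for centring.
#' @slot trainingIds Ids of the training molecules.
#' @slot threshold Activity threshold on the pIC50 scale (default 5.0).
#' @slot stats Named list of training statistics (\code{SD}, \code{R2},
#'   \code{F}, \code{p}, and optionally \code{stability}, test-set
#'   \code{RMSE}, \code{Q2}, \code{pearsonR}).
#' @export
setClass("CubeQSARModel",
         representation(hypothesisId = "character", gridOrigin = "numeric",
                        gridSpacing = "numeric", gridDims = "integer",
                        columns = "data.frame", coefficients = "numeric",
                        intercept = "numeric", plsFactors = "integer",
                        xMean = "numeric", trainingIds = "character",
                        threshold = "numeric", stats = "list"),
         validity = function(object) {
           if (length(object@coefficients) != nrow(object@columns))
             return("one coefficient per retained descriptor column required")
           if (object@gridSpacing <= 0)
             return("gridSpacing must be > 0")
           if (object@plsFactors < 1L)
             return("plsFactors must be >= 1")
           TRUE
         })

#' @describeIn CubeQSARModel-class Regression coefficients over descriptor
#'   columns.
#' @param object A \code{CubeQSARModel}.
#' @export
setMethod("coef", "CubeQSARModel", function(object) object@coefficients)

#' Training/test statistics panel of a model
#' @param object A \linkS4class{CubeQSARModel}.
#' @return Named list of statistics.
#' @export
setGeneric("modelStats", function(object) standardGeneric("modelStats"))

#' @rdname modelStats
#' @export
setMethod("modelStats", "CubeQSARModel", function(object) object@stats)

setMethod("show", "CubeQSARModel", function(object) {
  cat("CubeQSARModel (hypothesis", object@hypothesisId, ")\n")
  cat("  grid:", paste(object@gridDims, collapse = " x "), "cubes of",
      object@gridSpacing, "A;", nrow(object@columns),
      "retained descriptor columns\n")
  cat("  PLS factors:", object@plsFactors, " training n:",
      length(object@trainingIds), "\n")
  st <- object@stats
  if (length(st))
    cat("  R2 =", signif(st$R2, 3), " SD =", signif(st$SD, 3),
        " F =", signif(st$F, 4), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
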