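# Synthetic data with planted structure, so every pipeline stage is
# testable without external downloads. Two tiers:
#   * geometry-level site sets with a planted pharmacophore (fast, no
#     chemistry) plus pseudo-atom structures for the QSAR stage;
#   * SMILES-level molecules assembled from a fragment grammar, exercising
#     the full perception stack.
# Every generated set ships with its ground truth (the planted geometry and
# the activity-model coefficients), making recovery tests self-contained.

#' Specification of a planted pharmacophore
#'
#' The default geometry is an asymmetric four-site arrangement of three
#' hydrogen-bond acceptors and one aromatic ring (variant \code{"AAAR"})
#' with all intersite distances between 2 and 20 Angstrom and distinct
#' enough that the optimal match assignment is unique.
#'
#' @param variant Variant code (site types, sorted; default \code{"AAAR"}).
#' @param sitePositions k x 3 matrix of planted positions (Angstrom).
#' @param jitterSD Gaussian positional jitter per coordinate (Angstrom,
#'   default 0.3).
#' @param nExtraSites Range (length-2 integer vector) of random decoration
#'   sites added per active (default c(2, 2)).
#' @param matchTolerance Tolerance used for the decoy rejection oracle
#'   (default 2.0).
#' @return A list spec.
#' @export
plantedPharmacophoreSpec <- function(variant = "AAAR",
                                     sitePositions = NULL,
                                     jitterSD = 0.3,
                                     nExtraSites = c(2, 2),
                                     matchTolerance = 2.0) {
  types <- strsplit(variant, "")[[1]]
  if (is.null(sitePositions)) {
    stopifnot(identical(variant, "AAAR"))
    sitePositions <- rbind(c(0.0, 0.0, 0.0),
                           c(3.4, 0.6, 0.2),
                           c(1.4, 2.9, -0.5),
                           c(4.2, 3.1, 0.8))
  }
  sitePositions <- as.matrix(sitePositions)
  stopifnot(nrow(sitePositions) == length(types))
  D <- as.matrix(stats::dist(sitePositions))
  offDiag <- D[upper.tri(D)]
  stopifnot(all(offDiag >= 2), all(offDiag <= 20), jitterSD >= 0)
  list(variant = variant, types = types, sitePositions = sitePositions,
       jitterSD = jitterSD, nExtraSites = nExtraSites,
       matchTolerance = matchTolerance)
}

# Map site types to QSAR atom classes for pseudo-atom structures.
.siteClassMap <- c(A = "W", D = "D", H = "H", N = "N", P = "P", R = "H")

#' Generate planted site sets with construction-guaranteed decoys
#'
#' Actives carry the planted geometry plus Gaussian jitter and random extra
#' sites, then a random rigid motion. Decoys are random site sets re-sampled
#' (rejection) until a brute-force oracle confirms they contain no
#' type-compatible site subset matching the planted geometry within
#' tolerance, so decoy negativity is guaranteed by construction. Each
#' molecule also receives a pseudo-atom structure (one atom of 1.7 Angstrom
#' radius per site, classed by site type) so occupancy descriptors can be
#' built without chemistry.
#'
#' @param spec A \code{\link{plantedPharmacophoreSpec}}.
#' @param nActives,nDecoys Set sizes (nActives >= 2).
#' @param seed Integer seed.
#' @param maxRejects Rejection-sampling bound per decoy (default 200).
#' @return List with \code{siteSets} (named list, one single-conformer list
#'   per molecule), \code{structures} (named list of per-conformer
#'   structures), \code{labels} (logical: TRUE = planted active),
#'   \code{spec} and \code{canonical} (the jittered site tables in the
#'   canonical frame, before the rigid motion).
#' @export
generatePlantedSiteSets <- function(spec = plantedPharmacophoreSpec(),
                                    nActives = 20, nDecoys = 20, seed = 7,
                                    maxRejects = 200) {
  stopifnot(nActives >= 2)
  set.seed(seed)
  k <- length(spec$types)
  box <- apply(spec$sitePositions, 2L, range)
  siteSets <- list(); structures <- list(); canonical <- list()
  labels <- logical()

  sampleExtraSites <- function(n) {
    if (n == 0L) return(NULL)
    data.frame(type = sample(.SITE_TYPES, n, replace = TRUE),
               x = stats::runif(n, box[1, 1] - 3, box[2, 1] + 3),
               y = stats::runif(n, box[1, 2] - 3, box[2, 2] + 3),
               z = stats::runif(n, box[1, 3] - 3, box[2, 3] + 3),
               dx = NA_real_, dy = NA_real_, dz = NA_real_,
               stringsAsFactors = FALSE)
  }
  asTable <- function(types, pos) {
    data.frame(type = types, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               dx = NA_real_, dy = NA_real_, dz = NA_real_,
               stringsAsFactors = FALSE)
  }
  finishMolecule <- function(id, tab, isActive) {
    tab$sourceAtoms <- I(as.list(seq_len(nrow(tab))))
    canonical[[id]] <<- tab
    R <- randomRotation()
    tr <- stats::runif(3, -10, 10)
    ss <- transformSiteSet(newSiteSet(id, 1L, tab), R, tr)
    siteSets[[id]] <<- list(ss)
    pos <- sitePositions(ss)
    structures[[id]] <<- list(list(
      coords = pos,
      classes = unname(.siteClassMap[sites(ss)$type]),
      radii = rep(1.7, nrow(pos))))
    labels <<- c(labels, isActive)
  }

  for (i in seq_len(nActives)) {
    jit <- spec$sitePositions +
      matrix(stats::rnorm(3 * k, 0, spec$jitterSD), k, 3)
    nx <- if (spec$nExtraSites[1] == spec$nExtraSites[2]) spec$nExtraSites[1]
          else sample(seq(spec$nExtraSites[1], spec$nExtraSites[2]), 1L)
    tab <- rbind(asTable(spec$types, jit), sampleExtraSites(nx))
    finishMolecule(sprintf("active_%02d", i), tab, TRUE)
  }

  for (i in seq_len(nDecoys)) {
    ok <- FALSE
    for (try_ in seq_len(maxRejects)) {
      n <- k + sample(1:3, 1L)
      tab <- data.frame(
        type = sample(.SITE_TYPES, n, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.05, 0.05, 0.25)),
        x = stats::runif(n, box[1, 1] - 4, box[2, 1] + 4),
        y = stats::runif(n, box[1, 2] - 4, box[2, 2] + 4),
        z = stats::runif(n, box[1, 3] - 4, box[2, 3] + 4),
        dx = NA_real_, dy = NA_real_, dz = NA_real_,
        stringsAsFactors = FALSE)
      if (!bruteForcePlantedMatch(spec$types, spec$sitePositions, tab,
                                  spec$matchTolerance)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("decoy rejection sampling failed after ", maxRejects, " draws")
    finishMolecule(sprintf("decoy_%02d", i), tab, FALSE)
  }

  list(siteSets = siteSets, structures = structures, labels = labels,
       spec = spec, canonical = canonical)
}

#' Brute-force planted-geometry match oracle
#'
#' Enumerates every injective type-compatible assignment of the planted
#' sites to a candidate site table (no pruning, no heuristics) and reports
#' whether any assignment superimposes with every matched pair within
#' tolerance. Independent of the production matcher by design, so it can
#' serve as its oracle.
#'
#' @param types Planted site types.
#' @param positions Planted k x 3 positions.
#' @param siteTable Candidate site data frame (\code{type}, \code{x},
#'   \code{y}, \code{z}).
#' @param tolerance Per-site tolerance after superposition (Angstrom).
#' @return TRUE when a full type-compatible match within tolerance exists.
#' @export
bruteForcePlantedMatch <- function(types, positions, siteTable, tolerance) {
  k <- length(types)
  qPos <- as.matrix(siteTable[, c("x", "y", "z")])
  cand <- lapply(types, function(tp) which(siteTable$type == tp))
  if (any(lengths(cand) == 0L)) return(FALSE)
  idx <- integer(k)
  found <- FALSE
  recurse <- function(level) {
    if (found) return(invisible())
    if (level > k) {
      fit <- kabschFit(qPos[idx, , drop = FALSE], positions)
      posed <- applyRigid(qPos[idx, , drop = FALSE], fit$rotation,
                          fit$translation)
      if (all(sqrt(rowSums((posed - positions)^2)) <= tolerance))
        found <<- TRUE
      return(invisible())
    }
    for (q in cand[[level]]) {
      if (q %in% idx[seq_len(level - 1L)]) next
      idx[level] <<- q
      recurse(level + 1L)
    }
  }
  recurse(1L)
  found
}

#' Generate synthetic molecules from a fragment grammar
#'
#' Assembles SMILES by substituting random substituents into scaffold cores
#' (xanthine-like heteroaromatic cores by default, so that perception
#' smoke-tests touch acceptor-rich chemistry). Deterministic per seed; every
#' generated SMILES is validated through the chemistry backend.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param grammarPath Fragment grammar file (default the shipped
#'   xanthine-family grammar).
#' @param prefix Id prefix (default \code{"synth"}).
#' @return A \linkS4class{MoleculeSet} (no activities assigned).
#' @export
generateSyntheticMolecules <- function(n, seed = 7, grammarPath = NULL,
                                       prefix = "synth") {
  if (is.null(grammarPath))
    grammarPath <- system.file("extdata", "xanthine.frag",
                               package = "PharmSafe3D", mustWork = TRUE)
  lines <- readLines(grammarPath)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed grammar line: ", lines[bad][1])
  kind <- vapply(parts, `[`, "", 1L)
  frag <- vapply(parts, `[`, "", 2L)
  cores <- frag[kind == "core"]
  subs <- frag[kind == "sub"]
  if (!length(cores) || !length(subs))
    stop("grammar must contain at least one core and one sub line")
  chk <- chemBackend("parse", list(smiles = as.list(subs)))$results
  okSub <- vapply(chk, function(x) isTRUE(x$ok), logical(1))
  if (any(!okSub)) stop("invalid substituent fragment: ", subs[!okSub][1])

  set.seed(seed)
  smiles <- character(n)
  coreIdx <- integer(n)
  for (i in seq_len(n)) {
    coreIdx[i] <- sample(seq_along(cores), 1L)
    sm <- cores[coreIdx[i]]
    for (ph in c("{R1}", "{R2}")) {
      if (grepl(ph, sm, fixed = TRUE))
        sm <- sub(ph, sample(subs, 1L), sm, fixed = TRUE)
    }
    smiles[i] <- sm
  }
  parsed <- chemBackend("parse", list(smiles = as.list(smiles)))$results
  ok <- vapply(parsed, function(x) isTRUE(x$ok), logical(1))
  if (any(!ok))
    stop("grammar produced an unparsable SMILES: ", smiles[!ok][1])
  recs <- lapply(seq_len(n), function(i) {
    list(id = sprintf("%s_%03d", prefix, i),
         smiles = parsed[[i]]$canonical, pIC50 = NA_real_,
         setLabel = "unknown", mw = parsed[[i]]$mw,
         rotatableBonds = parsed[[i]]$rotatable_bonds,
         parentId = sprintf("%s_%03d", prefix, i), core = coreIdx[i],
         conformers = list())
  })
  newMoleculeSet(recs)
}

#' Assign synthetic activities
#'
#' pIC50 = intercept + bonus * matched + coefficients . occupancy +
#' N(0, noiseSD), with the active/inactive label set at the threshold
#' (active when pIC50 >= threshold). Returns the ground truth alongside.
#'
#' @param matched Logical vector (planted-pharmacophore membership).
#' @param X Optional binary occupancy matrix (rows aligned with
#'   \code{matched}).
#' @param coefficients Optional coefficient vector over \code{X} columns.
#' @param intercept Baseline pIC50 (default 5.0).
#' @param bonus Added activity for planted matches (default 1.5).
#' @param noiseSD Gaussian noise SD (default 0.3).
#' @param threshold Active/inactive threshold (default 5.0).
#' @param seed Integer seed.
#' @return List with \code{pIC50}, \code{active} (logical) and
#'   \code{groundTruth}.
#' @export
assignSyntheticActivities <- function(matched, X = NULL, coefficients = NULL,
                                      intercept = 5.0, bonus = 1.5,
                                      noiseSD = 0.3, threshold = 5.0,
                                      seed = 7) {
  stopifnot(noiseSD >= 0)
  n <- length(matched)
  set.seed(seed)
  contrib <- if (!is.null(X) && !is.null(coefficients))
    as.numeric(X %*% coefficients) else 0
  pIC50 <- intercept + bonus * as.numeric(matched) + contrib +
    stats::rnorm(n, 0, noiseSD)
  list(pIC50 = pIC50, active = pIC50 >= threshold,
       groundTruth = list(intercept = intercept, bonus = bonus,
                          coefficients = coefficients, noiseSD = noiseSD,
                          threshold = threshold))
}

#' Generate a synthetic QSAR recovery data set
#'
#' Builds aligned pseudo-molecules whose activity is exactly linear in their
#' cube occupancy plus Gaussian noise. A pool of candidate atom slots
#' (positions spaced at least 4 Angstrom apart, each with an atom class) is
#' defined once; every molecule activates each slot independently with
#' probability 1/2. A fixed number of slots carry nonzero planted
#' coefficients; the ground-truth coefficient of every descriptor cube is
#' the slot coefficient divided by the slot's cube count, so
#' \code{y = cubeTruth . occupancy + noise} holds exactly.
#'
#' @param nTrain,nTest Set sizes (default 120 / 40).
#' @param nSlots Candidate slot count (default 24).
#' @param nPlanted Slots with nonzero coefficients (default 8).
#' @param noiseSD Gaussian noise SD on pIC50 (default 0.3).
#' @param intercept Baseline pIC50 (default 5.0).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} (each \code{structures},
#'   \code{slots} membership matrix, \code{y}), and \code{truth}
#'   (slot positions, classes, planted \code{beta}).
#' @export
generateSyntheticQSARSet <- function(nTrain = 120, nTest = 40, nSlots = 24,
                                     nPlanted = 8, noiseSD = 0.3,
                                     intercept = 5.0, seed = 11) {
  set.seed(seed)
  # slot lattice: 4 Angstrom spacing guarantees disjoint cube sets
  gridSide <- ceiling(nSlots^(1 / 3))
  lattice <- as.matrix(expand.grid(x = seq_len(gridSide),
                                   y = seq_len(gridSide),
                                   z = seq_len(gridSide)))[seq_len(nSlots), ]
  slotPos <- (lattice - 1) * 4.0
  slotClass <- rep(c("W", "H", "D", "N", "P", "H"),
                   length.out = nSlots)
  beta <- numeric(nSlots)
  planted <- sort(sample.int(nSlots, nPlanted))
  beta[planted] <- sample(c(-1, 1), nPlanted, replace = TRUE) *
    stats::runif(nPlanted, 0.5, 1.0)

  makeSide <- function(n, offset) {
    Z <- matrix(stats::rbinom(n * nSlots, 1L, 0.5), n, nSlots)
    # guarantee every molecule occupies at least one slot
    none <- rowSums(Z) == 0L
    Z[none, 1L] <- 1L
    structures <- lapply(seq_len(n), function(i) {
      on <- which(Z[i, ] == 1L)
      list(coords = slotPos[on, , drop = FALSE],
           classes = slotClass[on], radii = rep(1.7, length(on)))
    })
    names(structures) <- sprintf("m%s_%03d", offset, seq_len(n))
    y <- intercept + as.numeric(Z %*% beta) + stats::rnorm(n, 0, noiseSD)
    list(structures = structures, slots = Z, y = y)
  }
  train <- makeSide(nTrain, "tr")
  test <- makeSide(nTest, "te")
  list(train = train, test = test,
       truth = list(slotPositions = slotPos, slotClasses = slotClass,
                    beta = beta, planted = planted, intercept = intercept,
                    noiseSD = noiseSD))
}

#' Ground-truth cube coefficients of a synthetic QSAR set
#'
#' Maps every retained descriptor column of a fitted grid back to its
#' generating slot (cube centre within the van-der-Waals radius of the slot
#' atom, same class) and spreads the slot coefficient uniformly over its
#' cubes.
#'
#' @param columns Column table from \code{\link{buildOccupancyDescriptors}}.
#' @param truth The \code{truth} element of
#'   \code{\link{generateSyntheticQSARSet}}.
#' @param radius Slot atom radius (default 1.7).
#' @return Numeric vector of ground-truth coefficients per column
#'   (0 for cubes of unplanted slots).
#' @export
syntheticCubeTruth <- function(columns, truth, radius = 1.7) {
  centres <- as.matrix(columns[, c("x", "y", "z")])
  out <- numeric(nrow(columns))
  slotCubeCount <- numeric(nrow(truth$slotPositions))
  slotOf <- integer(nrow(columns))
  for (j in seq_len(nrow(truth$slotPositions))) {
    d2 <- (centres[, 1] - truth$slotPositions[j, 1])^2 +
      (centres[, 2] - truth$slotPositions[j, 2])^2 +
      (centres[, 3] - truth$slotPositions[j, 3])^2
    inSlot <- d2 <= radius^2 & columns$class == truth$slotClasses[j]
    slotOf[inSlot] <- j
    slotCubeCount[j] <- sum(inSlot)
  }
  has <- slotOf > 0L
  out[has] <- truth$beta[slotOf[has]] / slotCubeCount[slotOf[has]]
  out
}
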