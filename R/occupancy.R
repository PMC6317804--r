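# Binary cube-occupancy descriptors for hypothesis-aligned molecules.
#
# A rectangular grid of 1 Angstrom^3 cubes is laid over the space occupied
# by the aligned training actives (plus a margin). For every molecule, the
# bit for (cube, atom class) is 1 exactly when the cube centre lies within
# the van-der-Waals radius of at least one atom of that class in the aligned
# pose. Columns constant across the training set carry no information for
# the regression and are dropped, with reversible bookkeeping.

#' Build an occupancy grid over aligned structures
#'
#' @param coordsList List of aligned heavy-atom coordinate matrices (the
#'   training actives).
#' @param spacing Cube edge length in Angstrom (default 1.0).
#' @param margin Margin beyond the bounding box in Angstrom (default 2.0).
#' @return A list with \code{origin}, \code{spacing} and integer \code{dims}.
#' @export
buildOccupancyGrid <- function(coordsList, spacing = 1.0, margin = 2.0) {
  stopifnot(spacing > 0, length(coordsList) >= 1L)
  allC <- do.call(rbind, coordsList)
  lo <- apply(allC, 2L, min) - margin
  hi <- apply(allC, 2L, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing))
  dims[dims < 1L] <- 1L
  list(origin = as.numeric(lo), spacing = spacing, dims = dims)
}

# Linear cube index (1-based) of integer cube coordinates, or NA outside.
.cubeLinear <- function(ijk, dims) {
  bad <- ijk[, 1] < 1L | ijk[, 1] > dims[1] | ijk[, 2] < 1L |
    ijk[, 2] > dims[2] | ijk[, 3] < 1L | ijk[, 3] > dims[3]
  lin <- (ijk[, 3] - 1L) * dims[1] * dims[2] + (ijk[, 2] - 1L) * dims[1] +
    ijk[, 1]
  lin[bad] <- NA_integer_
  lin
}

# Occupied (cube, class) keys of one aligned structure on a grid.
.occupiedKeys <- function(structure, grid) {
  coords <- structure$coords
  classes <- structure$classes
  radii <- rep_len(structure$radii %||% 1.7, nrow(coords))
  sp <- grid$spacing
  keys <- character()
  for (a in seq_len(nrow(coords))) {
    ctr <- coords[a, ]
    r <- radii[a]
    loIdx <- pmax(1L, as.integer(floor((ctr - r - grid$origin) / sp)) + 1L)
    hiIdx <- pmin(grid$dims,
                  as.integer(floor((ctr + r - grid$origin) / sp)) + 1L)
    if (any(loIdx > grid$dims) || any(hiIdx < 1L)) next
    ii <- seq(loIdx[1], hiIdx[1]); jj <- seq(loIdx[2], hiIdx[2])
    kk <- seq(loIdx[3], hiIdx[3])
    cand <- as.matrix(expand.grid(ii, jj, kk))
    centres <- sweep((cand - 0.5) * sp, 2L, grid$origin, "+")
    d2 <- (centres[, 1] - ctr[1])^2 + (centres[, 2] - ctr[2])^2 +
      (centres[, 3] - ctr[3])^2
    hit <- cand[d2 <= r^2, , drop = FALSE]
    if (!nrow(hit)) next
    lin <- .cubeLinear(hit, grid$dims)
    keys <- c(keys, paste0(lin, ":", classes[a]))
  }
  unique(keys)
}

#' Build binary cube-occupancy descriptors
#'
#' @param structures List of aligned structures, each a list with
#'   \code{coords} (heavy-atom n x 3 matrix, already posed in the hypothesis
#'   frame), \code{classes} (atom class per atom) and optional \code{radii}.
#' @param gridFrom Indices of \code{structures} used to define the grid (the
#'   training actives); defaults to all.
#' @param spacing Cube edge (Angstrom, default 1.0).
#' @param margin Grid margin (Angstrom, default 2.0).
#' @param dropConstant Drop columns constant across rows (default TRUE).
#' @param grid Optional pre-built grid (from a fitted model) overriding
#'   \code{gridFrom}.
#' @param columnKeys Optional fixed column key set (prediction on a model's
#'   retained columns).
#' @return A list with the binary matrix \code{X} (rows in input order,
#'   column names \code{"<cube>:<class>"}), the \code{grid}, a \code{columns}
#'   data frame (\code{key}, \code{ix}, \code{iy}, \code{iz}, \code{class},
#'   cube-centre coordinates) and \code{droppedConstant} (keys of dropped
#'   always-on columns).
#' @export
buildOccupancyDescriptors <- function(structures, gridFrom = NULL,
                                      spacing = 1.0, margin = 2.0,
                                      dropConstant = TRUE, grid = NULL,
                                      columnKeys = NULL) {
  stopifnot(length(structures) >= 1L)
  if (is.null(grid)) {
    if (is.null(gridFrom)) gridFrom <- seq_along(structures)
    grid <- buildOccupancyGrid(lapply(structures[gridFrom], `[[`, "coords"),
                               spacing, margin)
  }
  keysPerMol <- lapply(structures, .occupiedKeys, grid = grid)
  empty <- !lengths(keysPerMol)
  if (any(empty))
    warning(sum(empty), " molecule(s) occupy no grid cube ",
            "(pose outside the grid?): all-zero descriptor row")
  if (is.null(columnKeys)) {
    columnKeys <- sort(unique(unlist(keysPerMol)))
  }
  X <- matrix(0L, nrow = length(structures), ncol = length(columnKeys),
              dimnames = list(names(structures), columnKeys))
  for (i in seq_along(keysPerMol)) {
    hit <- intersect(keysPerMol[[i]], columnKeys)
    X[i, hit] <- 1L
  }
  droppedConstant <- character()
  if (dropConstant && nrow(X) > 1L) {
    csum <- colSums(X)
    const <- csum == 0L | csum == nrow(X)
    droppedConstant <- colnames(X)[const & csum == nrow(X)]
    X <- X[, !const, drop = FALSE]
  }
  list(X = X, grid = grid, columns = .columnTable(colnames(X), grid),
       droppedConstant = droppedConstant)
}

# Decode "<linear>:<class>" keys into cube indices and centre coordinates.
.columnTable <- function(keys, grid) {
  if (!length(keys))
    return(data.frame(key = character(), ix = integer(), iy = integer(),
                      iz = integer(), class = character(), x = numeric(),
                      y = numeric(), z = numeric()))
  parts <- strsplit(keys, ":", fixed = TRUE)
  lin <- as.integer(vapply(parts, `[`, "", 1L))
  cls <- vapply(parts, `[`, "", 2L)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  iz <- (lin - 1L) %/% (nx * ny) + 1L
  rem <- (lin - 1L) %% (nx * ny)
  iy <- rem %/% nx + 1L
  ix <- rem %% nx + 1L
  data.frame(key = keys, ix = ix, iy = iy, iz = iz, class = cls,
             x = grid$origin[1] + (ix - 0.5) * grid$spacing,
             y = grid$origin[2] + (iy - 0.5) * grid$spacing,
             z = grid$origin[3] + (iz - 0.5) * grid$spacing,
             stringsAsFactors = FALSE)
}

#' Descriptor row of one aligned structure on a model's columns
#'
#' @param model A \linkS4class{CubeQSARModel}.
#' @param structure Aligned structure (\code{coords}, \code{classes},
#'   optional \code{radii}) posed in the hypothesis frame.
#' @return Binary vector over the model's retained descriptor columns.
#' @export
descriptorRow <- function(model, structure) {
  grid <- list(origin = model@gridOrigin, spacing = model@gridSpacing,
               dims = model@gridDims)
  keys <- .occupiedKeys(structure, grid)
  as.integer(model@columns$key %in% keys)
}
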