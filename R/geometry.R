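# Rigid-body geometry: Kabsch superposition, rigid transforms, and
# van-der-Waals volume overlap. These primitives underpin hypothesis
# matching, conformer deduplication and hypothesis scoring.

#' Kabsch rigid superposition
#'
#' Finds the proper rotation and translation that best superimpose the moving
#' point set \code{P} onto the fixed point set \code{Q} in the least-squares
#' sense, via singular value decomposition of the cross-covariance matrix.
#' The returned rotation always has determinant +1 (reflections are never
#' produced).
#'
#' @param P Numeric n x 3 matrix, the moving points.
#' @param Q Numeric n x 3 matrix, the fixed points (row i pairs with row i
#'   of \code{P}).
#' @return A list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3) and \code{rmsd} such that
#'   \code{P \%*\% t(rotation) + translation} approximates \code{Q} with
#'   root-mean-square deviation \code{rmsd}.
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' th <- pi / 3
#' R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabschFit(P, P %*% t(R) + 2)
#' fit$rmsd   # ~0
#' @export
kabschFit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 1L)
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2L, cP); Q0 <- sweep(Q, 2L, cQ)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Q0)^2)))
  list(rotation = R, translation = as.numeric(cQ - R %*% cP), rmsd = rmsd)
}

#' Apply a rigid motion to a coordinate matrix
#'
#' @param X Numeric n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector.
#' @return The transformed n x 3 matrix.
#' @export
applyRigid <- function(X, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(X) %*% t(rotation), 2L, -translation)
}

#' Best-fit RMSD between two conformations
#'
#' Root-mean-square deviation after optimal rigid superposition, used for
#' conformer deduplication (heavy atoms, canonical atom order).
#'
#' @param A,B Numeric n x 3 coordinate matrices in the same atom order.
#' @return The RMSD in the units of the input (Angstrom throughout the
#'   package).
#' @export
bestFitRMSD <- function(A, B) {
  kabschFit(A, B)$rmsd
}

#' Random proper rotation matrix
#'
#' Draws a rotation uniformly (Haar measure) via QR decomposition of a
#' standard normal matrix, with the determinant forced to +1. Uses the
#' current RNG state.
#' @return A 3 x 3 rotation matrix.
#' @keywords internal
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Bondi van-der-Waals radii (Angstrom); elements outside the table fall
# back to the carbon radius.
.vdwTable <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Van-der-Waals radii for element symbols
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of Bondi radii in Angstrom (1.70 for elements not
#'   in the internal table).
#' @export
vdwRadii <- function(elements) {
  r <- .vdwTable[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Volume-overlap Tanimoto between two sets of spheres
#'
#' The shared-volume Tanimoto coefficient
#' V(A intersect B) / V(A union B) of two van-der-Waals sphere sets,
#' estimated by regular grid sampling at the given spacing. Used as the
#' volume component of hypothesis scores.
#'
#' @param coordsA,coordsB Numeric n x 3 sphere centres.
#' @param radiiA,radiiB Sphere radii (recycled).
#' @param spacing Grid sampling spacing in Angstrom (default 0.5).
#' @return Overlap Tanimoto in [0, 1].
#' @examples
#' a <- matrix(0, 1, 3)
#' volumeOverlapTanimoto(a, a, 1.7, 1.7)  # identical spheres -> 1
#' @export
volumeOverlapTanimoto <- function(coordsA, coordsB, radiiA = 1.7,
                                  radiiB = 1.7, spacing = 0.5) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  radiiA <- rep_len(radiiA, nrow(coordsA))
  radiiB <- rep_len(radiiB, nrow(coordsB))
  lo <- pmin(apply(coordsA - radiiA, 2L, min),
             apply(coordsB - radiiB, 2L, min)) - spacing / 2
  hi <- pmax(apply(coordsA + radiiA, 2L, max),
             apply(coordsB + radiiB, 2L, max)) + spacing / 2
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inSet <- function(coords, radii) {
    hit <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(coords))) {
      d2 <- (pts[, 1] - coords[i, 1])^2 + (pts[, 2] - coords[i, 2])^2 +
        (pts[, 3] - coords[i, 3])^2
      hit <- hit | d2 <= radii[i]^2
    }
    hit
  }
  inA <- inSet(coordsA, radiiA)
  inB <- inSet(coordsB, radiiB)
  uni <- sum(inA | inB)
  if (uni == 0L) return(0)
  sum(inA & inB) / uni
}

#' Normalize a vector to unit length
#' @param v Numeric vector.
#' @return Unit vector, or the zero vector if the input has zero norm.
#' @keywords internal
unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) return(v * 0)
  v / n
}
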