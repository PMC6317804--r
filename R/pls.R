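# Partial least squares (NIPALS, single response) on binary occupancy
# descriptors, plus the full model-statistics panel. Predictors are
# mean-centred but not variance-scaled (they are binary indicators);
# initialization is deterministic, so fits are bit-reproducible.

#' NIPALS partial least squares for a single response
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response vector (length n).
#' @param factors Number of latent factors.
#' @return List with \code{coefficients} (length p), \code{intercept},
#'   \code{fitted}, \code{xMean}, \code{yMean}, the factor matrices
#'   \code{W}, \code{P}, loadings \code{q}, and \code{factorsUsed} (may be
#'   lower than requested when the residual collapses).
#' @export
nipalsPLS <- function(X, y, factors) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::var(y) == 0) stop("response has zero variance")
  if (factors < 1L) stop("factors must be >= 1")
  if (factors >= n) stop("factors must be < number of observations")
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2L, xMean)
  f <- y - yMean
  W <- matrix(0, p, factors); P <- matrix(0, p, factors)
  q <- numeric(factors)
  used <- 0L
  for (a in seq_len(factors)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - t_ * q_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_
    used <- a
  }
  if (used == 0L) stop("PLS extracted no factors (degenerate predictors)")
  Wu <- W[, seq_len(used), drop = FALSE]
  Pu <- P[, seq_len(used), drop = FALSE]
  qu <- q[seq_len(used)]
  B <- Wu %*% solve(crossprod(Pu, Wu), qu)
  coefficients <- as.numeric(B)
  intercept <- yMean - sum(xMean * coefficients)
  fitted <- as.numeric(X %*% coefficients + intercept)
  list(coefficients = coefficients, intercept = intercept, fitted = fitted,
       xMean = xMean, yMean = yMean, W = Wu, P = Pu, q = qu,
       factorsUsed = used)
}

#' Fit a cube-occupancy PLS QSAR model
#'
#' Fits a mean-centred NIPALS PLS regression of pIC50 on binary cube
#' descriptors and computes the training statistics panel:
#' \itemize{
#'   \item \code{R2 = 1 - SSE/SST} (squared correlation of fit),
#'   \item \code{SD = sqrt(SSE / (n - factors - 1))}, the standard deviation
#'     of regression,
#'   \item \code{F = (SSR/factors) / (SSE/(n - factors - 1))}, the variance
#'     ratio,
#'   \item \code{p}, the upper tail of the F(factors, n - factors - 1)
#'     distribution.
#' }
#'
#' @param descriptors Result of \code{\link{buildOccupancyDescriptors}} (or a
#'   plain binary matrix, in which case grid metadata is left empty).
#' @param y pIC50 vector aligned with the descriptor rows.
#' @param factors Number of PLS factors (default 3, the conventional
#'   setting).
#' @param hypothesisId Identifier of the aligning hypothesis.
#' @param threshold Activity threshold on the pIC50 scale (default 5.0).
#' @return A \linkS4class{CubeQSARModel}.
#' @export
fitQSAR <- function(descriptors, y, factors = 3, hypothesisId = "",
                    threshold = 5.0) {
  if (is.matrix(descriptors)) {
    X0 <- descriptors
    keys <- colnames(X0) %||% paste0("c", seq_len(ncol(X0)))
    descriptors <- list(
      X = X0,
      grid = list(origin = c(0, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
      columns = data.frame(key = keys, ix = NA_integer_, iy = NA_integer_,
                           iz = NA_integer_, class = "X", x = NA_real_,
                           y = NA_real_, z = NA_real_,
                           stringsAsFactors = FALSE))
  }
  X <- descriptors$X
  n <- nrow(X)
  if (n < factors + 2) stop("need at least factors + 2 training molecules")
  if (!all(is.finite(y))) stop("training pIC50 values must be finite")
  fit <- nipalsPLS(X, y, factors)
  sse <- sum((y - fit$fitted)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  dfDen <- n - factors - 1
  Fval <- (ssr / factors) / (sse / dfDen)
  stats_ <- list(SD = sqrt(sse / dfDen), R2 = 1 - sse / sst, F = Fval,
                 p = stats::pf(Fval, factors, dfDen, lower.tail = FALSE),
                 n = n)
  cols <- descriptors$columns
  if (is.null(cols$key)) cols$key <- colnames(X)
  new("CubeQSARModel", hypothesisId = as.character(hypothesisId),
      gridOrigin = descriptors$grid$origin,
      gridSpacing = descriptors$grid$spacing,
      gridDims = as.integer(descriptors$grid$dims),
      columns = if (nrow(cols)) cols else .columnTable(colnames(X),
                                                       descriptors$grid),
      coefficients = fit$coefficients, intercept = fit$intercept,
      plsFactors = as.integer(fit$factorsUsed), xMean = fit$xMean,
      trainingIds = rownames(X) %||% as.character(seq_len(n)),
      threshold = threshold, stats = stats_)
}

#' @describeIn fitQSAR Predict from a descriptor matrix or vector.
#' @param object A \linkS4class{CubeQSARModel}.
#' @param newdata Binary descriptor matrix (columns in model order) or a
#'   single row vector.
#' @param ... Ignored.
#' @export
setMethod("predict", "CubeQSARModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  as.numeric(newdata %*% object@coefficients + object@intercept)
})

#' Predict the activity of one molecule against a model
#'
#' Selects the best conformer match against the hypothesis (maximum matched
#' sites, then minimum RMSD), poses the structure into the hypothesis frame,
#' builds its descriptor row on the model grid and applies the regression.
#' Molecules with no conformer matching at least \code{minSites} sites are
#' "non hits" and return \code{NA}.
#'
#' @param model A \linkS4class{CubeQSARModel}.
#' @param confSets List of \linkS4class{SiteSet} objects for the molecule's
#'   conformers.
#' @param confStructures List of structures (\code{coords}, \code{classes},
#'   \code{radii}), one per conformer, in the molecule frame.
#' @param hyp The aligning \linkS4class{PharmHypothesis}.
#' @param minSites Minimum matched sites (default 3).
#' @return A list with \code{matched}, \code{nMatched},
#'   \code{predicted} (\code{NA} for non hits) and the \code{match} detail.
#' @export
predictActivity <- function(model, confSets, confStructures, hyp,
                            minSites = 3L) {
  m <- bestConformerMatch(confSets, hyp, minSites)
  if (is.null(m))
    return(list(matched = FALSE, nMatched = 0L, predicted = NA_real_,
                match = NULL))
  st <- confStructures[[m$confId]]
  posed <- list(coords = applyRigid(st$coords, m$rotation, m$translation),
                classes = st$classes, radii = st$radii)
  row <- descriptorRow(model, posed)
  list(matched = TRUE, nMatched = m$nMatched,
       predicted = predict(model, row), match = m)
}

#' Test-set statistics panel
#'
#' Root-mean-square error, predictive Q2 (1 - SSE/SST about the test mean)
#' and the Pearson correlation of predicted versus observed activities.
#' Molecules without predictions (non hits) must be excluded by the caller.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3 pairs).
#' @return Named list with \code{RMSE}, \code{Q2}, \code{pearsonR} and
#'   \code{n}.
#' @export
qsarTestStats <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L)
    stop("need at least 3 predictable test molecules")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  list(RMSE = sqrt(mean((observed - predicted)^2)),
       Q2 = 1 - sse / sst,
       pearsonR = stats::cor(observed, predicted),
       n = length(observed))
}

#' Evaluate a model on a test set of descriptor rows
#'
#' Convenience wrapper around \code{\link{qsarTestStats}}; non-finite
#' predictions (non hits) are dropped from the regression statistics.
#'
#' @param model A \linkS4class{CubeQSARModel}.
#' @param X Test descriptor matrix on the model's columns.
#' @param observed Observed pIC50 values.
#' @return As \code{\link{qsarTestStats}}.
#' @export
evaluateOnTest <- function(model, X, observed) {
  qsarTestStats(observed, predict(model, X))
}

#' Stability of model predictions to training-set composition
#'
#' For each resampling round a random subset of the training set (holding
#' out \code{holdoutFraction}) is refit and the Pearson correlation between
#' the refit predictions and the full-model predictions over all training
#' molecules is recorded; the stability is the mean correlation (maximum 1).
#' Seeded and deterministic.
#'
#' @param model The fitted full \linkS4class{CubeQSARModel}.
#' @param X,y The training descriptors and responses used to fit
#'   \code{model}.
#' @param rounds Number of resampling rounds (>= 2, default 10).
#' @param holdoutFraction Fraction held out per round (in (0, 0.5), default
#'   0.2).
#' @param seed Integer seed.
#' @return The stability estimate (a value <= 1).
#' @export
estimateStability <- function(model, X, y, rounds = 10, holdoutFraction = 0.2,
                              seed = 1) {
  stopifnot(rounds >= 2, holdoutFraction > 0, holdoutFraction < 0.5)
  n <- nrow(X)
  full <- predict(model, X)
  cors <- numeric()
  set.seed(seed)
  for (r in seq_len(rounds)) {
    keep <- sort(sample.int(n, size = round((1 - holdoutFraction) * n)))
    refit <- tryCatch(
      nipalsPLS(X[keep, , drop = FALSE], y[keep], model@plsFactors),
      error = function(e) NULL)
    if (is.null(refit)) {
      warning("degenerate refit in stability round ", r, "; round skipped")
      next
    }
    pred <- as.numeric(X %*% refit$coefficients + refit$intercept)
    if (stats::sd(pred) == 0 || stats::sd(full) == 0) {
      warning("zero-variance predictions in stability round ", r,
              "; round skipped")
      next
    }
    cors <- c(cors, stats::cor(pred, full))
  }
  if (!length(cors)) stop("all stability rounds degenerate")
  out <- mean(cors)
  attr(out, "roundCorrelations") <- cors
  out
}

#' Export the cube-coefficient map of a model
#'
#' One row per retained descriptor column: cube centre coordinates, atom
#' class, coefficient and sign, suitable for rendering favorable (positive)
#' and unfavorable (negative) regions per class.
#'
#' @param model A \linkS4class{CubeQSARModel}.
#' @param byClass Optional class filter (one of D, H, N, P, W, X).
#' @return Data frame with columns \code{x}, \code{y}, \code{z},
#'   \code{class}, \code{coefficient}, \code{sign}.
#' @export
exportCoefficientMap <- function(model, byClass = NULL) {
  tab <- model@columns
  tab$coefficient <- model@coefficients
  tab$sign <- ifelse(tab$coefficient > 0, "positive",
                     ifelse(tab$coefficient < 0, "negative", "zero"))
  if (!is.null(byClass)) {
    if (!byClass %in% .ATOM_CLASSES)
      stop("unknown atom class filter: ", byClass)
    tab <- tab[tab$class == byClass, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("x", "y", "z", "class", "coefficient", "sign")]
}

#' Write / read a coefficient map as CSV (full precision round trip)
#'
#' @param map Data frame from \code{\link{exportCoefficientMap}}.
#' @param path CSV path.
#' @return Invisibly the path, or the data frame when reading.
#' @export
writeCoefficientMap <- function(map, path) {
  map$coefficient <- format(map$coefficient, digits = 17, scientific = TRUE,
                            trim = TRUE)
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCoefficientMap
#' @export
readCoefficientMap <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$coefficient <- as.numeric(tab$coefficient)
  tab
}

#' Serialize a fitted model to JSON
#' @param model A \linkS4class{CubeQSARModel}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeModelJSON <- function(model, path) {
  payload <- list(format = "PharmSafe3D-qsar-1",
                  hypothesisId = model@hypothesisId,
                  grid = list(origin = model@gridOrigin,
                              spacing = model@gridSpacing,
                              dims = model@gridDims),
                  columns = model@columns, coefficients = model@coefficients,
                  intercept = model@intercept, plsFactors = model@plsFactors,
                  xMean = model@xMean, trainingIds = model@trainingIds,
                  threshold = model@threshold, stats = model@stats)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#' @param path Path written by \code{\link{writeModelJSON}}.
#' @return A \linkS4class{CubeQSARModel}.
#' @export
readModelJSON <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CubeQSARModel", hypothesisId = pl$hypothesisId,
      gridOrigin = pl$grid$origin, gridSpacing = pl$grid$spacing,
      gridDims = as.integer(pl$grid$dims),
      columns = as.data.frame(pl$columns),
      coefficients = pl$coefficients, intercept = pl$intercept,
      plsFactors = as.integer(pl$plsFactors), xMean = pl$xMean,
      trainingIds = pl$trainingIds, threshold = pl$threshold,
      stats = as.list(pl$stats))
}
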