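# Editable pharmacophore feature definitions: a plain-text table mapping
# each of the six site types to SMARTS patterns, a placement rule and a
# directionality flag. The shipped default table approximates the feature
# sets common pharmacophore tools use; users can point to their own table
# to mirror any vendor definition.

#' Built-in pharmacophore feature definitions
#'
#' Loads the default feature-definition table shipped with the package,
#' covering the six site types: hydrogen-bond acceptor (A), hydrogen-bond
#' donor (D), hydrophobe (H), negative ionizable (N), positive ionizable (P)
#' and aromatic ring (R).
#'
#' @return A data frame with columns \code{type}, \code{smarts},
#'   \code{placement} (\code{"atom"}, \code{"group_centroid"} or
#'   \code{"ring_centroid"}) and \code{directed} (logical).
#' @examples
#' defs <- defaultFeatureDefinitions()
#' table(defs$type)
#' @export
defaultFeatureDefinitions <- function() {
  loadFeatureDefinitions(system.file("extdata", "feature_definitions.tsv",
                                     package = "PharmSafe3D",
                                     mustWork = TRUE),
                         validateSmarts = FALSE)
}

#' Load pharmacophore feature definitions from a file
#'
#' Parses a tab-separated table with columns type, SMARTS, placement and
#' directed flag. All six feature types must be present; unknown type codes
#' or placements are fatal and name the offending line.
#'
#' @param path Path to the definition table.
#' @param validateSmarts Check every pattern against the chemistry backend
#'   and fail naming any pattern that does not compile (default \code{TRUE};
#'   the shipped table skips this check).
#' @return A data frame as in \code{\link{defaultFeatureDefinitions}}.
#' @export
loadFeatureDefinitions <- function(path, validateSmarts = TRUE) {
  if (!file.exists(path)) stop("feature definition file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineNo <- which(keep)
  bad <- which(lengths(rows) != 4L)
  if (length(bad))
    stop("malformed feature definition at line ", lineNo[bad[1]],
         ": expected 4 tab-separated fields")
  defs <- data.frame(type = vapply(rows, `[`, "", 1L),
                     smarts = vapply(rows, `[`, "", 2L),
                     placement = vapply(rows, `[`, "", 3L),
                     directed = toupper(vapply(rows, `[`, "", 4L)) == "TRUE",
                     stringsAsFactors = FALSE)
  unknown <- !defs$type %in% .SITE_TYPES
  if (any(unknown))
    stop("unknown feature code '", defs$type[unknown][1], "' at line ",
         lineNo[unknown][1])
  badPlace <- !defs$placement %in% c("atom", "group_centroid", "ring_centroid")
  if (any(badPlace))
    stop("unknown placement '", defs$placement[badPlace][1], "' at line ",
         lineNo[badPlace][1])
  missing <- setdiff(.SITE_TYPES, defs$type)
  if (length(missing))
    stop("missing feature type ", paste(missing, collapse = ", "))
  if (validateSmarts) {
    chk <- chemBackend("check_smarts", list(smarts = as.list(defs$smarts)))
    ok <- vapply(chk$results, function(x) isTRUE(x$ok), logical(1))
    if (any(!ok))
      stop("malformed SMARTS pattern: ", defs$smarts[!ok][1])
  }
  defs
}
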