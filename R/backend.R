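#' @title Chemistry backend bridge
#'
#' @description PharmSafe3D delegates standard cheminformatics primitives
#' (SMILES parsing, salt stripping, stereoisomer enumeration,
#' distance-geometry conformer embedding with force-field minimization,
#' SMARTS substructure matching, radial fingerprints, SDF input/output) to
#' RDKit through a bundled Python helper script. One helper process is
#' spawned per request; requests are batched over molecules so the process
#' startup cost is paid once per operation, not per compound. All stochastic
#' operations receive explicit seeds and run single-threaded, so every
#' backend result is reproducible bit-for-bit.
#'
#' @param op Operation name understood by the helper
#'   (\code{"parse"}, \code{"standardize"}, \code{"embed"},
#'   \code{"fingerprint"}, \code{"sdf_write"}, \code{"sdf_read"}).
#' @param payload Named list forming the JSON request body.
#' @return The decoded JSON response as a nested list.
#' @keywords internal
chemBackend <- function(op, payload = list()) {
  script <- system.file("python", "chem_backend.py",
                        package = "PharmSafe3D", mustWork = TRUE)
  payload$op <- op
  req <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null")
  out <- suppressWarnings(
    system2(pythonBinary(), shQuote(script), input = req, stdout = TRUE,
            stderr = FALSE))
  status <- attr(out, "status")
  txt <- paste(out, collapse = "")
  if (!nzchar(txt)) {
    stop("chemistry backend produced no output (exit status ",
         if (is.null(status)) 0 else status, ")")
  }
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (isTRUE(res$fatal)) {
    stop("chemistry backend error: ", res$error)
  }
  res
}

#' Locate the python interpreter used for the chemistry backend
#'
#' The interpreter can be overridden with \code{options(PharmSafe3D.python=)};
#' by default the \code{python} found on the PATH is used.
#' @return Path to the python executable.
#' @keywords internal
pythonBinary <- function() {
  getOption("PharmSafe3D.python", "python")
}
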