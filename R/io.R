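## Delimited-text readers and JSON result envelopes for the command-line
## pipelines. Spectra and trajectories travel as plain whitespace- or
## tab-delimited text with `#` comment headers; machine-readable results
## travel as JSON.

#' Read a delimited (x, y[, err]) table or raw sample column
#'
#' Reads whitespace-, tab-, or comma-delimited numeric text; lines starting
#' with `#` (and blank lines) are ignored. Files with two or more columns
#' are interpreted as `(x, y[, err])` and returned with a strictly
#' increasing abscissa (sorted with a warning if needed; duplicated
#' abscissa values are an error); a one-column file is returned as raw
#' `samples`. A malformed numeric field raises an error naming the
#' offending line.
#'
#' @param path File path.
#' @param columns Expected column count (1, 2, or 3), or `NA` (default) to
#'   accept whatever the file has.
#' @return A data frame with columns among `x`, `y`, `err` (or a single
#'   `samples` column).
#' @export
read_xy <- function(path, columns = NA) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop(sprintf("no data lines in %s", path))
  fields <- strsplit(trimws(raw[keep]), "[,[:space:]]+")
  ncol <- length(fields[[1]])
  if (!ncol %in% 1:3)
    stop(sprintf("line %d: expected 1-3 numeric columns, found %d",
                 keep[1], ncol))
  if (!is.na(columns) && ncol != columns)
    stop(sprintf("expected %d column(s), file has %d", columns, ncol))
  vals <- matrix(NA_real_, length(fields), ncol)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != ncol)
      stop(sprintf("line %d: expected %d fields, found %d", keep[i], ncol,
                   length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v) | !is.finite(v)))
      stop(sprintf("line %d: malformed numeric field '%s'", keep[i],
                   f[which(is.na(suppressWarnings(as.numeric(f))) |
                             !is.finite(suppressWarnings(as.numeric(f))))[1]]))
    vals[i, ] <- v
  }
  if (ncol == 1L) return(data.frame(samples = vals[, 1]))
  out <- data.frame(x = vals[, 1], y = vals[, 2])
  if (ncol == 3L) out$err <- vals[, 3]
  if (is.unsorted(out$x)) {
    warning("abscissa not increasing; rows sorted by x")
    out <- out[order(out$x), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (any(diff(out$x) == 0)) stop("duplicated abscissa values")
  out
}

#' Build a machine-readable result envelope
#'
#' Wraps a command's results with the tool version, the fully resolved
#' configuration (including defaulted values and the seed), and any
#' warnings, so a run can be reproduced from its own output.
#'
#' @param command Command name.
#' @param config Named list of resolved parameters (include the seed).
#' @param results Results payload (named list / data frame).
#' @param warnings Character vector of warnings.
#' @return A list of class `result_envelope`.
#' @export
result_envelope <- function(command, config, results,
                            warnings = character(0)) {
  stopifnot(is.character(command), length(command) == 1L, is.list(config))
  structure(list(schema = "voigtline/1",
                 version = as.character(packageVersion("voigtline")),
                 command = command, config = config, results = results,
                 warnings = as.character(warnings)),
            class = "result_envelope")
}

#' Write / read a result envelope as JSON
#'
#' JSON round-trips losslessly (full double precision); rerunning a
#' deterministic command from the embedded config (or a stochastic one
#' from the embedded seed) reproduces the payload.
#'
#' @param envelope A [result_envelope()].
#' @param path Output path.
#' @return `write_result` returns `path` invisibly; `read_result` returns
#'   the envelope as a list.
#' @export
write_result <- function(envelope, path) {
  stopifnot(inherits(envelope, "result_envelope"))
  ok <- tryCatch({
    jsonlite::write_json(unclass(envelope), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, na = "null")
    TRUE
  }, error = function(e)
    stop(sprintf("cannot write result to '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
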