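.SESSION_FORMAT <- "topotest-session"
.SESSION_VERSION <- 1L

#' Save and load an analysis session
#'
#' The session container keeps the data, the design definitions, the
#' analysis parameters and the results in one versioned file, so results
#' can never be separated from the data and parameters that produced
#' them. The format is a serialized named list with a format/version
#' manifest; round trips are lossless (bitwise-equal arrays).
#'
#' @param path file path for the session container.
#' @param dataset an [ErpDataset-class] (or NULL).
#' @param within,between design objects (or NULL).
#' @param options a [RandomizationOptions-class] (or NULL).
#' @param results a named list of result objects (or NULL).
#' @return \code{loadSession}: a named list with elements
#'   \code{dataset}, \code{within}, \code{between}, \code{options},
#'   \code{results}.
#' @export
saveSession <- function(path, dataset = NULL, within = NULL,
                        between = NULL, options = NULL,
                        results = NULL) {
  payload <- list(
    format = .SESSION_FORMAT,
    version = .SESSION_VERSION,
    schema = c("dataset", "within", "between", "options", "results"),
    dataset = dataset, within = within, between = between,
    options = options, results = results)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  if (!file.exists(path))
    stop("session file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read session container ", path, ": ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(payload) ||
      !identical(payload$format, .SESSION_FORMAT))
    stop("not a topotest session container: ", path)
  if (!identical(payload$version, .SESSION_VERSION))
    stop("session version mismatch: file has ",
         payload$version, ", this package reads ", .SESSION_VERSION)
  payload[c("dataset", "within", "between", "options", "results")]
}
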