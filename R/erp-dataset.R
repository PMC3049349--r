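#' Construct an ErpDataset
#'
#' @param data 4-D numeric array, subjects x conditions x time x
#'   sensors. Missing cells are not allowed.
#' @param samplingRate sampling rate in Hz.
#' @param onset latency of the first sample in ms relative to the event.
#' @param subjectLabels,conditionLabels optional label vectors; defaults
#'   are generated.
#' @param montage optional sensor montage data.frame (columns
#'   \code{name}, \code{x}, \code{y}[, \code{z}]); display only.
#' @param reference \code{"none"} or \code{"average"}.
#' @return an [ErpDataset-class].
#' @examples
#' x <- array(rnorm(2 * 2 * 5 * 4), c(2, 2, 5, 4))
#' ds <- erpDataset(x, samplingRate = 250)
#' nSensors(ds)
#' @export
erpDataset <- function(data, samplingRate = 1000, onset = 0,
                       subjectLabels = NULL, conditionLabels = NULL,
                       montage = NULL, reference = "none") {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L)
    stop("data must be a 4-D array (subject, condition, time, sensor)")
  if (is.null(subjectLabels))
    subjectLabels <- sprintf("S%02d", seq_len(d[1L]))
  if (is.null(conditionLabels))
    conditionLabels <- sprintf("C%d", seq_len(d[2L]))
  new("ErpDataset", data = data, samplingRate = samplingRate,
      onset = onset, subjectLabels = as.character(subjectLabels),
      conditionLabels = as.character(conditionLabels),
      montage = montage, reference = reference)
}

#' @rdname ErpDataset-class
#' @export
setMethod("erpData", "ErpDataset", function(x) x@data)

#' @rdname ErpDataset-class
#' @export
setMethod("samplingRate", "ErpDataset", function(x) x@samplingRate)

#' @rdname ErpDataset-class
#' @export
setMethod("subjectLabels", "ErpDataset", function(x) x@subjectLabels)

#' @rdname ErpDataset-class
#' @export
setMethod("conditionLabels", "ErpDataset",
          function(x) x@conditionLabels)

#' @rdname ErpDataset-class
#' @export
setMethod("nSubjects", "ErpDataset", function(x) dim(x@data)[1L])

#' @rdname ErpDataset-class
#' @export
setMethod("nConditions", "ErpDataset", function(x) dim(x@data)[2L])

#' @rdname ErpDataset-class
#' @export
setMethod("nTimePoints", "ErpDataset", function(x) dim(x@data)[3L])

#' @rdname ErpDataset-class
#' @export
setMethod("nSensors", "ErpDataset", function(x) dim(x@data)[4L])

#' @rdname ErpDataset-class
#' @export
setMethod("timePoints", "ErpDataset", function(x)
  x@onset + (seq_len(dim(x@data)[3L]) - 1L) * 1000 / x@samplingRate)

#' @rdname ErpDataset-class
#' @export
setMethod("montage", "ErpDataset", function(x) x@montage)

setMethod("show", "ErpDataset", function(object) {
  d <- dim(object@data)
  cat("ErpDataset:", d[1L], "subjects x", d[2L], "conditions x",
      d[3L], "time points x", d[4L], "sensors\n")
  cat("  sampling rate:", object@samplingRate, "Hz; onset:",
      object@onset, "ms; reference:", object@reference, "\n")
  cat("  conditions:", paste(object@conditionLabels, collapse = ", "),
      "\n")
  cat("  montage:", if (is.null(object@montage)) "none" else
    paste0(nrow(object@montage), " sensors"), "\n")
})

#' @rdname applyAverageReference
#' @export
setMethod("applyAverageReference", "ErpDataset", function(x) {
  d <- dim(x@data)
  if (d[4L] < 2L)
    stop("average reference undefined for single-sensor data")
  m <- matrix(x@data, prod(d[1:3]), d[4L])
  m <- m - rowMeans(m)
  x@data <- array(m, d)
  x@reference <- "average"
  validObject(x)
  x
})

#' @rdname applyAverageReference
#' @param map numeric vector: one scalp map.
#' @export
averageReferenceMap <- function(map) {
  if (length(map) < 2L)
    stop("average reference undefined for single-sensor data")
  map - mean(map)
}

# subset helper (subjects/conditions), keeps metadata consistent
.subsetDataset <- function(x, subjects = NULL, conditions = NULL) {
  s <- if (is.null(subjects)) seq_len(dim(x@data)[1L]) else subjects
  k <- if (is.null(conditions)) seq_len(dim(x@data)[2L]) else conditions
  x@data <- x@data[s, k, , , drop = FALSE]
  x@subjectLabels <- x@subjectLabels[s]
  x@conditionLabels <- x@conditionLabels[k]
  x
}
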