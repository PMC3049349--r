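#' Read one plain-ASCII map series file
#'
#' Reads a whitespace-delimited numeric text file with one row per time
#' point and one column per sensor (no header). Any run of spaces/tabs
#' delimits; the decimal separator is the point.
#'
#' @param path file path.
#' @return numeric matrix, time x sensors.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeLines(c("1 2", "3 4"), f)
#' readAsciiMapSeries(f)
#' @export
readAsciiMapSeries <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  nf <- count.fields(path, blank.lines.skip = TRUE)
  if (length(nf) == 0L)
    stop("empty file: ", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf(
      "ragged rows in %s: line %d has %d fields, expected %d",
      path, bad, nf[bad], nf[1L]))
  }
  vals <- tryCatch(
    scan(path, what = numeric(), quiet = TRUE),
    error = function(e)
      stop("non-numeric token in ", path, ": ", conditionMessage(e),
           call. = FALSE))
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("non-finite value in ", path)
  matrix(vals, ncol = nf[1L], byrow = TRUE)
}

#' Import a directory of per-subject/per-condition ASCII files
#'
#' File names must carry a subject tag and a condition tag; the search
#' mask (a glob) matches exactly the files of one condition, with that
#' condition's tag appearing once in the mask. The remaining conditions'
#' file names are generated by substituting each other tag into the
#' matched names. Subjects are ordered by lexicographic sort of the
#' matched file names (logged at import).
#'
#' @param directory directory holding all files.
#' @param searchMask glob matching the files of one condition, e.g.
#'   \code{"S*_C1.asc"}.
#' @param conditionTags character vector of condition tags; exactly one
#'   must occur in the mask.
#' @param samplingRate,onset,montage passed to [erpDataset()].
#' @param applyReference apply the average reference on import
#'   (recommended for EEG; set FALSE for MEG-style data).
#' @param verbose log the imported matrix dimensions.
#' @return an [ErpDataset-class].
#' @export
importDataset <- function(directory, searchMask, conditionTags,
                          samplingRate = 1000, onset = 0,
                          montage = NULL, applyReference = TRUE,
                          verbose = TRUE) {
  if (length(conditionTags) < 1L)
    stop("at least one condition tag is required")
  inMask <- vapply(conditionTags, grepl, logical(1), x = searchMask,
                   fixed = TRUE)
  if (sum(inMask) != 1L)
    stop("exactly one condition tag must appear in the search mask; ",
         "found ", sum(inMask))
  tag0 <- conditionTags[inMask]
  files0 <- sort(basename(Sys.glob(file.path(directory, searchMask))))
  if (length(files0) == 0L)
    stop("search mask '", searchMask, "' matched no files in ",
         directory)
  # expected file table: rows subjects, cols conditions
  expected <- vapply(conditionTags, function(tg)
    vapply(files0, function(f) sub(tag0, tg, f, fixed = TRUE),
           character(1)), character(length(files0)))
  expected <- matrix(expected, nrow = length(files0),
                     dimnames = list(NULL, conditionTags))
  missing <- expected[!file.exists(file.path(directory, expected))]
  if (length(missing) > 0L)
    stop("expected files absent from ", directory, ": ",
         paste(missing, collapse = ", "))
  ns <- nrow(expected); nc <- length(conditionTags)
  shp <- NULL
  x <- NULL
  for (i in seq_len(ns))
    for (j in seq_len(nc)) {
      m <- readAsciiMapSeries(file.path(directory, expected[i, j]))
      if (is.null(shp)) {
        shp <- dim(m)
        x <- array(NA_real_, c(ns, nc, shp[1], shp[2]))
      } else if (!identical(dim(m), shp))
        stop(sprintf(
          "inconsistent matrix shape in %s: %d x %d, expected %d x %d",
          expected[i, j], nrow(m), ncol(m), shp[1], shp[2]))
      x[i, j, , ] <- m
    }
  subj <- sub("\\.[^.]*$", "", sub(tag0, "", files0, fixed = TRUE))
  subj <- gsub("_+$|^_+", "", subj)
  if (anyDuplicated(subj)) subj <- files0
  ds <- erpDataset(x, samplingRate = samplingRate, onset = onset,
                   subjectLabels = subj,
                   conditionLabels = conditionTags, montage = montage)
  if (applyReference && shp[2] >= 2L)
    ds <- applyAverageReference(ds)
  if (verbose)
    message(sprintf(
      "imported %d subjects x %d conditions x %d time points x %d sensors",
      ns, nc, shp[1], shp[2]))
  ds
}

#' Read a sensor montage file
#'
#' Whitespace table with a sensor name column followed by 2 or 3 numeric
#' position columns (projected 2-D coordinates or 3-D positions in cm).
#' Used for display and interpolation only, never for statistics.
#'
#' @param path file path.
#' @return data.frame with columns \code{name}, \code{x}, \code{y}
#'   (and \code{z} when present).
#' @export
readMontage <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || ncol(tab) > 4L)
    stop("montage file needs a name column plus 2 or 3 coordinates")
  names(tab) <- c("name", "x", "y", "z")[seq_len(ncol(tab))]
  if (!all(vapply(tab[-1L], is.numeric, logical(1))))
    stop("montage coordinates must be numeric")
  if (anyDuplicated(tab$name))
    stop("montage sensor names must be unique")
  tab$name <- as.character(tab$name)
  tab
}

#' Equally spaced circular montage
#'
#' Convenience montage: n sensors on the unit circle. Used as the
#' default montage of the synthetic generator.
#'
#' @param n number of sensors.
#' @return montage data.frame.
#' @export
circularMontage <- function(n) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(name = sprintf("E%02d", seq_len(n)),
             x = cos(th), y = sin(th))
}

#' Write a dataset as a directory of Ragu-dialect ASCII files
#'
#' One file per subject and condition, values written with enough digits
#' for a lossless (1e-12 relative) re-import round trip.
#'
#' @param dataset an [ErpDataset-class].
#' @param directory output directory (created if needed).
#' @param template \code{sprintf} template taking the subject index and
#'   the condition label, e.g. \code{"S\%02d_\%s.asc"}.
#' @return invisibly, the written file names.
#' @export
writeRaguDirectory <- function(dataset, directory,
                               template = "S%02d_%s.asc") {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  x <- erpData(dataset)
  d <- dim(x)
  files <- character(0)
  for (i in seq_len(d[1L]))
    for (j in seq_len(d[2L])) {
      f <- sprintf(template, i, conditionLabels(dataset)[j])
      m <- x[i, j, , , drop = TRUE]
      dim(m) <- d[3:4]
      lines <- apply(m, 1L, function(r)
        paste(formatC(r, format = "e", digits = 15), collapse = "\t"))
      writeLines(lines, file.path(directory, f))
      files <- c(files, f)
    }
  invisible(files)
}
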