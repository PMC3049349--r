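#' Export results as tab-delimited text
#'
#' Spreadsheet-friendly tab-delimited tables: one row per (effect,
#' time point) with the observed effect strength and p-value.
#'
#' @param result a [RandomizationResult-class].
#' @param path output file.
#' @return invisibly, the exported data.frame.
#' @export
writeResultsTable <- function(result, path) {
  ids <- effectIds(result)
  tms <- result@timeMs
  tab <- do.call(rbind, lapply(seq_along(ids), function(e)
    data.frame(effect = ids[e], sample = seq_along(tms), ms = tms,
               s = result@observed[e, ], p = result@p[e, ],
               stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tab)
}

#' @rdname writeResultsTable
#' @param global a [GlobalInference-class].
#' @export
writeGlobalTable <- function(global, path) {
  tab <- global@table
  cl <- do.call(rbind, lapply(names(global@clusters), function(id) {
    x <- global@clusters[[id]]
    if (nrow(x) == 0L) return(NULL)
    cbind(effect = id, x)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cl)) {
    writeLines("", con)
    write.table(cl, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(tab)
}

#' @rdname writeResultsTable
#' @param tct a [TctResult-class].
#' @export
writeTctTable <- function(tct, path) {
  tab <- do.call(rbind, lapply(seq_along(tct@strata), function(i)
    data.frame(stratum = tct@strata[i],
               sample = seq_along(tct@timeMs), ms = tct@timeMs,
               p = tct@p[i, ], gfp = tct@gfpMean[i, ],
               stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tab)
}

#' @rdname writeResultsTable
#' @param proj an [MdsProjection-class].
#' @export
writeMdsTable <- function(proj, path) {
  co <- proj@coordinates
  tab <- data.frame(map = proj@labels, axis1 = co[, 1L],
                    axis2 = co[, 2L], stringsAsFactors = FALSE)
  ev <- proj@eigenvectorMaps
  con <- file(path, "w")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("", con)
  write.table(data.frame(sensor = seq_len(nrow(ev)),
                         eigenvector1 = ev[, 1L],
                         eigenvector2 = ev[, 2L]),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
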