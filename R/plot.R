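#' @importFrom graphics abline axis barplot image layout legend lines
#'   mtext par plot points polygon rect text title
#' @importFrom grDevices colorRampPalette dev.off png
NULL

# inverse-distance-weighted interpolation of a map on a square grid
.interpolateMap <- function(map, montage, gridN = 50, power = 2) {
  px <- montage$x; py <- montage$y
  gx <- seq(min(px), max(px), length.out = gridN)
  gy <- seq(min(py), max(py), length.out = gridN)
  z <- matrix(NA_real_, gridN, gridN)
  for (i in seq_len(gridN))
    for (j in seq_len(gridN)) {
      d2 <- (px - gx[i])^2 + (py - gy[j])^2
      hit <- which(d2 < 1e-12)
      z[i, j] <- if (length(hit) > 0L) map[hit[1L]] else {
        w <- 1 / d2^(power / 2)
        sum(w * map) / sum(w)
      }
    }
  list(x = gx, y = gy, z = z)
}

.mapPalette <- function(n = 64)
  colorRampPalette(c("#1f3b99", "white", "#b01111"))(n)

# draw one mean map: interpolated image with montage, else sensor bars
.plotMap <- function(map, montage, main = "") {
  if (!is.null(montage)) {
    ip <- .interpolateMap(map, montage)
    lim <- max(abs(ip$z), 1e-12)
    image(ip$x, ip$y, ip$z, col = .mapPalette(),
          zlim = c(-lim, lim), axes = FALSE, xlab = "", ylab = "",
          main = main, asp = 1)
    points(montage$x, montage$y, pch = 16, cex = 0.4)
  } else {
    warning("no montage available; rendering maps as sensor bars")
    barplot(map, main = main, border = NA,
            col = ifelse(map >= 0, "#b01111", "#1f3b99"),
            names.arg = NULL)
  }
}

# p-trace panel with significance marking and optional duration mask
.plotPTrace <- function(tms, p, alpha, clusters = NULL,
                        main = "p(t)") {
  plot(tms, p, type = "n", ylim = c(0, 1), xlab = "time [ms]",
       ylab = "P(null)", main = main)
  if (!is.null(clusters) && nrow(clusters) > 0L)
    for (i in seq_len(nrow(clusters)))
      rect(clusters$startMs[i], 0, clusters$endMs[i], 1,
           col = "#ccf0cc", border = NA)
  lines(tms, p, lwd = 1.5)
  abline(h = alpha, col = "red", lty = 2)
  sig <- p < alpha
  if (any(sig)) points(tms[sig], p[sig], pch = 16, cex = 0.5,
                       col = "white")
  if (any(sig)) points(tms[sig], p[sig], pch = 1, cex = 0.5)
}

#' Display one effect: p-trace, mean maps and MDS scatter
#'
#' The standard result view: the p-value line graph over time with
#' significant samples marked (and duration-surviving periods
#' highlighted in green when a [GlobalInference-class] is supplied),
#' the effect's mean maps at a selected latency, and the MDS
#' projection of those maps. Window-averaged results are shown as a
#' significance bar instead of a line. Without a montage, maps are
#' rendered as sensor bar charts with a warning.
#'
#' @param dataset the analyzed [ErpDataset-class].
#' @param result a [RandomizationResult-class].
#' @param effect effect id or label.
#' @param within,between the designs used for the analysis.
#' @param tMs latency (ms) at which to display the mean maps; default:
#'   the latency of the minimal p.
#' @param global optional [GlobalInference-class] for the duration
#'   mask.
#' @return invisibly, the [MdsProjection-class] of the displayed maps.
#' @export
plotEffect <- function(dataset, result, effect, within = NULL,
                       between = NULL, tMs = NULL, global = NULL) {
  i <- .effectRow(result, effect)
  spec <- result@effects[[i]]
  p <- result@p[i, ]
  tms <- result@timeMs
  if (is.null(tMs)) tMs <- tms[which.min(p)]
  tIdx <- which.min(abs(timePoints(dataset) - tMs))
  M <- cellMeans(dataset, within, between, spec, tIdx)
  oldPar <- par(no.readonly = TRUE)
  on.exit(par(oldPar))
  nMaps <- nrow(M)
  layout(matrix(c(rep(1L, nMaps), seq_len(nMaps) + 1L,
                  rep(nMaps + 2L, nMaps)),
                nrow = 3, byrow = TRUE))
  par(mar = c(4, 4, 2, 1))
  if (result@averaged) {
    barplot(p, ylim = c(0, 1), names.arg = spec@id,
            main = sprintf("%s: p = %.4g (window %g-%g ms)",
                           spec@label, p[1L], result@windowMs[1L],
                           result@windowMs[2L]))
    abline(h = result@options@alpha, col = "red", lty = 2)
  } else {
    cl <- if (!is.null(global))
      significantClusters(global, spec@id) else NULL
    .plotPTrace(tms, p, result@options@alpha, cl,
                main = sprintf("%s (s at %g ms)", spec@label, tMs))
    abline(v = tMs, col = "grey40", lty = 3)
  }
  par(mar = c(1, 1, 2, 1))
  for (m in seq_len(nMaps))
    .plotMap(M[m, ], montage(dataset), main = rownames(M)[m])
  par(mar = c(4, 4, 2, 1))
  proj <- mdsProject(M)
  co <- proj@coordinates
  plot(co[, 1L], co[, 2L], pch = 16,
       xlab = sprintf("eigenvector 1 (%.0f%%)",
                      100 * proj@explained[1L]),
       ylab = sprintf("eigenvector 2 (%.0f%%)",
                      100 * proj@explained[2L]),
       main = "MDS of mean maps")
  text(co[, 1L], co[, 2L], labels = rownames(M), pos = 3, cex = 0.8)
  abline(h = 0, v = 0, col = "grey80")
  invisible(proj)
}

#' Display the topographic consistency test of one stratum
#'
#' Two stacked graphs per the standard display: the TCT p-value trace
#' with its threshold, and the GFP of the mean map with periods of
#' consistent topography marked in green.
#'
#' @param tct a [TctResult-class].
#' @param stratum stratum label (default: first).
#' @export
plotTct <- function(tct, stratum = NULL) {
  if (is.null(stratum)) stratum <- tct@strata[1L]
  oldPar <- par(no.readonly = TRUE)
  on.exit(par(oldPar))
  par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  .plotPTrace(tct@timeMs, tct@p[stratum, ], tct@options@alpha,
              main = paste("TCT:", stratum))
  cl <- tct@intervals[[stratum]]
  g <- tct@gfpMean[stratum, ]
  plot(tct@timeMs, g, type = "n", xlab = "time [ms]",
       ylab = "GFP [µV]", main = "GFP of mean map")
  if (nrow(cl) > 0L)
    for (i in seq_len(nrow(cl)))
      rect(cl$startMs[i], 0, cl$endMs[i], max(g) * 1.05,
           col = "#ccf0cc", border = NA)
  lines(tct@timeMs, g, lwd = 1.5)
  invisible(NULL)
}
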