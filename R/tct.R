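#' Topographic consistency test
#'
#' Tests, per condition (and group, if a categorical between design is
#' given) and time point, whether the subjects share a consistent scalp
#' field topography. The statistic is the GFP of the across-subject
#' mean map: consistent topographies add up, inconsistent ones cancel.
#' The null is built by independently shuffling, within each subject's
#' map, the values across sensors (one sensor permutation per subject
#' per run, reused across time points), then recomputing the statistic;
#' p-values follow the [pointwiseP()] rule. The GFP trace of the raw
#' mean map is reported alongside, and periods of consistent topography
#' are marked with the duration-threshold machinery of
#' [globalInference()].
#'
#' The statistic is invariant to re-referencing and to applying one
#' common sensor permutation to all subjects.
#'
#' @param dataset an [ErpDataset-class]; >= 2 subjects per tested
#'   stratum.
#' @param options a [RandomizationOptions-class]; the normalization
#'   option applies to the individual maps as in [runTanova()].
#' @param between optional categorical [BetweenDesign-class] to test
#'   each group separately.
#' @return a [TctResult-class].
#' @export
topographicConsistencyTest <- function(dataset,
                                       options =
                                         randomizationOptions(),
                                       between = NULL) {
  validObject(options)
  d <- dim(erpData(dataset))
  ns <- d[1L]; nc <- d[2L]; nch <- d[4L]
  tms <- timePoints(dataset)
  tsel <- seq_len(d[3L])
  if (length(options@window) == 2L) {
    tsel <- which(tms >= options@window[1L] & tms < options@window[2L])
    if (length(tsel) == 0L) stop("analysis window contains no samples")
  }
  nt <- length(tsel)
  if (!is.null(between) && between@mode != "categorical")
    stop("TCT strata need a categorical between design")
  groups <- if (is.null(between)) rep(1L, ns) else {
    g <- rep(NA_integer_, ns)
    g[between@use] <- match(between@values[between@use],
                            sort(unique(between@values[between@use])))
    g
  }
  nG <- max(groups, na.rm = TRUE)
  gLabs <- if (is.null(between)) "" else {
    u <- sort(unique(groups[!is.na(groups)]))
    if (length(between@groupLabels) >= max(u))
      between@groupLabels[u] else sprintf("g%d", u)
  }
  strata <- character(0)
  R <- options@nRuns
  pAll <- NULL; gfpAll <- NULL
  thresholds <- numeric(0); intervals <- list()
  for (g in seq_len(nG)) {
    subj <- which(groups == g)
    if (length(subj) < 2L)
      stop("TCT needs >= 2 subjects per stratum")
    for (k in seq_len(nc)) {
      lab <- if (nG > 1L)
        paste(gLabs[g], conditionLabels(dataset)[k], sep = ".") else
          conditionLabels(dataset)[k]
      X <- erpData(dataset)[subj, k, tsel, , drop = FALSE]
      dim(X) <- c(length(subj), nt, nch)
      gfpTrace <- .tctStat(X)          # raw-scale GFP of mean map
      if (options@normalization == "l2") {
        Xm <- matrix(X, length(subj) * nt, nch)
        Xm <- Xm - rowMeans(Xm)
        gg <- sqrt(rowMeans(Xm^2))
        if (any(gg == 0)) {
          i <- arrayInd(which(gg == 0)[1L], c(length(subj), nt))
          stop(sprintf(
            "flat map (GFP = 0) cannot be L2-normalized: subject %s, condition %s, sample %d",
            subjectLabels(dataset)[subj[i[1L]]], lab, i[2L]))
        }
        X <- array(Xm / gg, dim(X))
      }
      obs <- .tctStat(X)
      nullM <- matrix(NA_real_, R, nt)
      .withSeed(.effectSeed(options@seed, paste0("TCT.", lab)), {
        for (r in seq_len(R)) {
          S <- matrix(0, nt, nch)
          for (s in seq_len(dim(X)[1L])) {
            Xs <- X[s, , , drop = FALSE]
            dim(Xs) <- c(nt, nch)
            S <- S + Xs[, sample.int(nch), drop = FALSE]
          }
          M <- S / dim(X)[1L]
          rm <- rowMeans(M)
          nullM[r, ] <- sqrt(rowMeans((M - rm)^2))
        }
      })
      p <- (1 + colSums(nullM >= rep(obs, each = R))) / (1 + R)
      pseudo <- pseudoPMatrix(nullM)
      thr <- durationThreshold(pseudo, options@alpha)
      cl <- applyDurationMask(p, thr, options@alpha)
      cl$startMs <- tms[tsel][cl$start]
      cl$endMs <- tms[tsel][cl$end]
      strata <- c(strata, lab)
      pAll <- rbind(pAll, p)
      gfpAll <- rbind(gfpAll, gfpTrace)
      thresholds <- c(thresholds, thr)
      intervals <- c(intervals, list(cl))
    }
  }
  rownames(pAll) <- rownames(gfpAll) <- strata
  names(intervals) <- names(thresholds) <- strata
  new("TctResult", strata = strata, p = pAll, gfpMean = gfpAll,
      thresholds = thresholds, intervals = intervals,
      timeMs = tms[tsel], options = options)
}

# GFP of the across-subject mean map, per time point
.tctStat <- function(X) {
  M <- colMeans(X)             # nt x nch
  if (is.null(dim(M))) M <- matrix(M, 1L)
  rm <- rowMeans(M)
  sqrt(rowMeans((M - rm)^2))
}

setMethod("show", "TctResult", function(object) {
  cat("Topographic consistency test:", length(object@strata),
      "strata x", length(object@timeMs), "time points;",
      object@options@nRuns, "runs\n")
  for (i in seq_along(object@strata))
    cat(sprintf(
      "  %-12s %d of %d samples consistent (duration threshold %d)\n",
      object@strata[i], sum(object@intervals[[i]]$length),
      length(object@timeMs), as.integer(object@thresholds[i])))
})

#' @rdname TctResult-class
#' @param x a TctResult.
#' @param stratum stratum label (default: all, as a matrix).
#' @export
tctPValues <- function(x, stratum = NULL) {
  if (is.null(stratum)) return(x@p)
  x@p[stratum, ]
}

#' @rdname TctResult-class
#' @export
tctGfp <- function(x, stratum = NULL) {
  if (is.null(stratum)) return(x@gfpMean)
  x@gfpMean[stratum, ]
}

#' @rdname TctResult-class
#' @export
consistentIntervals <- function(x, stratum) x@intervals[[stratum]]
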