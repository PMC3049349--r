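#' Pseudo-P matrix of the randomization null
#'
#' For each randomization run r and time point t, the pseudo-P value
#' ranks the run's statistic against all other runs:
#' \code{p'(r, t) = (1 + #\{r' != r : s(r', t) >= s(r, t)\}) / nRuns}.
#' Each run thereby becomes an instance of a full time-point-wise
#' analysis under the null hypothesis, which is the basis of the
#' count and duration statistics. The ">=" tie rule matches
#' [pointwiseP()].
#'
#' @param nullS numeric matrix, runs x time, of null statistics.
#' @return matrix of the same shape with values in (0, 1].
#' @examples
#' pseudoPMatrix(matrix(c(3, 1, 2), 3, 1))  # 1/3, 1, 2/3
#' @export
pseudoPMatrix <- function(nullS) {
  if (!is.matrix(nullS) || nrow(nullS) < 2L)
    stop("need a runs x time matrix with >= 2 runs")
  R <- nrow(nullS)
  out <- apply(nullS, 2L, function(col)
    (R + 1 - rank(col, ties.method = "min")) / R)
  matrix(out, R, ncol(nullS))
}

#' Global count-of-significant-time-points test
#'
#' The observed count of time points with p below alpha is compared
#' against the null distribution of that count derived from the
#' pseudo-P matrix (each run's count of sub-alpha pseudo-P values),
#' yielding one global p per effect that is immune to multiple testing
#' across time.
#'
#' @param pObs observed p-value trace.
#' @param pseudo pseudo-P matrix from [pseudoPMatrix()] (shared time
#'   axis).
#' @param alpha the significance threshold defining "significant".
#' @return global p-value in (0, 1].
#' @export
countSignificanceTest <- function(pObs, pseudo, alpha = 0.05) {
  if (length(pObs) != ncol(pseudo))
    stop("pObs and pseudo must share the time axis")
  k <- sum(pObs < alpha)
  kr <- rowSums(pseudo < alpha)
  (1 + sum(kr >= k)) / (1 + nrow(pseudo))
}

# max run length of TRUE in a logical vector
.maxRunLength <- function(sig) {
  r <- rle(sig)
  w <- r$lengths[r$values]
  if (length(w) == 0L) 0L else max(w)
}

# smallest null-observed duration d with #{maxrun >= d} <= alpha * R
.durationQuantile <- function(maxRuns, alpha) {
  R <- length(maxRuns)
  cand <- sort(unique(c(1L, maxRuns[maxRuns >= 1L])))
  for (d in cand)
    if (sum(maxRuns >= d) <= alpha * R) return(as.integer(d))
  as.integer(max(maxRuns) + 1L)
}

#' Duration threshold for globally significant effects
#'
#' For each randomization run the maximal length of a contiguous
#' stretch of sub-alpha pseudo-P values is computed; the threshold is
#' the shortest duration exceeded by at most an alpha fraction of the
#' runs (the (1 - alpha) quantile of the null duration distribution,
#' reported as an achievable run length). Observed stretches of
#' sub-alpha p-values at least this long are globally significant;
#' using the per-run maximum gives familywise control analogous to
#' cluster-size statistics.
#'
#' @param pseudo pseudo-P matrix from [pseudoPMatrix()].
#' @param alpha the significance threshold.
#' @return threshold in samples (integer >= 1).
#' @export
durationThreshold <- function(pseudo, alpha = 0.05) {
  if (!is.matrix(pseudo) || nrow(pseudo) < 2L)
    stop("need a runs x time pseudo-P matrix with >= 2 runs")
  sig <- pseudo < alpha
  maxRuns <- apply(sig, 1L, .maxRunLength)
  .durationQuantile(maxRuns, alpha)
}

#' Mask a p-value trace with the duration criterion
#'
#' Returns the maximal intervals where \code{pObs < alpha} whose length
#' reaches the duration threshold. Boundary samples at exactly alpha
#' are non-significant.
#'
#' @param pObs observed p-value trace.
#' @param threshold duration threshold in samples (from
#'   [durationThreshold()]).
#' @param alpha the significance threshold.
#' @return data.frame with columns \code{start}, \code{end} (sample
#'   indices, inclusive) and \code{length}.
#' @export
applyDurationMask <- function(pObs, threshold, alpha = 0.05) {
  sig <- pObs < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= threshold
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Global inference for every effect of a randomization result
#'
#' Derives, from the same randomization runs as the time-point-wise
#' test (no fresh randomization), the count-test global p, the duration
#' threshold (samples and ms) and the clusters surviving it, per
#' effect.
#'
#' @param result a [RandomizationResult-class].
#' @param alpha threshold; defaults to the alpha of the run's options.
#' @return a [GlobalInference-class].
#' @export
globalInference <- function(result, alpha = NULL) {
  if (is.null(alpha)) alpha <- result@options@alpha
  tms <- result@timeMs
  dt <- if (length(tms) > 1L) tms[2L] - tms[1L] else NA_real_
  ids <- effectIds(result)
  rows <- vector("list", length(ids))
  clusters <- vector("list", length(ids))
  for (e in seq_along(ids)) {
    pseudo <- pseudoPMatrix(result@null[[e]])
    pObs <- result@p[e, ]
    cp <- countSignificanceTest(pObs, pseudo, alpha)
    thr <- durationThreshold(pseudo, alpha)
    cl <- applyDurationMask(pObs, thr, alpha)
    cl$startMs <- tms[cl$start]
    cl$endMs <- tms[cl$end]
    clusters[[e]] <- cl
    rows[[e]] <- data.frame(
      effect = ids[e], countP = cp, thresholdSamples = thr,
      thresholdMs = thr * dt, nClusters = nrow(cl),
      stringsAsFactors = FALSE)
  }
  names(clusters) <- ids
  new("GlobalInference", table = do.call(rbind, rows),
      clusters = clusters, alpha = alpha)
}
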