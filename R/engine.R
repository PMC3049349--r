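#' Construct randomization options
#'
#' @param nRuns number of randomization runs. 1000 runs are recommended
#'   for an accurate estimate at the 5\% level, 5000 at the 1\% level.
#' @param alpha significance threshold.
#' @param normalization \code{"none"}, \code{"l2"} (recommended:
#'   each individual map scaled to unit GFP before averaging) or
#'   \code{"dissimilarity"} (legacy: condition/group grand-mean maps
#'   normalized instead).
#' @param seed integer seed for all shuffles; NA uses the current RNG
#'   state. Per-effect substreams are derived deterministically, so each
#'   effect is reproducible independently.
#' @param window optional analysis window \code{c(start, end)} in ms,
#'   half-open \code{[start, end)}.
#' @return a [RandomizationOptions-class].
#' @export
randomizationOptions <- function(nRuns = 1000, alpha = 0.05,
                                 normalization = c("l2", "none",
                                                   "dissimilarity"),
                                 seed = NA, window = NULL) {
  new("RandomizationOptions", nRuns = as.integer(nRuns),
      alpha = alpha, normalization = match.arg(normalization),
      seed = as.integer(seed),
      window = if (is.null(window)) numeric(0) else as.numeric(window))
}

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic per-effect substream seed (kept < 2^31)
.effectSeed <- function(seed, id) {
  if (is.na(seed)) return(NA_integer_)
  h <- sum(utf8ToInt(id) * seq_len(nchar(id)))
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483647)
}

#' Time-point-wise randomization p-value
#'
#' The probability of the null hypothesis is the fraction of
#' randomization values of s that are larger than or equal to the
#' observed s, with the observed value counted as one realization of
#' the null: \code{p = (1 + #\{null >= observed\}) / (1 + nRuns)}. A
#' randomization p is therefore never exactly 0.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null statistics.
#' @return p-value in (0, 1].
#' @examples
#' pointwiseP(10, rep(1, 999))  # 1/1000
#' @export
pointwiseP <- function(observed, null) {
  if (length(null) == 0L) stop("null distribution is empty")
  (1 + sum(null >= observed)) / (1 + length(null))
}

# normalize every individual map of the 4-D array to unit GFP,
# with an informative error naming the offending map
.normalizeArrayL2 <- function(x, subjLab, condLab) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4L])
  m <- m - rowMeans(m)      # spatial mean per map (average reference)
  g <- sqrt(rowMeans(m^2))
  if (any(g == 0)) {
    i <- arrayInd(which(g == 0)[1L], d[1:3])
    stop(sprintf(
      "flat map (GFP = 0) cannot be L2-normalized: subject %s, condition %s, sample %d",
      subjLab[i[1L]], condLab[i[2L]], i[3L]))
  }
  array(m / g, d)
}

# normalize grand-mean maps (rows of M, per time point) to unit GFP
.normalizeCellMapsL2 <- function(M, nt, nch) {
  a <- array(M, c(nrow(M), nt, nch))
  a <- a - c(rowMeans(a, dims = 2L))
  g <- sqrt(rowSums(a * a, dims = 2L) / nch)
  if (any(g == 0))
    stop("flat grand-mean map (GFP = 0) under dissimilarity normalization")
  a <- a / c(g)
  dim(a) <- dim(M)
  a
}

# core engine shared by runTanova / runTancova / averagedWindowTanova
.runEngine <- function(dataset, within, between, options,
                       effects = NULL, averaged = FALSE,
                       windowMs = numeric(0)) {
  validObject(options)
  d <- dim(erpData(dataset))
  use <- if (is.null(between)) rep(TRUE, d[1L]) else between@use
  inc <- .includedConditions(within, d[2L])
  tms <- timePoints(dataset)
  tsel <- seq_len(d[3L])
  if (length(options@window) == 2L && !averaged) {
    tsel <- which(tms >= options@window[1L] & tms < options@window[2L])
    if (length(tsel) == 0L) stop("analysis window contains no samples")
  }
  x <- erpData(dataset)[use, inc, tsel, , drop = FALSE]
  ns <- dim(x)[1L]; nci <- dim(x)[2L]
  nt <- dim(x)[3L]; nch <- dim(x)[4L]
  if (options@normalization == "l2")
    x <- .normalizeArrayL2(x, subjectLabels(dataset)[use],
                           conditionLabels(dataset)[inc])
  D <- matrix(x, ns * nci, nt * nch)

  specs <- enumerateEffects(within, between)
  if (length(specs) == 0L) stop("the design defines no effects")
  if (!is.null(effects)) {
    keep <- vapply(specs, function(e)
      e@id %in% effects || e@label %in% effects, logical(1))
    if (!any(keep)) stop("no matching effects: ",
                         paste(effects, collapse = ", "))
    specs <- specs[keep]
  }
  rec <- if (options@alpha <= 0.01) 5000L else 1000L
  if (options@nRuns < rec)
    warning(sprintf(
      "%d randomization runs; %d are recommended for an accurate estimate at the %g%% level",
      options@nRuns, rec, 100 * options@alpha), call. = FALSE)

  R <- options@nRuns
  obs <- matrix(NA_real_, length(specs), nt)
  nulls <- vector("list", length(specs))
  pmat <- matrix(NA_real_, length(specs), nt)

  for (e in seq_along(specs)) {
    spec <- specs[[e]]
    wc <- .withinCells(within, spec@withinFactors, inc)
    bs <- .betweenState(between, spec)
    if (spec@betweenScheme == "covariate") {
      if (length(unique(bs$cov)) < 3L)
        stop("TANCOVA needs >= 3 distinct covariate values")
      if (options@normalization == "dissimilarity")
        stop("dissimilarity normalization is not defined for covariate effects")
    }
    if (!is.null(bs$groups) && any(tabulate(bs$groups) < 2L))
      stop("each group needs >= 2 used subjects for a between-subject effect")
    ctx <- .effectContext(spec, wc, bs, ns)
    cmp <- .withSeed(.effectSeed(options@seed, spec@id),
                     .computeEffect(spec, ctx, D, ns, nci, nt, nch,
                                    options@normalization, R))
    obs[e, ] <- cmp$obs
    nm <- cmp$null
    nulls[[e]] <- nm
    pmat[e, ] <- (1 + colSums(nm >= rep(obs[e, ], each = R))) /
      (1 + R)
  }
  ids <- vapply(specs, function(s) s@id, character(1))
  rownames(obs) <- rownames(pmat) <- names(nulls) <- ids
  new("RandomizationResult", effects = specs, observed = obs,
      null = nulls, p = pmat,
      timeMs = if (averaged) mean(windowMs) else tms[tsel],
      options = options, averaged = averaged, windowMs = windowMs)
}

# all permutations of 1..n, identity first
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[(k - 1L) * m + seq_len(m), ] <-
      cbind(rep(k, m), matrix(rest[sub], m))
  }
  out
}

# s(t) for blocks of (run, cell) mean/covariance maps stacked in M:
# rows ordered cell-fastest, columns (t, ch) t-fastest
.blockStrength <- function(M, P, ncells, nBlocks, nt, nch) {
  dim(M) <- c(ncells, nBlocks * nt * nch)
  PM <- if (ncells > 1L) P %*% M else M
  ssq <- .colSums(PM * PM, ncells, nBlocks * nt * nch)
  dim(ssq) <- c(nBlocks, nt, nch)
  sqrt(rowSums(ssq, dims = 2L) / nch)          # nBlocks x nt
}

# observed + null strengths for one effect, all runs batched.
# Row 1 of every block structure is the identity (observed) labeling.
.computeEffect <- function(spec, ctx, D, ns, nci, nt, nch,
                           normalization, R) {
  nW <- ctx$nW; nG <- ctx$nG; ncells <- nG * nW
  P <- ctx$P
  ntc <- nt * nch
  nB <- R + 1L

  if (spec@betweenScheme == "covariate") {
    # per-subject within-cell mean maps, computed once
    iv <- rep(seq_len(ns), nci) +
      (rep(ctx$baseCells[1L, ], each = ns) - 1L) * ns
    cnt <- tabulate(iv, ns * nW)
    if (any(cnt == 0L)) stop("empty cell: no data for some cell")
    V <- rowsum(D, iv) / cnt
    bMat <- matrix(NA_real_, ns, nB)
    bMat[, 1L] <- ctx$cov0
    for (r in seq_len(R)) bMat[, r + 1L] <- ctx$cov0[sample.int(ns)]
    chunk <- max(1L, min(nB, as.integer(5e7 / (nW * ntc))))
    sMat <- matrix(NA_real_, nB, nt)
    for (b0 in seq(1L, nB, by = chunk)) {
      bIdx <- b0:min(nB, b0 + chunk - 1L)
      nBc <- length(bIdx)
      big <- matrix(NA_real_, nW * nBc, ntc)
      for (w in seq_len(nW)) {
        Bw <- crossprod(bMat[, bIdx, drop = FALSE],
                        V[((w - 1L) * ns + 1L):(w * ns), ,
                          drop = FALSE])        # nBc x ntc
        big[seq(w, by = nW, length.out = nBc), ] <- Bw
      }
      # remove the spatial mean of each covariance map, so the
      # strength is exactly the GFP of beta
      a <- array(big, c(nW * nBc, nt, nch))
      a <- a - c(rowMeans(a, dims = 2L))
      sMat[bIdx, ] <- .blockStrength(a, P, nW, nBc, nt, nch)
    }
  } else {
    wcell <- ctx$baseCells[1L, ]
    g0 <- if (is.null(ctx$groups0)) rep(1L, ns) else ctx$groups0
    cnt0 <- tabulate((g0 - 1L) * nW + rep(wcell, each = ns), ncells)
    # counts are invariant under the shuffles (bijective relabelings)
    if (any(cnt0 == 0L))
      stop("empty cell: all subjects of some cell are excluded")
    # relabeling table: each row one possible per-subject relabeling
    permCells <- switch(spec@withinScheme,
      none = matrix(wcell, 1L, nci),
      factor = {
        Pm <- .allPerms(ctx$wdims[1L])
        matrix(Pm[, wcell], nrow(Pm), nci)
      },
      conditions = {
        if (nci <= 7L) {
          Pm <- .allPerms(nci)
          matrix(wcell[Pm], nrow(Pm), nci)
        } else NULL
      })
    if (!is.null(permCells)) {
      nPerm <- nrow(permCells)
      pick <- rbind(rep(1L, ns),
                    if (nPerm > 1L)
                      matrix(sample.int(nPerm, R * ns, TRUE), R, ns)
                    else matrix(1L, R, ns))
      cellsBig <- permCells[as.vector(pick), , drop = FALSE]
    } else {
      # too many condition permutations to tabulate: sample directly
      cellsBig <- matrix(0L, nB * ns, nci)
      for (s in seq_len(ns)) {
        cellsBig[(s - 1L) * nB + 1L, ] <- wcell
        for (r in seq_len(R))
          cellsBig[(s - 1L) * nB + 1L + r, ] <-
            wcell[sample.int(nci)]
      }
    }
    if (nG > 1L) {
      gAll <- matrix(0L, nB, ns)
      gAll[1L, ] <- g0
      for (r in seq_len(R)) gAll[r + 1L, ] <- g0[sample.int(ns)]
    }
    rIdx <- rep(seq_len(nB), times = ns * nci)
    sIdx <- rep(rep(seq_len(ns), each = nB), times = nci)
    cIdx <- rep(seq_len(nci), each = nB * ns)
    rsLin <- (sIdx - 1L) * nB + rIdx
    cellVal <- cellsBig[(cIdx - 1L) * (nB * ns) + rsLin]
    ci <- if (nG > 1L) (gAll[rsLin] - 1L) * nW + cellVal else cellVal
    Dcol <- sIdx + (cIdx - 1L) * ns
    chunk <- max(1L, min(nB, as.integer(5e7 / (ncells * ntc))))
    sMat <- matrix(NA_real_, nB, nt)
    for (b0 in seq(1L, nB, by = chunk)) {
      b1 <- min(nB, b0 + chunk - 1L)
      sel <- rIdx >= b0 & rIdx <= b1
      nBc <- b1 - b0 + 1L
      Arow <- (rIdx[sel] - b0) * ncells + ci[sel]
      A <- matrix(0, nBc * ncells, ns * nci)
      A[(Dcol[sel] - 1L) * (nBc * ncells) + Arow] <- 1 / cnt0[ci[sel]]
      M <- A %*% D                             # (nBc*ncells) x ntc
      if (normalization == "dissimilarity")
        M <- .normalizeCellMapsL2(M, nt, nch)
      sMat[b0:b1, ] <- .blockStrength(M, P, ncells, nBc, nt, nch)
    }
  }
  list(obs = sMat[1L, ], null = sMat[-1L, , drop = FALSE])
}

#' Run a TANOVA
#'
#' Topographic analysis of variance: for every effect of the design and
#' every time point in the analysis window, the observed global effect
#' strength s is computed from the (optionally normalized) cell mean
#' maps, and compared against a randomization null obtained by
#' shuffling condition/group labels. One shuffle is drawn per run and
#' reused across all time points, so the null preserves the temporal
#' autocorrelation required by the count/duration statistics of
#' [globalInference()].
#'
#' @param dataset an [ErpDataset-class] (average-referenced).
#' @param within a [WithinDesign-class] or NULL.
#' @param between a categorical [BetweenDesign-class] or NULL; use
#'   [runTancova()] for a continuous covariate.
#' @param options a [RandomizationOptions-class].
#' @param effects optional character vector restricting the tested
#'   effects (ids or labels).
#' @return a [RandomizationResult-class].
#' @examples
#' sim <- simulateErp(erpSimSpec(nSubjects = 6, nTime = 10,
#'                               nSensors = 8, seed = 1))
#' wd <- withinDesign(list(A = c(1, 1, 2, 2), B = c(1, 2, 1, 2)))
#' res <- suppressWarnings(runTanova(sim$dataset, wd,
#'   options = randomizationOptions(nRuns = 99, seed = 7)))
#' pValues(res, "A")[1:3]
#' @export
runTanova <- function(dataset, within = NULL, between = NULL,
                      options = randomizationOptions(),
                      effects = NULL) {
  if (!is.null(between) && between@mode == "continuous")
    stop("between design is continuous; use runTancova()")
  .runEngine(dataset, within, between, options, effects)
}

#' Run a TANCOVA
#'
#' Topographic analysis of covariance: the statistic is the GFP of the
#' covariance map between the subjects' maps and a continuous
#' per-subject predictor (for interaction terms, of the per-within-cell
#' covariance maps after centering across cells). The null permutes the
#' covariate values across subjects. Within-subject effects of the
#' design are tested alongside with their TANOVA schemes.
#'
#' @inheritParams runTanova
#' @param between a continuous [BetweenDesign-class] (the covariate);
#'   >= 3 distinct values among used subjects are required.
#' @return a [RandomizationResult-class].
#' @export
runTancova <- function(dataset, within = NULL, between,
                       options = randomizationOptions(),
                       effects = NULL) {
  if (is.null(between) || between@mode != "continuous")
    stop("runTancova needs a continuous between design (the covariate)")
  v <- between@values[between@use]
  if (length(unique(v)) < 3L)
    stop("TANCOVA needs >= 3 distinct covariate values (constant or binary covariates are not admissible)")
  .runEngine(dataset, within, between, options, effects)
}

#' TANOVA/TANCOVA on maps averaged across a time window
#'
#' For an a-priori latency hypothesis: each subject's and condition's
#' maps are averaged across the window (half-open \code{[start, end)}
#' in ms) and the identical statistic pipeline is applied to the
#' averaged maps, yielding a single p per effect. A window covering
#' exactly one sample reproduces the time-point-wise result at that
#' sample under the same seed.
#'
#' @inheritParams runTanova
#' @param window \code{c(start, end)} in ms.
#' @return a [RandomizationResult-class] with a single "time point".
#' @export
averagedWindowTanova <- function(dataset, within = NULL,
                                 between = NULL,
                                 options = randomizationOptions(),
                                 window, effects = NULL) {
  if (missing(window) || length(window) != 2L || diff(window) <= 0)
    stop("window must be c(start, end) in ms with end > start")
  tms <- timePoints(dataset)
  tsel <- which(tms >= window[1L] & tms < window[2L])
  if (length(tsel) == 0L)
    stop("empty window: no samples in [", window[1L], ", ",
         window[2L], ") ms")
  x <- erpData(dataset)
  xa <- x[, , tsel, , drop = FALSE]
  avg <- array(apply(xa, c(1, 2, 4), mean),
               c(dim(x)[1:2], 1L, dim(x)[4L]))
  ds <- dataset
  ds@data <- avg
  ds@onset <- mean(window)
  .runEngine(ds, within, between, options, effects,
             averaged = TRUE, windowMs = window)
}
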