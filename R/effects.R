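#' Enumerate the testable effects of a design
#'
#' Returns the deterministic, ordered list of main effects and
#' interactions defined by the within and between designs: with two
#' within factors A and B and a categorical between factor G the seven
#' effects A, B, AxB, G, GxA, GxB, GxAxB; with a continuous covariate
#' the G-family is replaced by TANCOVA terms (Cov, CovxA, CovxB,
#' CovxAxB). A pure function of the design objects; empty designs give
#' an empty list.
#'
#' @param within a [WithinDesign-class] or NULL.
#' @param between a [BetweenDesign-class] or NULL.
#' @return list of [EffectSpec-class].
#' @examples
#' wd <- withinDesign(list(expectancy = c(1, 1, 2, 2),
#'                         day = c(1, 2, 1, 2)))
#' length(enumerateEffects(wd))  # 3
#' @export
enumerateEffects <- function(within = NULL, between = NULL) {
  out <- list()
  nf <- if (is.null(within)) 0L else length(within@factorNames)
  fn <- if (nf > 0L) within@factorNames else character(0)
  mk <- function(id, label, wf, ws, bs)
    new("EffectSpec", id = id, label = label,
        withinFactors = as.integer(wf), withinScheme = ws,
        betweenScheme = bs)
  if (nf >= 1L)
    out <- c(out, list(mk("A", fn[1L], 1L, "factor", "none")))
  if (nf == 2L)
    out <- c(out, list(
      mk("B", fn[2L], 2L, "factor", "none"),
      mk("AxB", paste(fn[1L], "x", fn[2L]), c(1L, 2L), "conditions",
         "none")))
  if (!is.null(between)) {
    bn <- between@name
    if (between@mode == "categorical") {
      out <- c(out, list(mk("G", bn, integer(0), "none", "group")))
      if (nf >= 1L)
        out <- c(out, list(mk("GxA", paste(bn, "x", fn[1L]), 1L,
                              "factor", "group")))
      if (nf == 2L)
        out <- c(out, list(
          mk("GxB", paste(bn, "x", fn[2L]), 2L, "factor", "group"),
          mk("GxAxB", paste(bn, "x", fn[1L], "x", fn[2L]), c(1L, 2L),
             "conditions", "group")))
    } else {
      out <- c(out, list(mk("Cov", bn, integer(0), "none",
                            "covariate")))
      if (nf >= 1L)
        out <- c(out, list(mk("CovxA", paste(bn, "x", fn[1L]), 1L,
                              "none", "covariate")))
      if (nf == 2L)
        out <- c(out, list(
          mk("CovxB", paste(bn, "x", fn[2L]), 2L, "none",
             "covariate"),
          mk("CovxAxB", paste(bn, "x", fn[1L], "x", fn[2L]),
             c(1L, 2L), "none", "covariate")))
    }
  }
  out
}

setMethod("show", "EffectSpec", function(object) {
  cat("EffectSpec", object@id, "(", object@label, "), scheme:",
      object@withinScheme, "/", object@betweenScheme, "\n")
})

# used-subject group vector (dense 1..nG) and covariate for an effect
.betweenState <- function(between, effect) {
  if (is.null(between) || effect@betweenScheme == "none")
    return(list(groups = NULL, cov = NULL))
  v <- between@values[between@use]
  if (effect@betweenScheme == "group") {
    g <- match(v, sort(unique(v)))
    list(groups = as.integer(g), cov = NULL)
  } else {
    list(groups = NULL, cov = v - mean(v))
  }
}

#' Marginal cell mean maps of one effect
#'
#' For main effects, the mean maps of each level, averaged over the
#' other factor's levels and over the subjects of the relevant stratum.
#' For interactions, the fully centered cell means (all lower-order
#' marginal means removed), so that purely additive data yield cell
#' means of zero: the defining property of an interaction statistic.
#' For covariate (TANCOVA) effects, the covariance maps per within
#' cell, centered across cells for interaction terms. Maps are
#' average-referenced if the data are.
#'
#' @param dataset an [ErpDataset-class].
#' @param within,between design objects (either may be NULL).
#' @param effect an [EffectSpec-class] from [enumerateEffects()], or an
#'   effect id string.
#' @param t time sample index (1-based).
#' @return matrix cells x sensors with labelled rows.
#' @export
cellMeans <- function(dataset, within = NULL, between = NULL, effect,
                      t) {
  if (is.character(effect)) {
    specs <- enumerateEffects(within, between)
    hit <- which(vapply(specs, function(e) e@id == effect,
                        logical(1)))
    if (length(hit) != 1L)
      stop("unknown effect id: ", effect)
    effect <- specs[[hit]]
  }
  d <- dim(erpData(dataset))
  if (t < 1L || t > d[3L]) stop("time index out of range")
  use <- if (is.null(between)) rep(TRUE, d[1L]) else between@use
  inc <- .includedConditions(within, d[2L])
  x <- erpData(dataset)[use, inc, t, , drop = FALSE]
  ns <- dim(x)[1L]; nci <- dim(x)[2L]; nch <- dim(x)[4L]
  X <- matrix(x, ns * nci, nch)   # rows: subject fastest, then cond
  wc <- .withinCells(within, effect@withinFactors, inc)
  bs <- .betweenState(between, effect)

  if (effect@betweenScheme == "covariate") {
    nW <- prod(wc$dims)
    iv <- rep(seq_len(ns), nci) + (rep(wc$cell, each = ns) - 1L) * ns
    cnt <- tabulate(iv, ns * nW)
    if (any(cnt == 0L)) stop("empty cell: no data for some cell")
    V <- rowsum(X, iv) / cnt
    B <- matrix(0, nW, nch)
    for (w in seq_len(nW))
      B[w, ] <- crossprod(V[((w - 1L) * ns + 1L):(w * ns), ,
                            drop = FALSE], bs$cov)
    M <- B
    labels <- wc$labels
    nG <- 1L
  } else {
    nG <- if (is.null(bs$groups)) 1L else max(bs$groups)
    g <- if (is.null(bs$groups)) rep(1L, ns) else bs$groups
    nW <- prod(wc$dims)
    ci <- (g - 1L) * nW + rep(wc$cell, each = ns)
    cnt <- tabulate(ci, nG * nW)
    if (any(cnt == 0L))
      stop("empty cell: all subjects of some cell are excluded")
    M <- rowsum(X, ci) / cnt
    labels <- wc$labels
    if (nG > 1L) {
      gl <- if (length(between@groupLabels) >= nG)
        between@groupLabels[seq_len(nG)] else sprintf("g%d",
                                                      seq_len(nG))
      labels <- as.vector(t(outer(gl, wc$labels, paste, sep = ".")))
      if (identical(wc$labels, "all")) labels <- gl
    }
  }
  nFac <- (effect@betweenScheme != "none") +
    length(effect@withinFactors)
  if (nFac >= 2L) {
    P <- .effectProjection(nG, wc$dims)
    M <- P %*% M
  }
  rownames(M) <- labels
  M
}

#' Draw one label shuffling for an effect's randomization null
#'
#' Returns a relabeling that destroys the tested effect under its null
#' hypothesis while preserving all non-tested structure; subjects' data
#' maps are never altered, only their labels. Schemes: within main
#' effects permute that factor's level labels per subject (consistently
#' across the other factor); within interactions permute all included
#' condition labels per subject; a categorical between effect permutes
#' group labels globally across used subjects; mixed interactions do
#' both simultaneously; covariate effects permute the covariate values
#' across subjects. Uses the current RNG state (seed it beforehand).
#'
#' @param within,between design objects.
#' @param effect an [EffectSpec-class].
#' @param nSubjects number of (used) subjects.
#' @return list with \code{cells} (subjects x included-conditions
#'   matrix of within-cell assignments, or NULL), \code{groups}
#'   (permuted dense group indices, or NULL) and \code{covariate}
#'   (permuted centered covariate, or NULL).
#' @export
shuffleLabels <- function(within = NULL, between = NULL, effect,
                          nSubjects) {
  nCond <- if (is.null(within)) 1L else nrow(within@levels)
  inc <- .includedConditions(within, nCond)
  wc <- .withinCells(within, effect@withinFactors, inc)
  bs <- .betweenState(between, effect)
  ctx <- .effectContext(effect, wc, bs, nSubjects)
  sh <- ctx$shuffle()
  list(cells = sh$cells, groups = sh$groups, covariate = sh$cov)
}

# --- internal: per-effect shuffling/statistic context ------------------

.effectContext <- function(effect, wc, bs, ns) {
  nci <- length(wc$cell)
  nW <- prod(wc$dims)
  baseCells <- matrix(rep(wc$cell, each = ns), ns, nci)
  groups0 <- bs$groups
  nG <- if (is.null(groups0)) 1L else max(groups0)

  sampleWithin <- switch(effect@withinScheme,
    none = function() baseCells,
    factor = {
      # per-subject permutation of the involved factor's levels,
      # applied consistently across the other factor's levels;
      # wc$cell is the dense level of the single involved factor
      lev <- wc$cell
      nl <- wc$dims[1L]
      function() {
        perms <- matrix(0L, ns, nl)
        for (s in seq_len(ns)) perms[s, ] <- sample.int(nl)
        matrix(perms[cbind(rep(seq_len(ns), nci),
                           rep(lev, each = ns))], ns, nci)
      }
    },
    conditions = function() {
      cells <- matrix(0L, ns, nci)
      for (s in seq_len(ns))
        cells[s, ] <- wc$cell[sample.int(nci)]
      cells
    },
    stop("unknown within scheme"))

  shuffle <- function() {
    cells <- if (effect@betweenScheme == "covariate") NULL else
      sampleWithin()
    g <- if (!is.null(groups0)) groups0[sample.int(ns)] else NULL
    cv <- if (!is.null(bs$cov)) bs$cov[sample.int(ns)] else NULL
    list(cells = cells, groups = g, cov = cv)
  }
  identity <- list(cells = if (effect@betweenScheme == "covariate")
    NULL else baseCells, groups = groups0, cov = bs$cov)

  list(nW = nW, nG = nG, wdims = wc$dims, baseCells = baseCells,
       groups0 = groups0, cov0 = bs$cov, labels = wc$labels,
       P = .effectProjection(nG, wc$dims),
       shuffle = shuffle, identity = identity)
}
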