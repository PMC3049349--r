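#' Define a synthetic ERP source
#'
#' One source of the additive generative model: a fixed topography
#' whose amplitude follows a time course and is scaled per
#' design cell, group and/or covariate. The per-(subject, condition)
#' gain is \code{(amplitude * cellGain[cond] * groupGain[g(s)] +
#' covariateSlope * b(s)) * subjectFactor(s)}.
#'
#' @param topography sensor vector (will be average-referenced and
#'   scaled to unit GFP) or NULL for a random smooth unit-GFP map.
#' @param center,width Gaussian amplitude pulse center and SD in
#'   samples; alternatively pass \code{timecourse} directly.
#' @param timecourse optional explicit amplitude time course.
#' @param amplitude base amplitude (same units as the noise SD).
#' @param cellGain per-condition gain: vector over conditions or
#'   matrix over the factor-level grid (first factor in rows); NULL =
#'   all 1 (a background source common to all cells).
#' @param groupGain per-group gain vector; NULL = 1 for all groups.
#' @param covariateSlope linear dependence of the gain on the
#'   per-subject covariate.
#' @return a list describing the source.
#' @export
simSource <- function(topography = NULL, center = 20, width = 3,
                      timecourse = NULL, amplitude = 1,
                      cellGain = NULL, groupGain = NULL,
                      covariateSlope = 0) {
  list(topography = topography, center = center, width = width,
       timecourse = timecourse, amplitude = amplitude,
       cellGain = cellGain, groupGain = groupGain,
       covariateSlope = covariateSlope)
}

#' Generative specification for synthetic ERP datasets
#'
#' The generator emulates the physics of scalp field data: scalp
#' fields are additive, so each dataset is a superposition of fixed
#' source topographies with cell/group/covariate-dependent amplitudes,
#' per-subject gain variability, and spatially correlated sensor noise
#' (a squared-exponential kernel over montage distance mimics the
#' spatial blurring of the leadfield). The default toy scale is 12
#' subjects, a 2 x 2 within design, 40 time points and 16 sensors.
#'
#' @param nSubjects,nTime,nSensors data dimensions.
#' @param factorLevels within factor level counts (length 1 or 2);
#'   conditions are the full crossing, labelled \code{A1.B1} etc.
#' @param samplingRate Hz.
#' @param sources list of [simSource()] definitions.
#' @param nGroups number of (balanced, block-assigned) groups; 0 for
#'   none.
#' @param covariate draw a standardized per-subject covariate.
#' @param subjectSd SD of the multiplicative per-subject gain.
#' @param noiseSd sensor noise SD.
#' @param noiseCorrLength spatial correlation length of the noise (in
#'   montage units; 0 = white).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an [ErpSimSpec-class].
#' @export
erpSimSpec <- function(nSubjects = 12, factorLevels = c(2, 2),
                       nTime = 40, nSensors = 16, samplingRate = 250,
                       sources = list(simSource()), nGroups = 0,
                       covariate = FALSE, subjectSd = 0.2,
                       noiseSd = 1, noiseCorrLength = 0.6,
                       seed = 1) {
  new("ErpSimSpec", nSubjects = as.integer(nSubjects),
      factorLevels = as.integer(factorLevels),
      nTime = as.integer(nTime), nSensors = as.integer(nSensors),
      samplingRate = samplingRate, sources = sources,
      nGroups = as.integer(nGroups), covariate = covariate,
      subjectSd = subjectSd, noiseSd = noiseSd,
      noiseCorrLength = noiseCorrLength, seed = as.integer(seed))
}

# random smooth unit-GFP topography given sensor positions
.randomTopography <- function(pos, chol_) {
  z <- as.vector(rnorm(nrow(pos)) %*% chol_)
  z <- z - mean(z)
  g <- sqrt(mean(z^2))
  if (g == 0) z[1L] <- 1 else z <- z / g
  z - mean(z)
}

.spatialChol <- function(pos, ell) {
  n <- nrow(pos)
  if (ell <= 0) return(diag(n))
  dmat <- as.matrix(dist(pos))
  K <- exp(-dmat^2 / (2 * ell^2)) + diag(1e-6, n)
  chol(K)
}

#' Generate a synthetic ERP dataset with known ground truth
#'
#' @param spec an [ErpSimSpec-class].
#' @return list with elements \code{dataset} (an average-referenced
#'   [ErpDataset-class] with a circular montage) and \code{truth}: the
#'   true source topographies, time courses, effect windows (samples
#'   where the time course exceeds 5\% of its peak), group assignment,
#'   covariate values and per-subject gains.
#' @examples
#' sim <- simulateErp(erpSimSpec(nSubjects = 4, nTime = 10,
#'                               nSensors = 8, seed = 42))
#' sim$dataset
#' @export
simulateErp <- function(spec) {
  validObject(spec)
  ns <- spec@nSubjects; nt <- spec@nTime; nch <- spec@nSensors
  fl <- spec@factorLevels
  nc <- prod(fl)
  mont <- circularMontage(nch)
  pos <- as.matrix(mont[, c("x", "y")])
  condLabs <- if (length(fl) == 2L)
    as.vector(t(outer(sprintf("A%d", seq_len(fl[1L])),
                      sprintf("B%d", seq_len(fl[2L])), paste,
                      sep = "."))) else sprintf("A%d", seq_len(fl[1L]))
  groups <- if (spec@nGroups > 0L)
    rep(seq_len(spec@nGroups), length.out = ns) else NULL
  .withSeed(spec@seed, {
    chol_ <- .spatialChol(pos, spec@noiseCorrLength)
    b <- if (spec@covariate) {
      v <- rnorm(ns)
      as.vector(scale(v))
    } else NULL
    subjF <- pmax(0.2, 1 + rnorm(ns) * spec@subjectSd)
    x <- array(0, c(ns, nc, nt, nch))
    truthSources <- vector("list", length(spec@sources))
    for (k in seq_along(spec@sources)) {
      src <- spec@sources[[k]]
      topo <- if (is.null(src$topography))
        .randomTopography(pos, chol_) else {
          tp <- src$topography - mean(src$topography)
          tp / sqrt(mean((tp - mean(tp))^2))
        }
      tc <- if (!is.null(src$timecourse)) src$timecourse else
        exp(-(seq_len(nt) - src$center)^2 / (2 * src$width^2))
      cg <- if (is.null(src$cellGain)) rep(1, nc) else {
        v <- if (is.matrix(src$cellGain))
          as.vector(t(src$cellGain)) else src$cellGain
        if (length(v) != nc)
          stop("cellGain must cover all ", nc, " conditions")
        v
      }
      gg <- if (is.null(src$groupGain) || is.null(groups))
        rep(1, max(1L, spec@nGroups)) else src$groupGain
      for (s in seq_len(ns)) {
        gs <- if (is.null(groups)) 1 else gg[groups[s]]
        bs <- if (is.null(b)) 0 else src$covariateSlope * b[s]
        for (ci in seq_len(nc)) {
          gain <- (src$amplitude * cg[ci] * gs + bs) * subjF[s]
          if (gain != 0)
            x[s, ci, , ] <- x[s, ci, , ] + gain * outer(tc, topo)
        }
      }
      truthSources[[k]] <- list(
        topography = topo, timecourse = tc,
        window = which(tc > 0.05 * max(tc)), cellGain = cg,
        groupGain = gg, covariateSlope = src$covariateSlope)
    }
    if (spec@noiseSd > 0) {
      z <- matrix(rnorm(ns * nc * nt * nch), ns * nc * nt, nch)
      eps <- spec@noiseSd * (z %*% chol_)
      x <- x + array(eps, c(ns, nc, nt, nch))
    }
    ds <- erpDataset(x, samplingRate = spec@samplingRate, onset = 0,
                     conditionLabels = condLabs, montage = mont)
    ds <- applyAverageReference(ds)
    list(dataset = ds,
         truth = list(sources = truthSources, groups = groups,
                      covariate = b, subjectFactor = subjF,
                      factorLevels = fl))
  })
}

#' Within design matching a simulated dataset's factorial structure
#'
#' @param spec the [ErpSimSpec-class] used for generation.
#' @return a [WithinDesign-class] over the full crossing.
#' @export
simWithinDesign <- function(spec) {
  fl <- spec@factorLevels
  if (length(fl) == 2L) {
    grid <- expand.grid(B = seq_len(fl[2L]), A = seq_len(fl[1L]))
    withinDesign(list(A = grid$A, B = grid$B))
  } else {
    withinDesign(list(A = seq_len(fl[1L])))
  }
}
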