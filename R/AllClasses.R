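#' @import methods
#' @importFrom stats rnorm runif sd quantile ks.test t.test p.adjust cor
#' @importFrom utils count.fields read.table write.table head tail
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' ErpDataset: multi-subject factorial ERP scalp field data
#'
#' Container for event-related scalp field data from a factorial
#' experiment: a 4-D numeric array indexed (subject, condition, time,
#' sensor), plus sampling metadata and an optional sensor montage.
#' Statistics in this package never use the montage; it serves display
#' and interpolation only.
#'
#' @slot data numeric 4-D array, subjects x conditions x time x sensors
#'   (potentials in microvolts or fields in femtotesla; units are
#'   metadata only, statistics are unit-agnostic).
#' @slot samplingRate sampling rate in Hz.
#' @slot onset latency of the first sample in ms relative to the event.
#' @slot subjectLabels one label per subject.
#' @slot conditionLabels one label per condition.
#' @slot montage optional data.frame with columns \code{name}, \code{x},
#'   \code{y} (and optionally \code{z}).
#' @slot reference \code{"average"} once the average reference has been
#'   applied, otherwise \code{"none"}.
#' @seealso [erpDataset()], [importDataset()], [applyAverageReference()]
#' @export
setClass("ErpDataset",
  representation(
    data = "array",
    samplingRate = "numeric",
    onset = "numeric",
    subjectLabels = "character",
    conditionLabels = "character",
    montage = "dfOrNULL",
    reference = "character"
  ),
  prototype(samplingRate = 1000, onset = 0, montage = NULL,
            reference = "none")
)

setValidity("ErpDataset", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-D array (subject, condition, time, sensor)")
  if (any(d < 1L))
    return("all four dimensions must be >= 1")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("data must be finite with no missing cells")
  if (length(object@subjectLabels) != d[1L])
    return("subjectLabels length must equal the number of subjects")
  if (length(object@conditionLabels) != d[2L])
    return("conditionLabels length must equal the number of conditions")
  if (anyDuplicated(object@subjectLabels))
    return("subject labels must be unique")
  if (anyDuplicated(object@conditionLabels))
    return("condition labels must be unique")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (!is.null(object@montage)) {
    m <- object@montage
    if (!all(c("name", "x", "y") %in% names(m)))
      return("montage needs columns name, x, y")
    if (nrow(m) != d[4L])
      return("montage must have one entry per sensor")
    if (anyDuplicated(m$name))
      return("montage sensor names must be unique")
  }
  TRUE
})

#' WithinDesign: factor-level assignment of conditions
#'
#' Up to two within-subject factors; each included condition carries a
#' level index on every factor. With two factors the included conditions
#' must form a complete (orthogonal) crossing. Conditions with an
#' \code{NA} level are excluded from analysis.
#'
#' @slot factorNames names of the one or two factors.
#' @slot levels integer matrix, conditions x factors; \code{NA} rows mark
#'   excluded conditions.
#' @slot levelLabels list (one element per factor) of level label vectors.
#' @seealso [withinDesign()], [enumerateEffects()]
#' @export
setClass("WithinDesign",
  representation(
    factorNames = "character",
    levels = "matrix",
    levelLabels = "list"
  )
)

setValidity("WithinDesign", function(object) {
  nf <- length(object@factorNames)
  if (nf < 1L || nf > 2L)
    return("at most two within-subject factors are supported")
  if (ncol(object@levels) != nf)
    return("levels must have one column per factor")
  lv <- object@levels
  inc <- rowSums(is.na(lv)) == 0L
  if (any(rowSums(is.na(lv)) %in% seq_len(nf - 1L)))
    return("an included condition needs a level on every factor")
  if (!any(inc))
    return("at least one condition must be included")
  for (f in seq_len(nf)) {
    nl <- length(object@levelLabels[[f]])
    if (any(lv[inc, f] < 1L | lv[inc, f] > nl))
      return(sprintf("factor %d has level indices outside its labels",
                     f))
  }
  if (nf == 2L) {
    tab <- table(lv[inc, 1L], lv[inc, 2L])
    u1 <- sort(unique(lv[inc, 1L])); u2 <- sort(unique(lv[inc, 2L]))
    if (nrow(tab) != length(u1) || ncol(tab) != length(u2) ||
        any(tab == 0L) || length(unique(as.vector(tab))) != 1L)
      return(paste("the levels of the two factors must be orthogonal:",
                   "included conditions must form a complete, balanced",
                   "crossing"))
  }
  TRUE
})

#' BetweenDesign: group labels or a continuous covariate per subject
#'
#' One between-subject factor: either a categorical group assignment or
#' a continuous (interval/rank scaled) covariate used for TANCOVA.
#' Individual subjects can be excluded via the use flag.
#'
#' @slot mode \code{"categorical"} or \code{"continuous"}.
#' @slot values per-subject group index (categorical) or covariate value.
#' @slot use logical per subject; excluded subjects enter no analysis.
#' @slot groupLabels labels of the groups (categorical mode).
#' @slot name name of the between variable (appears in effect labels).
#' @seealso [betweenDesign()], [runTancova()]
#' @export
setClass("BetweenDesign",
  representation(
    mode = "character",
    values = "numeric",
    use = "logical",
    groupLabels = "character",
    name = "character"
  ),
  prototype(name = "group")
)

setValidity("BetweenDesign", function(object) {
  if (!object@mode %in% c("categorical", "continuous"))
    return("mode must be 'categorical' or 'continuous'")
  if (length(object@use) != length(object@values))
    return("use flags must match values length")
  if (!any(object@use))
    return("at least one subject must be in use")
  v <- object@values[object@use]
  if (anyNA(v))
    return("used subjects must all have a value")
  if (object@mode == "categorical") {
    if (any(v < 1L | v != round(v)))
      return("categorical values must be positive group indices")
    if (length(object@groupLabels) < max(v))
      return("groupLabels must cover all group indices")
  } else {
    if (length(unique(v)) < 2L)
      return("a continuous covariate needs >= 2 distinct values")
  }
  TRUE
})

#' EffectSpec: one testable effect and its permutation scheme
#'
#' Identifies a main effect or interaction of the design, the within
#' factors it marginalizes over, and the label-shuffling scheme that
#' generates its randomization null.
#'
#' @slot id short effect code (\code{"A"}, \code{"B"}, \code{"AxB"},
#'   \code{"G"}, \code{"GxA"}, \code{"GxB"}, \code{"GxAxB"}, or
#'   \code{"Cov"} analogues for a continuous covariate).
#' @slot label human-readable label built from factor names.
#' @slot withinFactors indices of the within factors involved.
#' @slot withinScheme \code{"none"}, \code{"factor"} (per-subject
#'   permutation of one factor's levels, consistent across the other
#'   factor) or \code{"conditions"} (per-subject permutation of all
#'   included condition labels).
#' @slot betweenScheme \code{"none"}, \code{"group"} (global permutation
#'   of group labels) or \code{"covariate"} (permutation of covariate
#'   values across subjects).
#' @export
setClass("EffectSpec",
  representation(
    id = "character",
    label = "character",
    withinFactors = "integer",
    withinScheme = "character",
    betweenScheme = "character"
  )
)

#' RandomizationOptions: parameters of the randomization tests
#'
#' @slot nRuns number of randomization runs (1000 recommended for
#'   alpha = .05, 5000 for alpha = .01).
#' @slot alpha significance threshold in (0, 1).
#' @slot normalization \code{"none"}, \code{"l2"} (each individual map
#'   scaled to unit global field power before averaging; recommended) or
#'   \code{"dissimilarity"} (legacy: grand-mean maps normalized instead).
#' @slot seed integer seed driving all shuffles (NA: use current RNG
#'   state); per-effect substreams are derived deterministically.
#' @slot window optional analysis window \code{c(start, end)} in ms,
#'   half-open \code{[start, end)}; empty means the full epoch.
#' @seealso [randomizationOptions()]
#' @export
setClass("RandomizationOptions",
  representation(
    nRuns = "integer",
    alpha = "numeric",
    normalization = "character",
    seed = "integer",
    window = "numeric"
  ),
  prototype(nRuns = 1000L, alpha = 0.05, normalization = "l2",
            seed = NA_integer_, window = numeric(0))
)

setValidity("RandomizationOptions", function(object) {
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (!object@normalization %in% c("none", "l2", "dissimilarity"))
    return("normalization must be none, l2 or dissimilarity")
  if (length(object@window) %in% c(0L, 2L) == FALSE)
    return("window must be empty or c(start, end) in ms")
  if (length(object@window) == 2L && diff(object@window) <= 0)
    return("window end must exceed window start")
  TRUE
})

#' RandomizationResult: observed strengths, null matrices and p-values
#'
#' One TANOVA/TANCOVA run: per effect, the observed global effect
#' strength s(t), the randomization null matrix (runs x time) and the
#' time-point-wise p-values.
#'
#' @slot effects list of [EffectSpec-class] objects, in test order.
#' @slot observed matrix effects x time of observed s.
#' @slot null list (per effect) of runs x time null matrices.
#' @slot p matrix effects x time of p-values in (0, 1].
#' @slot timeMs time axis in ms (length 1 for window-averaged results).
#' @slot options the [RandomizationOptions-class] used.
#' @slot averaged TRUE for window-averaged analyses.
#' @slot windowMs the averaging window in ms (averaged results only).
#' @seealso [runTanova()], [globalInference()]
#' @export
setClass("RandomizationResult",
  representation(
    effects = "list",
    observed = "matrix",
    null = "list",
    p = "matrix",
    timeMs = "numeric",
    options = "RandomizationOptions",
    averaged = "logical",
    windowMs = "numeric"
  ),
  prototype(averaged = FALSE, windowMs = numeric(0))
)

setValidity("RandomizationResult", function(object) {
  ne <- length(object@effects)
  nt <- length(object@timeMs)
  if (nrow(object@observed) != ne || ncol(object@observed) != nt)
    return("observed must be effects x time")
  if (length(object@null) != ne)
    return("one null matrix per effect required")
  for (m in object@null) {
    if (ncol(m) != nt) return("null matrices must share the time axis")
    if (nrow(m) != object@options@nRuns)
      return("null row count must equal nRuns")
  }
  if (any(object@p <= 0) || any(object@p > 1))
    return("p-values must lie in (0, 1]")
  TRUE
})

#' GlobalInference: count-test p and duration thresholds per effect
#'
#' Global multiple-testing control across time derived from the same
#' randomization runs as the time-point-wise test: the
#' count-of-significant-time-points global p, the duration threshold
#' (samples and ms), and the clusters surviving it.
#'
#' @slot table data.frame with one row per effect: \code{effect},
#'   \code{countP}, \code{thresholdSamples}, \code{thresholdMs},
#'   \code{nClusters}.
#' @slot clusters list (per effect) of data.frames with cluster
#'   \code{startSample}, \code{endSample}, \code{startMs}, \code{endMs}.
#' @slot alpha the threshold the inference was computed at.
#' @seealso [globalInference()], [durationThreshold()]
#' @export
setClass("GlobalInference",
  representation(table = "data.frame", clusters = "list",
                 alpha = "numeric")
)

#' TctResult: topographic consistency test outcome
#'
#' Per condition (or group x condition stratum): the p-value trace of
#' the consistency test, the GFP of the across-subject mean map, and the
#' intervals of consistent topography surviving the duration threshold.
#'
#' @slot strata labels of the tested strata.
#' @slot p matrix strata x time.
#' @slot gfpMean matrix strata x time: GFP of the mean map (raw scale).
#' @slot thresholds duration threshold in samples per stratum.
#' @slot intervals list per stratum of consistent-interval data.frames.
#' @slot timeMs time axis in ms.
#' @slot options the [RandomizationOptions-class] used.
#' @seealso [topographicConsistencyTest()]
#' @export
setClass("TctResult",
  representation(
    strata = "character",
    p = "matrix",
    gfpMean = "matrix",
    thresholds = "numeric",
    intervals = "list",
    timeMs = "numeric",
    options = "RandomizationOptions"
  )
)

#' MdsProjection: mean maps in the plane of the first two eigenvectors
#'
#' Spatial PCA of a set of (centered) mean scalp field maps: each map is
#' projected onto the first two eigenvectors of the between-map
#' covariance structure, yielding 2-D display coordinates.
#'
#' @slot coordinates maps x 2 matrix of projections.
#' @slot eigenvectorMaps sensors x 2 matrix: the two spatial
#'   eigenvector maps (orthonormal; sign fixed so the largest-|loading|
#'   sensor is positive).
#' @slot explained fraction of total between-map covariance captured by
#'   each of the two axes.
#' @slot labels map labels.
#' @seealso [mdsProject()]
#' @export
setClass("MdsProjection",
  representation(
    coordinates = "matrix",
    eigenvectorMaps = "matrix",
    explained = "numeric",
    labels = "character"
  )
)

#' ErpSimSpec: generative specification for synthetic ERP data
#'
#' Additive source model: each source is a fixed unit-GFP topography
#' multiplied by an amplitude time course and by cell/group/covariate
#' dependent gains, superposed and measured with spatially correlated
#' sensor noise. The ground truth (true effect windows, true
#' topographies) is returned alongside the data so every statistic is
#' testable.
#'
#' @slot nSubjects,nTime,nSensors data dimensions.
#' @slot factorLevels integer vector (length 1 or 2) of within factor
#'   level counts; conditions form the full crossing.
#' @slot samplingRate Hz.
#' @slot sources list of source definitions (see [erpSimSpec()]).
#' @slot nGroups number of between groups (0: none).
#' @slot covariate logical: draw a per-subject covariate.
#' @slot subjectSd SD of the multiplicative per-subject gain (around 1).
#' @slot noiseSd sensor noise SD.
#' @slot noiseCorrLength squared-exponential spatial correlation length
#'   of the noise, in montage distance units (0: white noise).
#' @slot seed integer seed; generation is deterministic given the seed.
#' @seealso [erpSimSpec()], [simulateErp()]
#' @export
setClass("ErpSimSpec",
  representation(
    nSubjects = "integer",
    factorLevels = "integer",
    nTime = "integer",
    nSensors = "integer",
    samplingRate = "numeric",
    sources = "list",
    nGroups = "integer",
    covariate = "logical",
    subjectSd = "numeric",
    noiseSd = "numeric",
    noiseCorrLength = "numeric",
    seed = "integer"
  )
)

setValidity("ErpSimSpec", function(object) {
  if (object@nSubjects < 2L) return("need >= 2 subjects")
  if (object@nTime < 1L || object@nSensors < 2L)
    return("need >= 1 time point and >= 2 sensors")
  if (length(object@factorLevels) < 1L ||
      length(object@factorLevels) > 2L ||
      any(object@factorLevels < 1L))
    return("factorLevels must be 1 or 2 positive counts")
  if (object@noiseSd < 0 || object@subjectSd < 0)
    return("noise and subject SDs must be >= 0")
  if (object@nGroups > 0L && object@nSubjects < 2L * object@nGroups)
    return("each group needs >= 2 subjects")
  TRUE
})
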