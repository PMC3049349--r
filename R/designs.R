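#' Construct a within-subject design
#'
#' Assigns each condition a level on one or two within-subject factors.
#' Conditions given an \code{NA} level are excluded from analysis (for
#' post-hoc comparisons). With two factors, the included conditions must
#' form a complete, balanced crossing of the levels (orthogonality); a
#' design whose exclusions break the crossing is rejected with an error.
#'
#' @param factors named list: one or two elements, each an integer (or
#'   \code{NA}) vector of level indices per condition; names are the
#'   factor names.
#' @param levelLabels optional list of level label vectors per factor;
#'   defaults are generated.
#' @return a [WithinDesign-class].
#' @examples
#' # 2 x 2: conditions C1, C2, F1, F2
#' wd <- withinDesign(list(
#'   expectancy = c(1, 1, 2, 2),
#'   day = c(1, 2, 1, 2)))
#' @export
withinDesign <- function(factors, levelLabels = NULL) {
  if (!is.list(factors) || is.null(names(factors)) ||
      any(names(factors) == ""))
    stop("factors must be a named list of level vectors")
  lv <- vapply(factors, as.integer, integer(length(factors[[1L]])))
  lv <- matrix(lv, ncol = length(factors))
  if (is.null(levelLabels))
    levelLabels <- lapply(seq_along(factors), function(f)
      as.character(seq_len(max(lv[, f], na.rm = TRUE))))
  new("WithinDesign", factorNames = names(factors), levels = lv,
      levelLabels = levelLabels)
}

#' Construct a between-subject design
#'
#' Either a categorical group assignment or a continuous/rank-scaled
#' covariate per subject (the TANCOVA predictor). Subjects can be
#' excluded from all analyses via \code{use}.
#'
#' @param values per-subject group index (categorical) or covariate
#'   value (continuous). \code{NA} values force \code{use = FALSE}.
#' @param mode \code{"categorical"} or \code{"continuous"}.
#' @param use logical per subject (default: value not NA).
#' @param groupLabels labels for the groups (categorical mode).
#' @param name variable name, shown in effect labels.
#' @return a [BetweenDesign-class].
#' @examples
#' bd <- betweenDesign(c(1, 1, 2, 2), mode = "categorical",
#'                     groupLabels = c("good", "poor"),
#'                     name = "learning")
#' @export
betweenDesign <- function(values,
                          mode = c("categorical", "continuous"),
                          use = NULL, groupLabels = NULL,
                          name = "group") {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (is.null(use)) use <- !is.na(values)
  use <- use & !is.na(values)
  if (is.null(groupLabels))
    groupLabels <- if (mode == "categorical" && any(use))
      sprintf("group %d", seq_len(max(values[use]))) else character(0)
  new("BetweenDesign", mode = mode, values = values, use = use,
      groupLabels = groupLabels, name = name)
}

#' @rdname BetweenDesign-class
#' @param x a BetweenDesign.
#' @export
useFlags <- function(x) x@use

setMethod("show", "WithinDesign", function(object) {
  cat("WithinDesign:", paste(object@factorNames, collapse = " x "),
      "\n")
  inc <- rowSums(is.na(object@levels)) == 0L
  cat(" ", sum(inc), "included /", nrow(object@levels),
      "conditions\n")
  for (f in seq_along(object@factorNames))
    cat("  ", object@factorNames[f], ": ",
        paste(object@levelLabels[[f]], collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "BetweenDesign", function(object) {
  cat("BetweenDesign (", object@mode, "): '", object@name, "', ",
      sum(object@use), " of ", length(object@use),
      " subjects in use\n", sep = "")
})

#' Read design tables from declarative text files
#'
#' \code{readWithinDesign} reads a tab/space-delimited table with a
#' header, one row per condition: a \code{condition} column followed by
#' one column per factor holding level indices (empty/NA = excluded).
#' \code{readBetweenDesign} reads a table with columns \code{subject},
#' \code{value} and optionally \code{use} (0/1).
#'
#' @param path file path.
#' @param mode for the between table, \code{"categorical"} or
#'   \code{"continuous"}.
#' @param name between variable name.
#' @return a design object.
#' @export
readWithinDesign <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("within-design table needs a condition column and >= 1 factor")
  factors <- as.list(tab[-1L])
  withinDesign(factors)
}

#' @rdname readWithinDesign
#' @export
readBetweenDesign <- function(path,
                              mode = c("categorical", "continuous"),
                              name = "group") {
  mode <- match.arg(mode)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"value" %in% names(tab))
    stop("between-design table needs a 'value' column")
  use <- if ("use" %in% names(tab)) tab$use != 0 else NULL
  betweenDesign(tab$value, mode = mode, use = use, name = name)
}

# --- internal design helpers -------------------------------------------

.includedConditions <- function(within, nCond) {
  if (is.null(within)) return(seq_len(nCond))
  which(rowSums(is.na(within@levels)) == 0L)
}

# grid cell index of each included condition over the given within
# factors (first listed factor slowest); list(cell, dims, labels)
.withinCells <- function(within, factors, inc) {
  if (length(factors) == 0L) {
    return(list(cell = rep(1L, length(inc)), dims = 1L,
                labels = "all"))
  }
  lv <- within@levels[inc, , drop = FALSE]
  dims <- vapply(factors, function(f)
    length(unique(lv[, f])), integer(1))
  # map raw level indices to dense 1..k (levels absent after exclusion)
  dense <- lapply(factors, function(f)
    match(lv[, f], sort(unique(lv[, f]))))
  cell <- dense[[1L]]
  if (length(factors) == 2L)
    cell <- (dense[[1L]] - 1L) * dims[2L] + dense[[2L]]
  labs <- lapply(seq_along(factors), function(k) {
    f <- factors[k]
    within@levelLabels[[f]][sort(unique(lv[, f]))]
  })
  labels <- labs[[1L]]
  if (length(factors) == 2L)
    labels <- as.vector(t(outer(labs[[1L]], labs[[2L]], paste,
                                sep = ".")))
  list(cell = cell, dims = dims, labels = labels)
}

.centerMat <- function(k) diag(k) - 1 / k

# centering projection over the effect's cell grid: Kronecker product
# of per-factor centering matrices, group factor slowest
.effectProjection <- function(nG, wdims) {
  parts <- list()
  if (nG > 1L) parts <- c(parts, list(.centerMat(nG)))
  for (d in wdims) if (d > 1L) parts <- c(parts, list(.centerMat(d)))
  if (length(parts) == 0L) return(matrix(1, 1, 1))
  Reduce(`%x%`, parts)
}
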