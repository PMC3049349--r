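#' Global Field Power of a scalp map
#'
#' The GFP is the root-mean-square deviation of the map about its
#' spatial mean, i.e. the (population) standard deviation across
#' sensors: \code{sqrt(mean((v - mean(v))^2))}. It is independent of the
#' recording reference (invariant to adding a constant to all sensors)
#' and absolutely homogeneous: \code{gfp(k * m) == abs(k) * gfp(m)}.
#'
#' @param map numeric vector of sensor values (>= 2 sensors).
#' @return non-negative scalar.
#' @examples
#' gfp(c(1, -1))   # 1
#' gfp(c(5, 5, 5)) # 0
#' @export
gfp <- function(map) {
  if (length(map) < 2L)
    stop("GFP needs at least 2 sensors")
  if (anyNA(map) || any(!is.finite(map)))
    stop("map must be finite")
  sqrt(mean((map - mean(map))^2))
}

#' Normalize a scalp map to unit GFP
#'
#' L2 normalization scales each map to unit spatial variance (unit
#' GFP), dissociating topographic (qualitative) from amplitude
#' (quantitative) differences. The map's shape (direction) is
#' preserved: the output is proportional to the centered input. The
#' \code{"dissimilarity"} mode performs the same scaling; the modes
#' differ only in where the analysis pipeline applies them (individual
#' maps vs. grand-mean maps).
#'
#' @param map numeric sensor vector.
#' @param mode \code{"l2"}, \code{"none"} or \code{"dissimilarity"}.
#' @return the normalized map (unchanged for \code{"none"}).
#' @examples
#' normalizeMap(c(2, -2))  # c(1, -1)
#' @export
normalizeMap <- function(map, mode = c("l2", "none", "dissimilarity")) {
  mode <- match.arg(mode)
  if (mode == "none") return(map)
  g <- gfp(map)
  if (g == 0)
    stop("cannot normalize a flat map (GFP = 0)")
  map / g
}

#' Global effect strength s of a set of cell mean maps
#'
#' The generalized GFP-of-differences statistic: with cell mean maps
#' \eqn{\bar v_{ij}} (cell i, sensor j) and the unweighted grand mean
#' \eqn{\bar{\bar v}_j} across cells,
#' \deqn{s = \sqrt{ \sum_i \sum_j (\bar v_{ij} - \bar{\bar v}_j)^2 / n }}
#' where n is the number of sensors. s is zero iff all cell means are
#' identical, invariant under permutation of the cell list and under
#' adding a common map to every cell.
#'
#' @param cellMeans numeric matrix (cells x sensors) or list of equal
#'   length sensor vectors; >= 2 cells, average-referenced.
#' @return non-negative scalar.
#' @examples
#' effectStrength(rbind(c(1, -1), c(-1, 1)))  # sqrt(2)
#' @export
effectStrength <- function(cellMeans) {
  if (is.list(cellMeans)) {
    ln <- lengths(cellMeans)
    if (length(unique(ln)) != 1L)
      stop("cell means have mismatched sensor counts")
    cellMeans <- do.call(rbind, cellMeans)
  }
  if (!is.matrix(cellMeans) || nrow(cellMeans) < 2L)
    stop("need >= 2 cell means")
  n <- ncol(cellMeans)
  grand <- colMeans(cellMeans)
  dev <- sweep(cellMeans, 2L, grand)
  sqrt(sum(dev^2) / n)
}

#' Covariance map of scalp maps with a linear predictor
#'
#' Estimates the topography of the sources whose strength varies
#' linearly with a per-observation predictor b:
#' \deqn{\beta_j = \sum_i v_{ij} (b_i - \bar b)}
#' The predictor is mean-centered (so beta is a covariance-type map,
#' not a raw cross-product); pass \code{center = FALSE} to use b as is.
#' beta is bilinear in the maps and the predictor.
#'
#' @param maps matrix (observations x sensors) or list of sensor
#'   vectors.
#' @param predictor numeric vector, one value per map.
#' @param center mean-center the predictor (default TRUE).
#' @return sensor vector beta.
#' @export
covarianceMap <- function(maps, predictor, center = TRUE) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  if (nrow(maps) != length(predictor))
    stop("one predictor value per map required")
  b <- if (center) predictor - mean(predictor) else predictor
  as.vector(crossprod(maps, b))
}

#' TANCOVA effect strength: GFP of the covariance map
#'
#' @param beta a covariance map (sensor vector).
#' @return non-negative scalar, \code{gfp(beta)}.
#' @export
tancovaStrength <- function(beta) gfp(beta)
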