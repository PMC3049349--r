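#' Project mean maps onto their first two spatial eigenvectors
#'
#' Spatial PCA / multidimensional scaling of a set of mean scalp field
#' maps: the maps are centered across the map set, the eigenstructure
#' of their between-map covariance is computed, and each map is
#' projected onto the first two (orthonormal) spatial eigenvectors,
#' yielding 2-D coordinates whose distances approximate the maps'
#' dissimilarities. Eigenvector signs are fixed so that the
#' largest-|loading| sensor is positive, making plots reproducible. A
#' rank-1 map set yields a second coordinate of zero (not an error).
#'
#' @param maps matrix (maps x sensors) or list of sensor vectors;
#'   >= 2 maps on a common sensor set. Typically the output of
#'   [cellMeans()].
#' @param labels optional map labels.
#' @return an [MdsProjection-class].
#' @examples
#' m <- c(1, -1, 0.5, -0.5)
#' proj <- mdsProject(rbind(m, -m))
#' proj@coordinates   # symmetric about the origin on axis 1
#' @export
mdsProject <- function(maps, labels = NULL) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  if (!is.matrix(maps) || nrow(maps) < 2L)
    stop("need >= 2 maps")
  if (is.null(labels))
    labels <- if (!is.null(rownames(maps))) rownames(maps) else
      sprintf("map%d", seq_len(nrow(maps)))
  Xc <- scale(maps, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  k <- length(sv$d)
  V <- matrix(0, ncol(maps), 2L)
  dd <- c(sv$d, 0, 0)[1:2]
  V[, seq_len(min(2L, k))] <- sv$v[, seq_len(min(2L, k)),
                                   drop = FALSE]
  # treat numerically-zero axes as absent (rank deficiency)
  for (a in 1:2)
    if (dd[a] < max(dd[1L], .Machine$double.eps) * 1e-8)
      V[, a] <- 0
  for (a in 1:2) {
    if (all(V[, a] == 0)) next
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) V[, a] <- -V[, a]
  }
  coords <- Xc %*% V
  expl <- if (tot > 0) dd^2 / tot else c(0, 0)
  dimnames(coords) <- list(labels, c("axis1", "axis2"))
  new("MdsProjection", coordinates = coords, eigenvectorMaps = V,
      explained = expl, labels = labels)
}

setMethod("show", "MdsProjection", function(object) {
  cat("MdsProjection of", nrow(object@coordinates), "mean maps\n")
  cat(sprintf("  axis 1: %.1f%%, axis 2: %.1f%% of between-map covariance\n",
              100 * object@explained[1L], 100 * object@explained[2L]))
  print(round(object@coordinates, 4))
})

#' @rdname MdsProjection-class
#' @param x an MdsProjection.
#' @export
mdsCoordinates <- function(x) x@coordinates

#' @rdname MdsProjection-class
#' @export
eigenvectorMaps <- function(x) x@eigenvectorMaps
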