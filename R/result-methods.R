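.effectRow <- function(x, effect) {
  ids <- vapply(x@effects, function(e) e@id, character(1))
  labs <- vapply(x@effects, function(e) e@label, character(1))
  i <- which(ids == effect | labs == effect)
  if (length(i) != 1L)
    stop("unknown effect '", effect, "'; available: ",
         paste(ids, collapse = ", "))
  i
}

#' @rdname RandomizationResult-class
#' @export
setMethod("effectIds", "RandomizationResult", function(x)
  vapply(x@effects, function(e) e@id, character(1)))

#' @rdname RandomizationResult-class
#' @export
setMethod("pValues", "RandomizationResult", function(x, effect = NULL) {
  if (is.null(effect)) return(x@p)
  x@p[.effectRow(x, effect), ]
})

#' @rdname RandomizationResult-class
#' @export
setMethod("observedStrength", "RandomizationResult",
          function(x, effect = NULL) {
  if (is.null(effect)) return(x@observed)
  x@observed[.effectRow(x, effect), ]
})

#' @rdname RandomizationResult-class
#' @export
setMethod("nullDistribution", "RandomizationResult",
          function(x, effect) x@null[[.effectRow(x, effect)]])

#' @rdname RandomizationResult-class
#' @export
setMethod("timePoints", "RandomizationResult", function(x) x@timeMs)

setMethod("show", "RandomizationResult", function(object) {
  kind <- if (any(vapply(object@effects, function(e)
    e@betweenScheme == "covariate", logical(1)))) "TANCOVA" else
      "TANOVA"
  cat(kind, if (object@averaged) "(window-averaged)" else
    "(time-point-wise)", "\n")
  cat(" ", length(object@effects), "effects x",
      length(object@timeMs), "time points;",
      object@options@nRuns, "runs; normalization:",
      object@options@normalization, "\n")
  if (object@averaged && length(object@windowMs) == 2L)
    cat("  window:", object@windowMs[1L], "-", object@windowMs[2L],
        "ms\n")
  for (e in seq_along(object@effects)) {
    p <- object@p[e, ]
    cat(sprintf("  %-10s min p = %.4g (%d of %d samples < %.2g)\n",
                object@effects[[e]]@id, min(p),
                sum(p < object@options@alpha), length(p),
                object@options@alpha))
  }
})

setMethod("show", "GlobalInference", function(object) {
  cat("GlobalInference at alpha =", object@alpha, "\n")
  print(object@table, row.names = FALSE)
})

#' @rdname GlobalInference-class
#' @param x a GlobalInference.
#' @export
globalTable <- function(x) x@table

#' @rdname GlobalInference-class
#' @param effect effect id.
#' @export
significantClusters <- function(x, effect) {
  i <- which(x@table$effect == effect)
  if (length(i) != 1L) stop("unknown effect '", effect, "'")
  x@clusters[[i]]
}
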