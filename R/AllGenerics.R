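#' @rdname ErpDataset-class
#' @param object,x an object.
#' @export
setGeneric("erpData", function(x) standardGeneric("erpData"))

#' @rdname ErpDataset-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname ErpDataset-class
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' @rdname ErpDataset-class
#' @export
setGeneric("conditionLabels",
           function(x) standardGeneric("conditionLabels"))

#' @rdname ErpDataset-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname ErpDataset-class
#' @export
setGeneric("nConditions", function(x) standardGeneric("nConditions"))

#' @rdname ErpDataset-class
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname ErpDataset-class
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname ErpDataset-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname ErpDataset-class
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' Apply the average reference
#'
#' Subtracts, at every subject/condition/time point, the mean over
#' sensors, so that every map has zero spatial mean. All statistics in
#' this package assume average-referenced data. The operation is
#' idempotent and leaves the GFP of every map unchanged.
#'
#' @param x an [ErpDataset-class].
#' @return the re-referenced dataset (reference flag set).
#' @export
setGeneric("applyAverageReference",
           function(x) standardGeneric("applyAverageReference"))

#' @rdname RandomizationResult-class
#' @param x a result object.
#' @export
setGeneric("effectIds", function(x) standardGeneric("effectIds"))

#' @rdname RandomizationResult-class
#' @param effect effect id or label (default: all effects).
#' @export
setGeneric("pValues",
           function(x, effect = NULL) standardGeneric("pValues"))

#' @rdname RandomizationResult-class
#' @export
setGeneric("observedStrength",
           function(x, effect = NULL) standardGeneric("observedStrength"))

#' @rdname RandomizationResult-class
#' @export
setGeneric("nullDistribution",
           function(x, effect) standardGeneric("nullDistribution"))
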