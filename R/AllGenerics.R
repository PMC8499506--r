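#' Accessors for lactomics classes
#'
#' `participants()` and `diaries()` return the component tables of a
#' [LactationCohort-class]; `analyteClass()` and `lod()` return per-analyte
#' metadata of an [AnalyteExperiment-class]; `samplingProbs()` returns the
#' per-participant sampling probabilities of a case-control subset.
#'
#' @param object A lactomics object.
#' @return The corresponding component (`data.frame` or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))

#' @rdname accessors
#' @export
setGeneric("diaries", function(object) standardGeneric("diaries"))

#' @rdname accessors
#' @export
setGeneric("analyteClass", function(object) standardGeneric("analyteClass"))

#' @rdname accessors
#' @export
setGeneric("lod", function(object) standardGeneric("lod"))

#' @rdname accessors
#' @export
setGeneric("samplingProbs", function(object) standardGeneric("samplingProbs"))

#' @rdname accessors
#' @export
setMethod("participants", "LactationCohort", function(object)
  object@participants)

#' @rdname accessors
#' @export
setMethod("diaries", "LactationCohort", function(object) object@diaries)

#' @rdname accessors
#' @export
setMethod("analyteClass", "AnalyteExperiment", function(object)
  as.character(rowData(object)$class))

#' @rdname accessors
#' @export
setMethod("lod", "AnalyteExperiment", function(object)
  stats::setNames(as.numeric(rowData(object)$lod), rownames(object)))

#' @rdname accessors
#' @export
setMethod("samplingProbs", "LactationCohort", function(object)
  stats::setNames(object@participants$samplingProb, object@participants$id))
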