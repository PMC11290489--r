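#' @rdname SBAScreen-class
#' @param object,x an object.
#' @export
setGeneric("mfiTable", function(x) standardGeneric("mfiTable"))

#' @rdname SBAScreen-class
#' @export
setGeneric("antibodyPanel", function(x) standardGeneric("antibodyPanel"))

#' @rdname SBAScreen-class
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname SBAScreen-class
#' @export
setGeneric("schemeTable", function(x) standardGeneric("schemeTable"))

#' @rdname SBAScreen-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ScoreMatrix-class
#' @param x an object.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("scoreKind", function(x) standardGeneric("scoreKind"))

#' @rdname CallMatrix-class
#' @param x an object.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname ThresholdSet-class
#' @param x an object.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname SBAScreen-class
#' @export
setMethod("mfiTable", "SBAScreen", function(x) x@mfi)

#' @rdname SBAScreen-class
#' @export
setMethod("antibodyPanel", "SBAScreen", function(x) x@panel)

#' @rdname SBAScreen-class
#' @export
setMethod("sampleSheet", "SBAScreen", function(x) x@samples)

#' @rdname SBAScreen-class
#' @export
setMethod("schemeTable", "SBAScreen", function(x) x@schemes)

#' @rdname SBAScreen-class
#' @export
setMethod("groundTruth", "SBAScreen", function(x) x@truth)

#' @rdname ScoreMatrix-class
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' @rdname ScoreMatrix-class
#' @export
setMethod("scoreKind", "ScoreMatrix", function(x) x@scoreKind)

#' @rdname CallMatrix-class
#' @export
setMethod("calls", "CallMatrix", function(x) x@calls)

#' @rdname ThresholdSet-class
#' @export
setMethod("thresholds", "ThresholdSet", function(x) x@thresholds)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
    object@nGpcrs, "GPCRs x (mock +", length(object@ramps), "RAMPs)\n")
  cat("  interactProb:", object@interactProb,
    " logEffect:", object@logEffect,
    " noiseSd:", object@noiseSd, "\n")
  cat("  protein Abs per GPCR in [",
    object@nProteinAbsRange[1L], ",", object@nProteinAbsRange[2L],
    "]  bufferWells:", object@nBufferWells,
    "  seed:", object@seed, "\n")
})

setMethod("show", "SBAScreen", function(object) {
  ns <- sum(!object@samples$is_buffer &
    object@samples$gpcr_id != "mock")
  cat("SBAScreen with", nrow(object@mfi), "MFI records\n")
  cat("  samples:", nrow(object@samples),
    sprintf("(%d GPCR-containing, %d buffer)", ns,
      sum(object@samples$is_buffer)), "\n")
  cat("  panel:", nrow(object@panel), "antibodies;",
    "schemes:", nrow(object@schemes), "\n")
  if (nrow(object@truth)) {
    cat("  ground truth:", sum(object@truth$interacting), "of",
      nrow(object@truth), "pairs interacting\n")
  }
})

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix (", object@scoreKind, ") with ",
    nrow(object@scores), " scores over ",
    length(unique(object@scores$unit_id)), " unit(s)\n", sep = "")
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet:", nrow(object@thresholds), "unit threshold(s);",
    "endogenous cutoff", object@endogenous, "\n")
})

setMethod("show", "CallMatrix", function(object) {
  cat("CallMatrix:", nrow(object@calls), "calls,",
    sum(object@calls$hit), "hits\n")
})
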