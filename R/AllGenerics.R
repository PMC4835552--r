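#' @include AllClasses.R
NULL

#' @describeIn ReferenceTimecourse stage times in minutes AED.
#' @param x a package object.
#' @export
setGeneric("stageTimes", function(x) standardGeneric("stageTimes"))

#' @describeIn ReferenceTimecourse ordered stage labels.
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @describeIn RulerSet ordered ruler gene ids.
#' @param x a package object.
#' @export
setGeneric("rulerGenes", function(x) standardGeneric("rulerGenes"))

#' @describeIn RulerSet compilation parameters.
#' @export
setGeneric("rulerParams", function(x) standardGeneric("rulerParams"))

#' @describeIn GeneClasses named character vector of class labels.
#' @param x a package object.
#' @export
setGeneric("geneClassLabels", function(x) standardGeneric("geneClassLabels"))

#' @describeIn FoldChangeTable named numeric vector of log2 fold-changes.
#' @param x a package object.
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' Extract an estimated time difference in minutes
#'
#' @param x a [DeltaTimeEstimate-class] or [DecayFit-class].
#' @return signed time difference, minutes.
#' @export
setGeneric("deltaT", function(x) standardGeneric("deltaT"))

#' @describeIn StageEstimate interpolated time(s), minutes AED.
#' @param x a stage estimate or list thereof.
#' @export
setGeneric("interpTimes", function(x) standardGeneric("interpTimes"))

#' @describeIn StageEstimate best (discrete) stage label(s).
#' @export
setGeneric("bestStages", function(x) standardGeneric("bestStages"))

#' @describeIn StageEstimate per-stage similarity profile(s).
#' @export
setGeneric("similarityProfile", function(x) standardGeneric("similarityProfile"))

#' Summarize replicate stage estimates into one consensus estimate
#'
#' Replicates are estimated independently and summarized by the median:
#' the consensus `interpTime` is the median across samples, the consensus
#' similarity profile is the per-stage median, and the consensus best stage
#' is the argmax of that median profile (earliest stage on ties).
#'
#' @param x a [StageEstimateList-class].
#' @return A [StageEstimate-class].
#' @export
setGeneric("consensusEstimate", function(x) standardGeneric("consensusEstimate"))

#' Time difference between two staged conditions
#'
#' `deltaTime(a, b)` returns the signed developmental time difference
#' `interpTime(b) - interpTime(a)` in minutes; it is antisymmetric in its
#' arguments. Both estimates must have been made against the same reference.
#' Applied to a [DecayFit-class], it wraps the decay-regression offset.
#'
#' @param a,b [StageEstimate-class] or [StageEstimateList-class] objects
#'   (lists are reduced with [consensusEstimate()]), or a single
#'   [DecayFit-class].
#' @return A [DeltaTimeEstimate-class].
#' @export
setGeneric("deltaTime", function(a, b) standardGeneric("deltaTime"))

#' @describeIn ShiftSummary per-class summary table.
#' @param x a `ShiftSummary`.
#' @export
setGeneric("shiftTable", function(x) standardGeneric("shiftTable"))
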