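#' @include AllGenerics.R
NULL

#' @export
setMethod("stageTimes", "ReferenceTimecourse",
          function(x) setNames(colData(x)$time, colnames(x)))

#' @export
setMethod("stageLabels", "ReferenceTimecourse",
          function(x) as.character(colData(x)$stage))

#' @export
setMethod("rulerGenes", "RulerSet", function(x) x@genes)

#' @export
setMethod("rulerParams", "RulerSet", function(x) x@params)

#' @export
setMethod("geneClassLabels", "GeneClasses", function(x) x@labels)

#' @export
setMethod("foldChanges", "FoldChangeTable", function(x) x@log2fc)

#' @export
setMethod("deltaT", "DeltaTimeEstimate", function(x) x@deltaT)

#' @export
setMethod("deltaT", "DecayFit", function(x) x@deltaT)

#' @export
setMethod("interpTimes", "StageEstimate", function(x) x@interpTime)

#' @export
setMethod("interpTimes", "StageEstimateList",
          function(x) vapply(x, function(e) e@interpTime, numeric(1L)))

#' @export
setMethod("bestStages", "StageEstimate", function(x) x@bestStage)

#' @export
setMethod("bestStages", "StageEstimateList",
          function(x) vapply(x, function(e) e@bestStage, character(1L)))

#' @export
setMethod("similarityProfile", "StageEstimate", function(x) x@similarity)

#' @export
setMethod("similarityProfile", "StageEstimateList",
          function(x) do.call(rbind, lapply(x, function(e) e@similarity)))

#' @export
setMethod("consensusEstimate", "StageEstimateList", function(x) {
  if (length(x) == 0L) stop("empty StageEstimateList")
  if (length(x) == 1L) return(x[[1L]])
  sim <- apply(similarityProfile(x), 2L, median)
  mx <- max(sim)
  best <- names(sim)[which(sim >= mx - 1e-12)[1L]]
  new("StageEstimate", similarity = sim, bestStage = best,
      interpTime = median(interpTimes(x)), bootstrapSd = NA_real_,
      params = c(x[[1L]]@params, list(consensus = "median")),
      referenceId = x[[1L]]@referenceId)
})

#' @export
setMethod("shiftTable", "ShiftSummary", function(x) x@table)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ReferenceTimecourse", function(object) {
  callNextMethod()
  tm <- stageTimes(object)
  cat(sprintf("stage times (min AED): %s\n",
              paste(sprintf("%s=%g", names(tm), tm), collapse = ", ")))
})

setMethod("show", "GeneClasses", function(object) {
  tab <- table(factor(object@labels, levels = .GENE_CLASS_LEVELS))
  cat(sprintf("GeneClasses with %d genes (%s)\n", length(object@labels),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  if (nzchar(object@source)) cat("source:", object@source, "\n")
})

setMethod("show", "RulerSet", function(object) {
  cat(sprintf("RulerSet of %d monotonically decreasing maternal genes\n",
              length(object@genes)))
  p <- object@params
  if (length(p))
    cat("params:", paste(sprintf("%s=%s", names(p), unlist(p)), collapse = ", "), "\n")
})

setMethod("show", "StageEstimate", function(object) {
  cat(sprintf("StageEstimate: best stage '%s', interpolated time %.2f min AED\n",
              object@bestStage, object@interpTime))
  if (!is.na(object@bootstrapSd))
    cat(sprintf("bootstrap sd: %.2f min\n", object@bootstrapSd))
  cat("similarity:\n")
  print(round(object@similarity, 4L))
})

setMethod("show", "StageEstimateList", function(object) {
  cat(sprintf("StageEstimateList of %d sample(s)\n", length(object)))
  if (length(object)) {
    df <- data.frame(sample = names(object), bestStage = bestStages(object),
                     interpTime = round(interpTimes(object), 2L),
                     row.names = NULL)
    print(df)
  }
})

setMethod("show", "DeltaTimeEstimate", function(object) {
  cat(sprintf("DeltaTimeEstimate (%s): %.2f min (B minus A)\n",
              object@method, object@deltaT))
})

setMethod("show", "FoldChangeTable", function(object) {
  cat(sprintf("FoldChangeTable: %d genes, log2(%s vs %s), pseudocount %g\n",
              length(object@log2fc), object@conditions[2L],
              object@conditions[1L], object@pseudocount))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%s): %d maternal genes (%d excluded as induced)\n",
              object@fitMode, object@nGenes, object@nExcluded))
  if (!is.na(object@deltaT))
    cat(sprintf("estimated offset: %.2f min; residual sd %.3f log2\n",
                object@deltaT, object@residualSd))
  cat(sprintf("cor(extent of reduction, half-life): Spearman %.3f, Pearson %.3f%s\n",
              object@spearman, object@pearson,
              if (object@degenerate) " [degenerate: zero variance]" else ""))
})

setMethod("show", "ShiftSummary", function(object) {
  cat("Global maternal/zygotic shift summary\n")
  print(object@table)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d maternal + %d zygotic + %d stable genes\n",
    "half-life ~ 2^N(%.2f, %.2f) min; onset %g min (scale %g min)\n",
    "noise sd %.2f log2; %d reference stages (%g-%g min AED); seed %d\n"),
    object@nMaternal, object@nZygotic, object@nStable,
    object@halflifeLog2Mean, object@halflifeLog2Sd, object@onsetTime,
    object@activationScale, object@noiseDispersion,
    length(object@referenceTimes), min(object@referenceTimes),
    max(object@referenceTimes), object@seed))
})

setMethod("show", "SimTruth", function(object) {
  tab <- table(object@geneClass)
  cat(sprintf("SimTruth: %d genes (%s); onset %g min; seed %d\n",
              length(object@geneClass),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              object@onsetTime, object@seed))
  if (length(object@sampleTime))
    cat("sample times (min AED):",
        paste(sprintf("%s=%g", names(object@sampleTime), object@sampleTime),
              collapse = ", "), "\n")
})
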