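#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# ReferenceTimecourse
# ---------------------------------------------------------------------------

#' Reference developmental time-course
#'
#' A `ReferenceTimecourse` is a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose columns are ordered developmental stages (for *Drosophila*, nuclear
#' cycles c10...c14), each annotated with a time in minutes after egg
#' deposition (AED). Column metadata holds `stage` (label) and `time`
#' (minutes); stage times must be strictly increasing.
#'
#' @slot .Data inherits all `SummarizedExperiment` slots.
#' @export
setClass("ReferenceTimecourse", contains = "SummarizedExperiment")

setValidity("ReferenceTimecourse", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("stage", "time") %in% colnames(cd)))
    return("colData must contain 'stage' and 'time'")
  tm <- cd$time
  if (!is.numeric(tm) || anyNA(tm) || any(!is.finite(tm)))
    msg <- c(msg, "stage times must be finite numbers")
  else if (length(tm) > 1L && any(diff(tm) <= 0))
    msg <- c(msg, "stage times must be strictly increasing")
  if (!identical(as.character(cd$stage), colnames(object)))
    msg <- c(msg, "stage labels must equal column names, in order")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated stage labels")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene ids")
  v <- assay(object, 1L)
  if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "negative expression values")
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "need at least one gene and one stage")
  if (length(msg)) msg else TRUE
})

#' Construct a reference time-course
#'
#' @param values non-negative gene x stage matrix (genes as rownames).
#' @param stageLabels ordered stage names, one per column.
#' @param stageTimes strictly increasing stage times, minutes AED.
#' @param unit unit tag for the values (`"rpkm"`, `"abundance"` or `"counts"`).
#' @return A [ReferenceTimecourse-class] object.
#' @examples
#' m <- matrix(c(8, 4, 2, 1, 2, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("mat1", "zyg1"), NULL))
#' ref <- ReferenceTimecourse(m, c("c11", "c12", "c13"), c(80, 95, 105))
#' stageTimes(ref)
#' @export
ReferenceTimecourse <- function(values, stageLabels = colnames(values),
                                stageTimes, unit = "abundance") {
  values <- .exprValues(values, "values")
  if (is.null(stageLabels)) stop("'stageLabels' required when 'values' has no colnames")
  stageLabels <- as.character(stageLabels)
  if (length(stageLabels) != ncol(values) || length(stageTimes) != ncol(values))
    stop("'stageLabels' and 'stageTimes' must have one entry per column")
  colnames(values) <- stageLabels
  se <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(stage = stageLabels, time = as.numeric(stageTimes),
                        row.names = stageLabels))
  metadata(se)$unit <- match.arg(unit, c("abundance", "rpkm", "counts"))
  new("ReferenceTimecourse", se)
}

# ---------------------------------------------------------------------------
# GeneClasses
# ---------------------------------------------------------------------------

.GENE_CLASS_LEVELS <- c("maternal", "zygotic", "stable", "unclassified")

#' Gene class assignments
#'
#' Maps gene ids to one of `"maternal"`, `"zygotic"`, `"stable"` or
#' `"unclassified"`. Maternal transcripts are deposited in the egg and decay;
#' zygotic transcripts are newly transcribed around the MZT.
#'
#' @slot labels named character vector of class labels.
#' @slot source free-text provenance (e.g. which published list).
#' @slot params parameters used when classes were derived from data.
#' @export
setClass("GeneClasses",
         representation(labels = "character", source = "character",
                        params = "list"),
         prototype(source = "", params = list()))

setValidity("GeneClasses", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || any(!nzchar(names(object@labels))))
    msg <- c(msg, "all labels must be named by gene id")
  if (anyDuplicated(names(object@labels)))
    msg <- c(msg, "each gene may appear at most once")
  bad <- setdiff(unique(object@labels), .GENE_CLASS_LEVELS)
  if (length(bad))
    msg <- c(msg, paste0("invalid class label(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct gene class assignments
#'
#' @param maternal,zygotic,stable,unclassified character vectors of gene ids.
#' @param source free-text provenance tag.
#' @param params optional list of derivation parameters.
#' @return A [GeneClasses-class] object.
#' @examples
#' geneClasses(maternal = c("bcd", "nos"), zygotic = "ftz")
#' @export
geneClasses <- function(maternal = character(), zygotic = character(),
                        stable = character(), unclassified = character(),
                        source = "", params = list()) {
  lists <- list(maternal = maternal, zygotic = zygotic, stable = stable,
                unclassified = unclassified)
  for (i in seq_along(lists)) for (j in seq_len(i - 1L)) {
    ov <- intersect(lists[[i]], lists[[j]])
    if (length(ov))
      stop(sprintf("gene(s) assigned to both '%s' and '%s': %s",
                   names(lists)[j], names(lists)[i],
                   paste(head(ov, 5L), collapse = ", ")))
  }
  labels <- unlist(lapply(names(lists), function(nm)
    setNames(rep(nm, length(lists[[nm]])), lists[[nm]])))
  if (is.null(labels)) labels <- setNames(character(), character())
  new("GeneClasses", labels = labels, source = source, params = params)
}

# ---------------------------------------------------------------------------
# RulerSet
# ---------------------------------------------------------------------------

#' Ruler gene set
#'
#' The compiled set of maternal genes decreasing monotonically across the
#' reference time-course, ordered by descending first-stage expression. Ruler
#' genes anchor stage estimation: their relative decay acts as a molecular
#' clock.
#'
#' @slot genes ordered character vector of gene ids.
#' @slot params compilation parameters, recorded verbatim.
#' @slot provenance reference identifier the ruler was compiled against.
#' @export
setClass("RulerSet",
         representation(genes = "character", params = "list",
                        provenance = "character"),
         prototype(params = list(), provenance = ""))

setValidity("RulerSet", function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "ruler set must be non-empty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated ruler genes")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# StageEstimate / StageEstimateList / DeltaTimeEstimate
# ---------------------------------------------------------------------------

#' Stage estimate for a query transcriptome
#'
#' Per-stage similarity profile, best (discrete) stage, interpolated
#' continuous developmental time and optional bootstrap uncertainty.
#'
#' @slot similarity named numeric, one similarity per reference stage.
#' @slot bestStage label of the stage attaining maximal similarity
#'   (earliest stage on ties).
#' @slot interpTime interpolated time, minutes AED, within the reference span.
#' @slot bootstrapSd bootstrap standard deviation of `interpTime` (NA until
#'   [bootstrapStage()] is run).
#' @slot params method parameters used.
#' @slot referenceId fingerprint of the reference mapped against.
#' @export
setClass("StageEstimate",
         representation(similarity = "numeric", bestStage = "character",
                        interpTime = "numeric", bootstrapSd = "numeric",
                        params = "list", referenceId = "character"),
         prototype(bootstrapSd = NA_real_, params = list(), referenceId = ""))

setValidity("StageEstimate", function(object) {
  msg <- character()
  if (is.null(names(object@similarity)))
    msg <- c(msg, "similarity vector must be named by stage")
  if (length(object@bestStage) != 1L)
    msg <- c(msg, "bestStage must be a single label")
  else if (!object@bestStage %in% names(object@similarity))
    msg <- c(msg, "bestStage must be one of the reference stages")
  else {
    mx <- max(object@similarity)
    if (object@similarity[[object@bestStage]] < mx - 1e-9)
      msg <- c(msg, "bestStage must attain the maximal similarity")
  }
  if (length(object@interpTime) != 1L || !is.finite(object@interpTime))
    msg <- c(msg, "interpTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' List of per-sample stage estimates
#'
#' Returned by [estimateStage()]: one [StageEstimate-class] per query sample.
#' @export
setClass("StageEstimateList", contains = "list")

setValidity("StageEstimateList", function(object) {
  if (!all(vapply(object@.Data, is, logical(1L), "StageEstimate")))
    return("all elements must be StageEstimate objects")
  TRUE
})

#' Developmental time difference between two conditions
#'
#' @slot deltaT signed time difference in minutes (condition B minus A).
#' @slot method `"stage-mapping"` or `"decay-regression"`.
#' @slot components the two [StageEstimate-class]s, or the [DecayFit-class].
#' @export
setClass("DeltaTimeEstimate",
         representation(deltaT = "numeric", method = "character",
                        components = "list"))

setValidity("DeltaTimeEstimate", function(object) {
  msg <- character()
  if (length(object@deltaT) != 1L || !is.finite(object@deltaT))
    msg <- c(msg, "deltaT must be a single finite number")
  if (!object@method %in% c("stage-mapping", "decay-regression"))
    msg <- c(msg, "method must be 'stage-mapping' or 'decay-regression'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# FoldChangeTable / DecayFit / ShiftSummary
# ---------------------------------------------------------------------------

#' Per-gene log2 fold-changes between two conditions
#'
#' @slot log2fc named numeric vector of log2 fold-changes (B vs A).
#' @slot pseudocount pseudocount used (abundance units).
#' @slot conditions labels of conditions A and B.
#' @export
setClass("FoldChangeTable",
         representation(log2fc = "numeric", pseudocount = "numeric",
                        conditions = "character"))

setValidity("FoldChangeTable", function(object) {
  msg <- character()
  if (is.null(names(object@log2fc))) msg <- c(msg, "fold-changes must be named")
  if (any(!is.finite(object@log2fc))) msg <- c(msg, "fold-changes must be finite")
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single value > 0")
  if (length(object@conditions) != 2L)
    msg <- c(msg, "conditions must be two labels")
  if (length(msg)) msg else TRUE
})

#' Decay-clock fit
#'
#' Output of [halfLifeCorrelation()] / [estimateDeltaTimeDecay()]: the
#' correlation between the extent of maternal-transcript reduction and
#' half-life, and the developmental offset implied by first-order decay.
#'
#' @slot deltaT estimated offset in minutes (NA when only correlations were
#'   computed).
#' @slot spearman,pearson correlation between extent of reduction (-log2FC)
#'   and half-life over maternal genes.
#' @slot nGenes number of maternal genes used.
#' @slot nExcluded genes excluded as apparently induced.
#' @slot residualSd residual standard deviation, log2 units.
#' @slot intercept fitted intercept (0 for through-origin fits).
#' @slot fitMode `"through-origin"` or `"free-intercept"`.
#' @slot degenerate TRUE when correlations are undefined (zero variance) and
#'   reported as 0 by convention.
#' @export
setClass("DecayFit",
         representation(deltaT = "numeric", spearman = "numeric",
                        pearson = "numeric", nGenes = "integer",
                        nExcluded = "integer", residualSd = "numeric",
                        intercept = "numeric", fitMode = "character",
                        degenerate = "logical"),
         prototype(deltaT = NA_real_, nExcluded = 0L, residualSd = NA_real_,
                   intercept = 0, fitMode = "through-origin",
                   degenerate = FALSE))

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@nGenes < 3L) msg <- c(msg, "nGenes must be >= 3")
  ok <- function(x) length(x) == 1L && (is.na(x) || (x >= -1 && x <= 1))
  if (!ok(object@spearman) || !ok(object@pearson))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!object@fitMode %in% c("through-origin", "free-intercept"))
    msg <- c(msg, "fitMode must be 'through-origin' or 'free-intercept'")
  if (length(msg)) msg else TRUE
})

#' Global maternal/zygotic shift summary
#'
#' Per-class medians, fractions of genes moving down/up, and exact two-sided
#' sign-test p-values for the global shift between two conditions.
#'
#' @slot table data.frame with one row per gene class.
#' @export
setClass("ShiftSummary", representation(table = "data.frame"))

# ---------------------------------------------------------------------------
# SimulationConfig / SimTruth
# ---------------------------------------------------------------------------

#' Configuration of the synthetic MZT simulator
#'
#' Defines the generative model: maternal transcripts decay exponentially
#' from gene-specific baselines with log-normally distributed half-lives;
#' zygotic transcripts activate logistically around an onset time; stable
#' (housekeeping) genes are flat. Observation noise is multiplicative
#' log-normal. See [simulationConfig()] for defaults and units.
#'
#' @slot nMaternal,nZygotic,nStable gene counts per class.
#' @slot halflifeLog2Mean,halflifeLog2Sd mean/sd of log2(half-life, minutes).
#' @slot onsetTime zygotic activation midpoint, minutes AED.
#' @slot activationScale logistic time scale of activation, minutes.
#' @slot baselineLog2Mean,baselineLog2Sd mean/sd of log2 baseline abundance.
#' @slot noiseDispersion sd of log2 multiplicative observation noise.
#' @slot referenceTimes ordered reference stage times, minutes AED.
#' @slot stageLabels stage names, one per reference time.
#' @slot seed integer seed fixing the realized gene table.
#' @export
setClass("SimulationConfig",
         representation(nMaternal = "integer", nZygotic = "integer",
                        nStable = "integer", halflifeLog2Mean = "numeric",
                        halflifeLog2Sd = "numeric", onsetTime = "numeric",
                        activationScale = "numeric",
                        baselineLog2Mean = "numeric",
                        baselineLog2Sd = "numeric",
                        noiseDispersion = "numeric",
                        referenceTimes = "numeric", stageLabels = "character",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nMaternal < 1L || object@nZygotic < 1L || object@nStable < 1L)
    msg <- c(msg, "all gene counts must be > 0")
  if (object@activationScale <= 0) msg <- c(msg, "activationScale must be > 0")
  if (object@onsetTime < 0) msg <- c(msg, "onsetTime must be >= 0")
  if (object@halflifeLog2Sd < 0 || object@baselineLog2Sd < 0)
    msg <- c(msg, "log2 sds must be >= 0")
  if (object@noiseDispersion < 0) msg <- c(msg, "noiseDispersion must be >= 0")
  if (length(object@referenceTimes) < 2L ||
      any(diff(object@referenceTimes) <= 0) ||
      any(object@referenceTimes < 0))
    msg <- c(msg, "referenceTimes must be >= 0 and strictly increasing")
  if (length(object@stageLabels) != length(object@referenceTimes))
    msg <- c(msg, "one stage label per reference time required")
  if (anyDuplicated(object@stageLabels)) msg <- c(msg, "duplicated stage labels")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulation
#'
#' @slot sampleTime named numeric: true time (minutes AED) per sample.
#' @slot geneClass named character: true class per gene.
#' @slot halfLife named numeric: true half-life (minutes) per maternal gene.
#' @slot effectLog2 named numeric: planted log2 condition effects (may be empty).
#' @slot onsetTime true zygotic onset, minutes AED.
#' @slot seed seed used for the realization.
#' @export
setClass("SimTruth",
         representation(sampleTime = "numeric", geneClass = "character",
                        halfLife = "numeric", effectLog2 = "numeric",
                        onsetTime = "numeric", seed = "integer"),
         prototype(effectLog2 = setNames(numeric(), character())))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@geneClass) &&
      !all(object@geneClass %in% c("maternal", "zygotic", "stable")))
    msg <- c(msg, "gene classes must be maternal/zygotic/stable")
  mat <- names(object@geneClass)[object@geneClass == "maternal"]
  hl <- object@halfLife[mat]
  if (length(mat) && (anyNA(hl) || any(!is.finite(hl)) || any(hl <= 0)))
    msg <- c(msg, "every maternal gene needs a finite positive half-life")
  if (length(msg)) msg else TRUE
})
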