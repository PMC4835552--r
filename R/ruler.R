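#' @include AllClasses.R
NULL

#' Compile the ruler gene set
#'
#' Selects the "ruler": maternal genes decreasing monotonically across the
#' reference time-course, the molecular clock used to anchor stage
#' estimation. A gene `g` enters the ruler iff all of:
#'
#' 1. `class(g) == "maternal"`;
#' 2. first-stage expression `>= minFirstStageExpr`;
#' 3. for every consecutive stage pair,
#'    `expr(i+1) <= expr(i) * (1 + monotoneTolerance)` (small upward jitter
#'    tolerated);
#' 4. total decline `expr(first) / expr(last) >= minTotalDecline`.
#'
#' Output order is descending first-stage expression. The parameters are
#' recorded verbatim on the result.
#'
#' @param reference a [ReferenceTimecourse-class] with at least 3 stages.
#' @param classes a [GeneClasses-class] covering the reference genes
#'   (genes without a class are treated as unclassified and excluded).
#' @param minFirstStageExpr minimum first-stage abundance.
#' @param monotoneTolerance allowed fractional upward jitter between
#'   adjacent stages (0 = strict monotone decrease).
#' @param minTotalDecline minimum first/last fold decline.
#' @return A [RulerSet-class].
#' @examples
#' sim <- simulateReference(simulationConfig(nMaternal = 30, nZygotic = 5,
#'                                           nStable = 5, seed = 2))
#' compileRuler(sim$reference, trueClasses(sim$truth))
#' @export
compileRuler <- function(reference, classes,
                         minFirstStageExpr = 1, monotoneTolerance = 0.05,
                         minTotalDecline = 2) {
  stopifnot(is(reference, "ReferenceTimecourse"), is(classes, "GeneClasses"))
  if (ncol(reference) < 3L) stop("reference needs at least 3 stages")
  .checkScalarNumber(minFirstStageExpr, "minFirstStageExpr", nonneg = TRUE)
  .checkScalarNumber(monotoneTolerance, "monotoneTolerance", nonneg = TRUE)
  .checkScalarNumber(minTotalDecline, "minTotalDecline", positive = TRUE)

  vals <- assay(reference, 1L)
  cl <- geneClassLabels(classes)
  isMaternal <- rownames(vals) %in% names(cl)[cl == "maternal"]
  first <- vals[, 1L]
  last <- vals[, ncol(vals)]
  monotone <- rep(TRUE, nrow(vals))
  for (j in seq_len(ncol(vals) - 1L))
    monotone <- monotone & (vals[, j + 1L] <= vals[, j] * (1 + monotoneTolerance))
  decline <- ifelse(last > 0, first / last, Inf)
  decline[first == 0 & last == 0] <- 1
  keep <- isMaternal & first >= minFirstStageExpr & monotone &
    decline >= minTotalDecline
  genes <- rownames(vals)[keep]
  if (length(genes) == 0L)
    stop("no gene passed the ruler filters; consider relaxing ",
         "'minFirstStageExpr', 'monotoneTolerance' or 'minTotalDecline'")
  genes <- genes[order(first[genes], decreasing = TRUE)]
  new("RulerSet", genes = genes,
      params = list(min_first_stage_expr = minFirstStageExpr,
                    monotone_tolerance = monotoneTolerance,
                    min_total_decline = minTotalDecline),
      provenance = .referenceId(reference))
}

#' Per-gene ruler diagnostics
#'
#' One row per ruler gene, in ruler order: first- and last-stage expression,
#' total decline fold, and the monotonicity margin (the largest fractional
#' upward step between adjacent stages; `<= monotoneTolerance` by
#' construction).
#'
#' @param ruler a [RulerSet-class].
#' @param reference the [ReferenceTimecourse-class] the ruler was compiled
#'   against; every ruler gene must be present.
#' @return data.frame with columns `gene`, `firstExpr`, `lastExpr`,
#'   `declineFold`, `monotonicityMargin`.
#' @export
rulerReport <- function(ruler, reference) {
  stopifnot(is(ruler, "RulerSet"), is(reference, "ReferenceTimecourse"))
  genes <- rulerGenes(ruler)
  missing <- setdiff(genes, rownames(reference))
  if (length(missing))
    stop("ruler gene(s) missing from reference: ",
         paste(head(missing, 5L), collapse = ", "))
  vals <- assay(reference, 1L)[genes, , drop = FALSE]
  steps <- vals[, -1L, drop = FALSE] / vals[, -ncol(vals), drop = FALSE]
  steps[!is.finite(steps)] <- 1
  data.frame(gene = genes,
             firstExpr = unname(vals[, 1L]),
             lastExpr = unname(vals[, ncol(vals)]),
             declineFold = unname(vals[, 1L] / vals[, ncol(vals)]),
             monotonicityMargin = unname(apply(steps, 1L, max) - 1),
             row.names = NULL)
}

#' Read / write a ruler gene set
#'
#' Gene-list file whose `#` header records the compilation parameters
#' (machine-parseable `# key=value` lines).
#'
#' @param ruler a [RulerSet-class].
#' @param path file path.
#' @return `readRuler` returns a [RulerSet-class].
#' @export
writeRuler <- function(ruler, path) {
  stopifnot(is(ruler, "RulerSet"))
  p <- ruler@params
  comments <- c(sprintf("%s=%.10g", names(p), unlist(p)),
                sprintf("provenance=%s", ruler@provenance))
  writeGeneList(rulerGenes(ruler), path, comments = comments)
}

#' @rdname writeRuler
#' @export
readRuler <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- trimws(sub("^#", "", lines[startsWith(lines, "#")]))
  kv <- strsplit(hdr[grepl("=", hdr)], "=", fixed = TRUE)
  params <- list(); provenance <- ""
  for (p in kv) {
    key <- trimws(p[[1L]])
    val <- trimws(paste(p[-1L], collapse = "="))
    if (key == "provenance") provenance <- val
    else params[[key]] <- suppressWarnings(as.numeric(val))
  }
  new("RulerSet", genes = readGeneList(path), params = params,
      provenance = provenance)
}
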