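#' @include AllClasses.R
NULL

#' Derive maternal/zygotic gene classes from a reference time-course
#'
#' A stand-in for published class lists when none are supplied: a gene is
#' called maternal when it is expressed at the first stage
#' (`>= exprThreshold`) and declines at least `foldThreshold`-fold by the
#' last stage; zygotic when it starts below `exprThreshold` and rises at
#' least `foldThreshold`-fold; otherwise unclassified.
#'
#' @param reference a [ReferenceTimecourse-class] with `>= 3` stages.
#' @param exprThreshold first-stage expression threshold (abundance units).
#' @param foldThreshold minimum fold decline/rise.
#' @param pseudocount stabilizes the fold ratios near zero.
#' @return A [GeneClasses-class] with the parameters recorded.
#' @export
deriveGeneClasses <- function(reference, exprThreshold = 1,
                              foldThreshold = 2, pseudocount = 0.5) {
  stopifnot(is(reference, "ReferenceTimecourse"))
  if (ncol(reference) < 3L) stop("reference needs at least 3 stages")
  if (foldThreshold <= 1 || exprThreshold <= 0)
    warning("degenerate thresholds: every expressed gene will be classified")
  vals <- assay(reference, 1L)
  first <- vals[, 1L]; last <- vals[, ncol(vals)]
  decline <- (first + pseudocount) / (last + pseudocount)
  rise <- (last + pseudocount) / (first + pseudocount)
  maternal <- first >= exprThreshold & decline >= foldThreshold
  zygotic <- !maternal & first < exprThreshold & rise >= foldThreshold
  labels <- ifelse(maternal, "maternal",
                   ifelse(zygotic, "zygotic", "unclassified"))
  geneClasses(maternal = rownames(vals)[labels == "maternal"],
              zygotic = rownames(vals)[labels == "zygotic"],
              unclassified = rownames(vals)[labels == "unclassified"],
              source = "derived from reference time-course",
              params = list(exprThreshold = exprThreshold,
                            foldThreshold = foldThreshold,
                            pseudocount = pseudocount))
}

# Exact two-sided sign test on the non-zero fold-changes.
.signTest <- function(fc) {
  nz <- fc[fc != 0]
  if (length(nz) == 0L) return(NA_real_)
  binom.test(sum(nz < 0), length(nz), p = 0.5,
             alternative = "two.sided")$p.value
}

#' Global maternal/zygotic shift summary
#'
#' Summarizes the global signature of a developmental shift between two
#' conditions: per gene class (maternal, zygotic), the median log2
#' fold-change, the fractions of genes strictly decreased/increased, and an
#' exact two-sided sign-test p-value for a systematic shift. Zero
#' fold-changes are dropped from the sign test and counted separately. A
#' class absent from the data yields a flagged row of NAs.
#'
#' @param fc a [FoldChangeTable-class] (condition B vs A).
#' @param classes a [GeneClasses-class].
#' @return A [ShiftSummary-class]; see [shiftTable()].
#' @examples
#' fc <- new("FoldChangeTable",
#'           log2fc = c(m1 = -1, m2 = -1, m3 = 1, z1 = 2),
#'           pseudocount = 0.5, conditions = c("ctrl", "treat"))
#' cls <- geneClasses(maternal = c("m1", "m2", "m3"), zygotic = "z1")
#' shiftTable(globalShift(fc, cls))
#' @export
globalShift <- function(fc, classes) {
  stopifnot(is(fc, "FoldChangeTable"), is(classes, "GeneClasses"))
  cl <- geneClassLabels(classes)
  vals <- foldChanges(fc)
  anyClassified <- FALSE
  rows <- lapply(c("maternal", "zygotic"), function(label) {
    genes <- intersect(names(vals), names(cl)[cl == label])
    if (length(genes) == 0L) {
      return(data.frame(class = label, n = 0L, nZero = NA_integer_,
                        medianLog2FC = NA_real_, fracDecreased = NA_real_,
                        fracIncreased = NA_real_, pSign = NA_real_,
                        degenerate = NA, absent = TRUE))
    }
    anyClassified <<- TRUE
    v <- vals[genes]
    p <- .signTest(v)
    data.frame(class = label, n = length(genes), nZero = sum(v == 0),
               medianLog2FC = median(v), fracDecreased = mean(v < 0),
               fracIncreased = mean(v > 0), pSign = p,
               degenerate = is.na(p), absent = FALSE)
  })
  if (!anyClassified) stop("no classified gene with a fold-change")
  new("ShiftSummary", table = do.call(rbind, rows))
}

#' Residual fold-changes against a stage-matched profile
#'
#' Computes per-gene `log2((query mean + pc) / (matched + pc))` between a
#' query transcriptome and the stage-matched reference profile at the
#' query's estimated stage (see [stageMatchedProfile()]). Comparing against
#' the stage-matched profile rather than the raw control separates
#' condition-specific effects from staging effects: on a timing-only
#' difference the residuals carry no maternal-down / zygotic-up signature.
#'
#' @param query gene x sample matrix or `SummarizedExperiment` (replicate
#'   means are taken first); normalize with [normalizeToReference()] before
#'   calling.
#' @param matched stage-matched profile: named numeric vector from
#'   [stageMatchedProfile()] (or a one-column matrix).
#' @param pseudocount added to both sides before the ratio.
#' @return A [FoldChangeTable-class] with conditions
#'   `("stage-matched", "query")`.
#' @export
residualFoldChanges <- function(query, matched, pseudocount = 0.5) {
  m <- .exprValues(matched, "matched")
  if (ncol(m) != 1L) stop("'matched' must be a single profile")
  log2FoldChanges(m, query, pseudocount = pseudocount,
                  conditions = c("stage-matched", "query"))
}
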