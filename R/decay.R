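#' @include AllClasses.R
NULL

#' Per-gene log2 fold-changes between two conditions
#'
#' Replicate means are computed first, then
#' `log2((mean_B + pc) / (mean_A + pc))` per gene over the shared gene set.
#'
#' @param A,B gene x sample matrices or `SummarizedExperiment`s (condition A
#'   = baseline, condition B = comparison).
#' @param pseudocount added to both means before the ratio (`> 0`).
#' @param conditions labels for A and B.
#' @return A [FoldChangeTable-class] (genes in the order of `A`).
#' @examples
#' a <- matrix(c(8, 2), 2, dimnames = list(c("g1", "g2"), "s1"))
#' foldChanges(log2FoldChanges(a, a * c(2, 1), pseudocount = 1e-6))
#' @export
log2FoldChanges <- function(A, B, pseudocount = 0.5,
                            conditions = c("A", "B")) {
  .checkScalarNumber(pseudocount, "pseudocount", positive = TRUE)
  mA <- .exprValues(A, "A"); mB <- .exprValues(B, "B")
  shared <- intersect(rownames(mA), rownames(mB))
  if (length(shared) == 0L) stop("empty gene intersection between A and B")
  fc <- log2((rowMeans(mB[shared, , drop = FALSE]) + pseudocount) /
             (rowMeans(mA[shared, , drop = FALSE]) + pseudocount))
  new("FoldChangeTable", log2fc = fc, pseudocount = pseudocount,
      conditions = as.character(conditions))
}

# Maternal genes carrying both a fold-change and a half-life.
.maternalDecayGenes <- function(fc, halfLives, classes) {
  cl <- geneClassLabels(classes)
  maternal <- names(cl)[cl == "maternal"]
  genes <- intersect(intersect(names(foldChanges(fc)), names(halfLives)),
                     maternal)
  if (any(!is.finite(halfLives[genes]) | halfLives[genes] <= 0))
    stop("half-lives must be finite and > 0")
  genes
}

#' Correlation between extent of maternal reduction and half-life
#'
#' Under first-order decay with no new synthesis, a transcript's log2
#' fold-change between two times is `-dt / t1/2`: short-lived transcripts
#' drop most. The "extent of reduction" is `-log2FC`; when condition B is
#' developmentally older its correlation with half-life is negative. Both
#' Spearman and Pearson coefficients are reported, restricted to maternal
#' genes. When either variable has zero variance (e.g. `dt = 0`, all
#' extents zero) the correlations are reported as 0 with the `degenerate`
#' flag set.
#'
#' @param fc a [FoldChangeTable-class] (B vs A).
#' @param halfLives named numeric of half-lives in minutes (see
#'   [readHalfLives()]).
#' @param classes a [GeneClasses-class]; only maternal genes are used.
#' @return A [DecayFit-class] with the correlation slots populated
#'   (`deltaT` is `NA`).
#' @export
halfLifeCorrelation <- function(fc, halfLives, classes) {
  stopifnot(is(fc, "FoldChangeTable"), is(classes, "GeneClasses"))
  genes <- .maternalDecayGenes(fc, halfLives, classes)
  if (length(genes) < 3L)
    stop("need >= 3 maternal genes with both a fold-change and a half-life")
  extent <- -foldChanges(fc)[genes]
  hl <- halfLives[genes]
  degenerate <- sd(extent) == 0 || sd(hl) == 0
  new("DecayFit",
      deltaT = NA_real_,
      spearman = if (degenerate) 0 else cor(extent, hl, method = "spearman"),
      pearson = if (degenerate) 0 else cor(extent, hl),
      nGenes = length(genes), nExcluded = 0L, residualSd = NA_real_,
      intercept = NA_real_, fitMode = "through-origin",
      degenerate = degenerate)
}

# Repeated-medians slope (Siegel): robust to a minority of outliers.
.repeatedMediansSlope <- function(x, y) {
  n <- length(x)
  med_i <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    ok <- dx != 0
    median((y[-i][ok] - y[i]) / dx[ok])
  }, numeric(1L))
  median(med_i)
}

#' Decay-clock estimate of the developmental offset
#'
#' Formalizes the half-life relation as an estimator: under first-order
#' decay, `log2FC_g = -dt / t1/2_g`, so regressing the per-gene log2
#' fold-change on `x_g = 1 / t1/2_g` gives a slope of `-dt`. The default fit
#' is through the origin (the decay law forces FC = 0 at dt = 0); the
#' free-intercept mode absorbs a global normalization offset on real data.
#' Genes with `log2FC > inductionThreshold` violate the decay-only
#' assumption (apparent zygotic re-expression) and are excluded and counted.
#'
#' @inheritParams halfLifeCorrelation
#' @param fitMode `"through-origin"` (default) or `"free-intercept"`.
#' @param robust use the repeated-medians slope (through-origin: median of
#'   per-gene slopes) instead of least squares.
#' @param inductionThreshold exclusion threshold in log2 units (default
#'   `+0.5`).
#' @return A [DecayFit-class] with `deltaT`, correlations, gene counts and
#'   residual sd populated.
#' @examples
#' cfg <- simulationConfig(nMaternal = 30, nZygotic = 5, nStable = 5,
#'                         seed = 6)
#' simA <- simulateQuery(cfg, 95, seed = 1, noiseDispersion = 0)
#' simB <- simulateQuery(cfg, 130, seed = 2, noiseDispersion = 0)
#' fc <- log2FoldChanges(simA$query, simB$query, pseudocount = 1e-9)
#' fit <- estimateDeltaTimeDecay(fc, trueHalfLives(simA$truth),
#'                               trueClasses(simA$truth))
#' deltaT(fit)  # 35 minutes
#' @export
estimateDeltaTimeDecay <- function(fc, halfLives, classes,
                                   fitMode = c("through-origin",
                                               "free-intercept"),
                                   robust = FALSE,
                                   inductionThreshold = 0.5) {
  fitMode <- match.arg(fitMode)
  stopifnot(is(fc, "FoldChangeTable"), is(classes, "GeneClasses"))
  genes <- .maternalDecayGenes(fc, halfLives, classes)
  if (length(genes) < 3L)
    stop("need >= 3 maternal genes with both a fold-change and a half-life")
  y <- foldChanges(fc)[genes]
  induced <- y > inductionThreshold
  nExcluded <- sum(induced)
  genes <- genes[!induced]
  if (length(genes) < 3L)
    stop(sprintf("only %d gene(s) left after excluding %d apparently induced gene(s)",
                 length(genes), nExcluded))
  y <- y[genes]
  x <- 1 / halfLives[genes]

  if (fitMode == "through-origin") {
    slope <- if (robust) median(y / x) else sum(x * y) / sum(x * x)
    intercept <- 0
  } else if (robust) {
    slope <- .repeatedMediansSlope(x, y)
    intercept <- median(y - slope * x)
  } else {
    co <- coef(lm(y ~ x))
    intercept <- unname(co[1L]); slope <- unname(co[2L])
  }
  resid <- y - intercept - slope * x
  extent <- -y
  hl <- halfLives[genes]
  degenerate <- sd(extent) == 0 || sd(hl) == 0
  new("DecayFit",
      deltaT = -slope,
      spearman = if (degenerate) 0 else cor(extent, hl, method = "spearman"),
      pearson = if (degenerate) 0 else cor(extent, hl),
      nGenes = length(genes), nExcluded = as.integer(nExcluded),
      residualSd = if (length(genes) > 1L) sd(resid) else 0,
      intercept = intercept, fitMode = fitMode, degenerate = degenerate)
}
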