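#' @include AllClasses.R AllGenerics.R
NULL

# log2(+pseudocount) values of the reference restricted to ruler genes,
# optionally on a fine time grid (geometric interpolation between stages,
# which is exact for first-order decay).
.rulerGrid <- function(reference, genes, times, pseudocount) {
  vals <- assay(reference, 1L)[genes, , drop = FALSE]
  st <- unname(stageTimes(reference))
  .log2p(.geomInterp(vals, st, times), pseudocount)
}

.similarityVector <- function(qlog, reflog, metric, band) {
  if (metric == "spearman") {
    if (sd(qlog) == 0)
      stop("constant query profile over ruler genes: rank similarity undefined")
    as.vector(cor(qlog, reflog, method = "spearman"))
  } else {
    colMeans(abs(reflog - qlog) <= log2(band))
  }
}

#' Similarity of a query profile to each reference stage
#'
#' The default metric is the Spearman rank correlation between
#' `log2(x + pseudocount)` query and reference-stage profiles restricted to
#' the ruler genes (scale-free, robust to normalization residue). The
#' `"overlap"` metric is the fraction of ruler genes whose query/reference
#' ratio lies within a `band`-fold band; it requires a normalized query
#' (see [normalizeToReference()]).
#'
#' @param query a single query profile: named numeric vector, one-column
#'   matrix or one-sample `SummarizedExperiment`.
#' @param reference a [ReferenceTimecourse-class].
#' @param ruler a [RulerSet-class] (or character vector of gene ids).
#' @param metric `"spearman"` (default) or `"overlap"`.
#' @param pseudocount added before the log2 transform (abundance units).
#' @param band fold-band half-width for the overlap metric.
#' @return named numeric vector, one similarity per reference stage
#'   (in `[-1, 1]` for Spearman, `[0, 1]` for overlap).
#' @export
stageSimilarity <- function(query, reference, ruler,
                            metric = c("spearman", "overlap"),
                            pseudocount = 0.5, band = 2) {
  metric <- match.arg(metric)
  stopifnot(is(reference, "ReferenceTimecourse"))
  genes <- if (is(ruler, "RulerSet")) rulerGenes(ruler) else as.character(ruler)
  if (length(genes) == 0L) stop("empty ruler")
  q <- .exprValues(query, "query")
  if (ncol(q) != 1L) stop("'query' must be a single profile; see estimateStage()")
  missing <- setdiff(genes, rownames(q))
  missingRef <- setdiff(genes, rownames(reference))
  if (length(missing) || length(missingRef))
    stop("ruler gene(s) missing from query or reference: ",
         paste(head(c(missing, missingRef), 5L), collapse = ", "))
  qlog <- .log2p(q[genes, 1L], pseudocount)
  reflog <- .log2p(assay(reference, 1L)[genes, , drop = FALSE], pseudocount)
  sims <- .similarityVector(qlog, reflog, metric, band)
  setNames(sims, stageLabels(reference))
}

# Interpolated time for one profile. Returns list(similarity, best, time).
.estimateOne <- function(qvec, reference, genes, metric, interpolate,
                         pseudocount, band, interpMethod, grid) {
  qlog <- .log2p(qvec[genes], pseudocount)
  if (metric == "spearman" && sd(qlog) == 0)
    stop("constant query profile over ruler genes: rank similarity undefined")
  reflog <- .log2p(assay(reference, 1L)[genes, , drop = FALSE], pseudocount)
  sims <- setNames(.similarityVector(qlog, reflog, metric, band),
                   stageLabels(reference))
  st <- stageTimes(reference)
  mx <- max(sims)
  bestIdx <- which(sims >= mx - 1e-12)[1L]  # ties -> earliest stage
  best <- names(sims)[bestIdx]
  if (!interpolate) {
    return(list(similarity = sims, best = best, time = unname(st[bestIdx])))
  }
  if (interpMethod == "parabola") {
    k <- bestIdx
    if (k == 1L || k == length(sims)) {
      time <- unname(st[k])
    } else {
      tt <- unname(st[(k - 1L):(k + 1L)]); yy <- unname(sims[(k - 1L):(k + 1L)])
      d21 <- (yy[2L] - yy[1L]) / (tt[2L] - tt[1L])
      d32 <- (yy[3L] - yy[2L]) / (tt[3L] - tt[2L])
      a <- (d32 - d21) / (tt[3L] - tt[1L])
      time <- if (a >= 0) unname(st[k]) else {
        v <- (tt[1L] + tt[2L]) / 2 - d21 / (2 * a)
        min(max(v, tt[1L]), tt[3L])
      }
    }
  } else {
    gsims <- .similarityVector(qlog, grid$logmat, metric, band)
    gmx <- max(gsims)
    plateau <- grid$times[gsims >= gmx - 1e-12]
    onPlateau <- st[vapply(st, function(s) any(abs(plateau - s) < 1e-9),
                           logical(1L))]
    # snap to a stage time when one attains the maximum (exact self-mapping);
    # otherwise take the midpoint of the optimal plateau
    time <- if (length(onPlateau)) unname(onPlateau[1L]) else median(plateau)
  }
  list(similarity = sims, best = best,
       time = min(max(time, st[1L]), st[length(st)]))
}

#' Map query transcriptomes onto the reference time-course
#'
#' For each query sample: computes the per-stage similarity over ruler genes,
#' takes the best stage (argmax; ties broken towards the earliest stage,
#' because maternal rulers lose resolution late), and optionally interpolates
#' a continuous developmental time. Replicates are estimated independently;
#' summarize them with [consensusEstimate()] (median).
#'
#' Two interpolation methods are available. `"grid"` (default) evaluates the
#' similarity on a fine time grid of log-linearly interpolated reference
#' profiles and returns the midpoint of the optimal plateau; log-linear
#' interpolation reproduces first-order maternal decay exactly, so noise-free
#' queries are recovered to grid resolution. `"parabola"` fits a 3-point
#' parabola through the per-stage similarities around the argmax (classic,
#' but limited by the coarseness of the stage grid).
#'
#' @inheritParams stageSimilarity
#' @param query gene x sample matrix or `SummarizedExperiment`; each column
#'   is estimated independently.
#' @param interpolate interpolate a continuous time (default TRUE).
#' @param gridResolution fine-grid spacing in minutes for
#'   `interpMethod = "grid"`.
#' @param interpMethod `"grid"` or `"parabola"`.
#' @return A [StageEstimateList-class], one [StageEstimate-class] per sample.
#' @examples
#' cfg <- simulationConfig(nMaternal = 50, nZygotic = 10, nStable = 10,
#'                         seed = 4)
#' sim <- simulateReference(cfg)
#' ruler <- compileRuler(sim$reference, trueClasses(sim$truth))
#' q <- simulateQuery(cfg, trueTime = 100, nReplicates = 2, seed = 5,
#'                    noiseDispersion = 0)
#' est <- estimateStage(q$query, sim$reference, ruler)
#' interpTimes(est)
#' @export
estimateStage <- function(query, reference, ruler,
                          metric = c("spearman", "overlap"),
                          interpolate = TRUE, pseudocount = 0.5,
                          gridResolution = 0.5,
                          interpMethod = c("grid", "parabola"), band = 2) {
  metric <- match.arg(metric)
  interpMethod <- match.arg(interpMethod)
  stopifnot(is(reference, "ReferenceTimecourse"))
  .checkScalarNumber(pseudocount, "pseudocount", positive = TRUE)
  .checkScalarNumber(gridResolution, "gridResolution", positive = TRUE)
  genes <- if (is(ruler, "RulerSet")) rulerGenes(ruler) else as.character(ruler)
  if (length(genes) == 0L) stop("empty ruler")
  q <- .exprValues(query, "query")
  missing <- setdiff(genes, rownames(q))
  missingRef <- setdiff(genes, rownames(reference))
  if (length(missing) || length(missingRef))
    stop("ruler gene(s) missing from query or reference: ",
         paste(head(c(missing, missingRef), 5L), collapse = ", "))

  grid <- NULL
  if (interpolate && interpMethod == "grid") {
    st <- unname(stageTimes(reference))
    times <- sort(unique(c(seq(st[1L], st[length(st)], by = gridResolution),
                           st)))
    grid <- list(times = times,
                 logmat = .rulerGrid(reference, genes, times, pseudocount))
  }
  params <- list(metric = metric, interpolate = interpolate,
                 pseudocount = pseudocount, interpMethod = interpMethod,
                 gridResolution = gridResolution, band = band,
                 nRulerGenes = length(genes))
  refId <- .referenceId(reference)
  ests <- lapply(seq_len(ncol(q)), function(j) {
    r <- .estimateOne(q[, j], reference, genes, metric, interpolate,
                      pseudocount, band, interpMethod, grid)
    new("StageEstimate", similarity = r$similarity, bestStage = r$best,
        interpTime = r$time, bootstrapSd = NA_real_, params = params,
        referenceId = refId)
  })
  names(ests) <- colnames(q)
  new("StageEstimateList", ests)
}

#' @export
setMethod("deltaTime", signature("StageEstimate", "StageEstimate"),
  function(a, b) {
    if (!identical(a@referenceId, b@referenceId))
      stop("stage estimates were made against different references")
    new("DeltaTimeEstimate", deltaT = b@interpTime - a@interpTime,
        method = "stage-mapping", components = list(A = a, B = b))
  })

#' @export
setMethod("deltaTime", signature("StageEstimateList", "StageEstimateList"),
  function(a, b) deltaTime(consensusEstimate(a), consensusEstimate(b)))

#' @export
setMethod("deltaTime", signature("StageEstimate", "StageEstimateList"),
  function(a, b) deltaTime(a, consensusEstimate(b)))

#' @export
setMethod("deltaTime", signature("StageEstimateList", "StageEstimate"),
  function(a, b) deltaTime(consensusEstimate(a), b))

#' @export
setMethod("deltaTime", signature("DecayFit", "missing"),
  function(a, b) {
    if (is.na(a@deltaT)) stop("DecayFit carries no offset estimate")
    new("DeltaTimeEstimate", deltaT = a@deltaT, method = "decay-regression",
        components = list(fit = a))
  })

#' Stage-matched reference expression profile
#'
#' Returns the reference expression profile (all genes) at a query's
#' estimated stage, for staging-adjusted comparison: with `interpolate =
#' FALSE` the column of the best stage verbatim; otherwise the log-linear
#' (geometric) interpolation between the flanking stage columns at the
#' estimated continuous time. Times outside the reference span are clamped
#' with a warning.
#'
#' @param reference a [ReferenceTimecourse-class].
#' @param est a [StageEstimate-class] (or [StageEstimateList-class], reduced
#'   by [consensusEstimate()]), or a bare numeric time in minutes AED.
#' @param interpolate use the continuous interpolated time (default TRUE).
#' @return named numeric vector: one abundance per reference gene.
#' @export
stageMatchedProfile <- function(reference, est, interpolate = TRUE) {
  stopifnot(is(reference, "ReferenceTimecourse"))
  st <- stageTimes(reference)
  vals <- assay(reference, 1L)
  if (is(est, "StageEstimateList")) est <- consensusEstimate(est)
  if (is(est, "StageEstimate")) {
    if (!identical(est@referenceId, .referenceId(reference)))
      stop("stage estimate was made against a different reference")
    if (!interpolate || !isTRUE(est@params$interpolate))
      return(vals[, est@bestStage])
    t <- est@interpTime
  } else {
    t <- .checkScalarNumber(est, "est")
    if (!interpolate) {
      k <- which.min(abs(st - t))
      return(vals[, k])
    }
  }
  if (t < st[1L] || t > st[length(st)]) {
    warning(sprintf("time %.2f outside reference span [%g, %g]; clamped",
                    t, st[1L], st[length(st)]))
    t <- min(max(t, st[1L]), st[length(st)])
  }
  hit <- which(abs(st - t) < 1e-9)
  if (length(hit)) return(vals[, hit[1L]])
  .geomInterp(vals, unname(st), t)[, 1L]
}

#' Normalize a query to the reference scale using ruler genes
#'
#' Rescales every query sample by a single factor so that its ruler-gene
#' levels match the reference. With `anchor = "matched"` (default) the stage
#' of each sample is first estimated with the scale-free rank metric and the
#' factor is the median, over ruler genes, of matched-profile / query - so
#' a pure library-size multiplier is recovered exactly on noise-free data.
#' `anchor = "first"` computes the factor against the first reference stage
#' instead. All-zero ruler rows are excluded from the median; scaling
#' factors are recorded in the output `colData`.
#'
#' @inheritParams estimateStage
#' @param anchor `"matched"` or `"first"`.
#' @param minShared minimum number of shared ruler genes (default 10).
#' @param interpolate anchor at the continuous interpolated time (default)
#'   or at the discrete best stage (`FALSE`; appropriate when queries are
#'   compared against a verbatim reference column).
#' @return A `SummarizedExperiment` with the rescaled `abundance` assay and
#'   a `scaleFactor` column in `colData`.
#' @export
normalizeToReference <- function(query, reference, ruler,
                                 anchor = c("matched", "first"),
                                 minShared = 10L, pseudocount = 0.5,
                                 gridResolution = 0.5, interpolate = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(is(reference, "ReferenceTimecourse"))
  genes <- if (is(ruler, "RulerSet")) rulerGenes(ruler) else as.character(ruler)
  q <- .exprValues(query, "query")
  shared <- intersect(genes, intersect(rownames(q), rownames(reference)))
  if (length(shared) < minShared)
    stop(sprintf("only %d ruler gene(s) shared between query and reference (need >= %d)",
                 length(shared), minShared))
  factors <- vapply(seq_len(ncol(q)), function(j) {
    qv <- q[shared, j]
    target <- if (anchor == "first") {
      assay(reference, 1L)[shared, 1L]
    } else {
      est <- estimateStage(q[, j, drop = FALSE], reference, shared,
                           metric = "spearman", interpolate = interpolate,
                           pseudocount = pseudocount,
                           gridResolution = gridResolution)[[1L]]
      stageMatchedProfile(reference, est, interpolate = interpolate)[shared]
    }
    ok <- qv > 0 & target > 0
    if (!any(ok)) stop("no non-zero ruler gene shared with the reference")
    median(target[ok] / qv[ok])
  }, numeric(1L))
  scaled <- sweep(q, 2L, factors, `*`)
  out <- SummarizedExperiment(
    assays = list(abundance = scaled),
    colData = DataFrame(scaleFactor = factors, row.names = colnames(q)))
  metadata(out)$normalization <- list(anchor = anchor, ruler = length(shared),
                                      pseudocount = pseudocount)
  out
}

#' Bootstrap uncertainty of the interpolated staging time
#'
#' Resamples ruler genes with replacement, re-estimates the staging time of
#' the query (replicates summarized by median), and reports the standard
#' deviation of the interpolated time across bootstrap draws.
#'
#' @inheritParams estimateStage
#' @param nBoot number of bootstrap draws (`>= 100`).
#' @param seed integer seed (draws are reproducible).
#' @return The consensus [StageEstimate-class] with `bootstrapSd` filled in;
#'   the bootstrap time distribution is in `params$bootTimes`.
#' @export
bootstrapStage <- function(query, reference, ruler, nBoot = 200L, seed = 1L,
                           metric = c("spearman", "overlap"),
                           interpolate = TRUE, pseudocount = 0.5,
                           gridResolution = 0.5,
                           interpMethod = c("grid", "parabola"), band = 2) {
  metric <- match.arg(metric)
  interpMethod <- match.arg(interpMethod)
  nBoot <- as.integer(nBoot)
  if (nBoot < 100L) stop("'nBoot' must be >= 100")
  genes <- if (is(ruler, "RulerSet")) rulerGenes(ruler) else as.character(ruler)
  est0 <- consensusEstimate(estimateStage(query, reference, genes,
                                          metric = metric,
                                          interpolate = interpolate,
                                          pseudocount = pseudocount,
                                          gridResolution = gridResolution,
                                          interpMethod = interpMethod,
                                          band = band))
  times <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      g <- sample(genes, length(genes), replace = TRUE)
      median(interpTimes(estimateStage(query, reference, g, metric = metric,
                                       interpolate = interpolate,
                                       pseudocount = pseudocount,
                                       gridResolution = gridResolution,
                                       interpMethod = interpMethod,
                                       band = band)))
    }, numeric(1L))
  })
  est0@bootstrapSd <- sd(times)
  est0@params$nBoot <- nBoot
  est0@params$bootSeed <- as.integer(seed)
  est0@params$bootTimes <- times
  est0
}
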