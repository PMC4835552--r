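#' @include AllClasses.R
NULL

#' Configure the synthetic MZT simulator
#'
#' Builds a [SimulationConfig-class] describing a synthetic early-embryo
#' transcriptome. The generative model has three gene classes:
#'
#' * maternal: `m(t) = m0 * 2^(-t / t1/2)`, first-order decay from a
#'   gene-specific baseline `m0` with a gene-specific half-life `t1/2`
#'   (minutes) drawn log-normally;
#' * zygotic: `z(t) = zmax * logistic((t - onsetTime) / activationScale)`,
#'   sigmoidal activation with midpoint `onsetTime`;
#' * stable: constant housekeeping expression.
#'
#' Baselines (`m0`, `zmax`, stable levels) are drawn log-normally on the
#' log2 scale. Observed values multiply the noise-free mean by
#' `2^rnorm(0, noiseDispersion)`.
#'
#' Defaults emulate the *Drosophila* pre-cellularization regime: 8 reference
#' stages indexed by nuclear cycles c10-c14D between 60 and 170 min after
#' egg deposition, zygotic activation centred at 120 min, and maternal
#' half-lives mostly between ~20 and ~180 min.
#'
#' @param nMaternal,nZygotic,nStable gene counts per class.
#' @param halflifeLog2Mean,halflifeLog2Sd mean and sd of log2(half-life in
#'   minutes); defaults `log2(60)` and `0.8`.
#' @param onsetTime zygotic activation midpoint, minutes AED.
#' @param activationScale logistic time scale of activation, minutes.
#' @param baselineLog2Mean,baselineLog2Sd mean and sd of log2 baseline
#'   abundance (RPKM-like units).
#' @param noiseDispersion sd of the per-observation multiplicative noise on
#'   the log2 scale; `0` disables noise.
#' @param referenceTimes strictly increasing stage times, minutes AED.
#' @param stageLabels one label per reference time.
#' @param seed integer seed fixing the realized gene table (baselines,
#'   half-lives). All simulation outputs derived from the same config share
#'   the same genes.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nMaternal = 20, nZygotic = 5, nStable = 5, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nMaternal = 300L, nZygotic = 150L, nStable = 100L,
                             halflifeLog2Mean = log2(60),
                             halflifeLog2Sd = 0.8,
                             onsetTime = 120, activationScale = 15,
                             baselineLog2Mean = 5, baselineLog2Sd = 2,
                             noiseDispersion = 0.25,
                             referenceTimes = c(60, 80, 95, 105, 115, 130, 150, 170),
                             stageLabels = c("c10", "c11", "c12", "c13",
                                             "c14A", "c14B", "c14C", "c14D"),
                             seed = 1L) {
  new("SimulationConfig",
      nMaternal = as.integer(nMaternal), nZygotic = as.integer(nZygotic),
      nStable = as.integer(nStable),
      halflifeLog2Mean = as.numeric(halflifeLog2Mean),
      halflifeLog2Sd = as.numeric(halflifeLog2Sd),
      onsetTime = as.numeric(onsetTime),
      activationScale = as.numeric(activationScale),
      baselineLog2Mean = as.numeric(baselineLog2Mean),
      baselineLog2Sd = as.numeric(baselineLog2Sd),
      noiseDispersion = as.numeric(noiseDispersion),
      referenceTimes = as.numeric(referenceTimes),
      stageLabels = as.character(stageLabels), seed = as.integer(seed))
}

# Deterministic realization of the per-gene parameter table from the config
# seed: ids, classes, baselines, half-lives. Draw order is fixed so that the
# realization is bit-reproducible.
.realizeGenes <- function(config) {
  .withSeed(config@seed, {
    nm <- config@nMaternal; nz <- config@nZygotic; ns <- config@nStable
    gene <- c(sprintf("mat_%04d", seq_len(nm)),
              sprintf("zyg_%04d", seq_len(nz)),
              sprintf("stb_%04d", seq_len(ns)))
    class <- rep(c("maternal", "zygotic", "stable"), c(nm, nz, ns))
    scale <- 2^rnorm(nm + nz + ns, config@baselineLog2Mean, config@baselineLog2Sd)
    halflife <- rep(NA_real_, nm + nz + ns)
    halflife[seq_len(nm)] <- 2^rnorm(nm, config@halflifeLog2Mean,
                                     config@halflifeLog2Sd)
    data.frame(gene = gene, class = class, scale = scale,
               halflife = halflife, stringsAsFactors = FALSE)
  })
}

.meanExpression <- function(genes, times, onsetTime, activationScale) {
  out <- matrix(NA_real_, nrow(genes), length(times),
                dimnames = list(genes$gene, NULL))
  mat <- genes$class == "maternal"
  zyg <- genes$class == "zygotic"
  stb <- genes$class == "stable"
  for (j in seq_along(times)) {
    t <- times[j]
    out[mat, j] <- genes$scale[mat] * 2^(-t / genes$halflife[mat])
    out[zyg, j] <- genes$scale[zyg] *
      plogis((t - onsetTime) / activationScale)
    out[stb, j] <- genes$scale[stb]
  }
  out
}

#' Noise-free expected expression of simulated genes
#'
#' Evaluates the deterministic mean of the generative model: exponential
#' decay for maternal genes, logistic activation for zygotic genes, constant
#' levels for stable genes.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene ids to evaluate; `NULL` for all realized genes.
#' @param times one or more times, minutes AED (must be `>= 0`).
#' @return A genes x times numeric matrix of non-negative abundances
#'   (column names are the times).
#' @examples
#' cfg <- simulationConfig(nMaternal = 3, nZygotic = 2, nStable = 1, seed = 7)
#' expectedExpression(cfg, times = c(60, 120))
#' @export
expectedExpression <- function(config, genes = NULL, times) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.numeric(times) || any(times < 0) || any(!is.finite(times)))
    stop("'times' must be finite and >= 0")
  tab <- .realizeGenes(config)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, tab$gene)
    if (length(unknown))
      stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
    tab <- tab[match(genes, tab$gene), , drop = FALSE]
  }
  out <- .meanExpression(tab, times, config@onsetTime, config@activationScale)
  colnames(out) <- as.character(times)
  out
}

#' Simulate a reference developmental time-course
#'
#' Generates one column per configured reference time, noise-free by default
#' (the published time-course the analysis maps onto is treated as the
#' ground-truth trajectory), optionally perturbed by the configured
#' multiplicative noise.
#'
#' @param config a [SimulationConfig-class].
#' @param noise if TRUE, apply multiplicative log-normal noise with sd
#'   `noiseDispersion(config)` (seeded from `config@seed + 1`).
#' @return A list with elements `reference` ([ReferenceTimecourse-class]) and
#'   `truth` ([SimTruth-class]).
#' @examples
#' sim <- simulateReference(simulationConfig(nMaternal = 5, nZygotic = 2,
#'                                           nStable = 2, seed = 3))
#' sim$reference
#' @export
simulateReference <- function(config, noise = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  tab <- .realizeGenes(config)
  values <- .meanExpression(tab, config@referenceTimes, config@onsetTime,
                            config@activationScale)
  if (noise && config@noiseDispersion > 0) {
    values <- .withSeed(config@seed + 1L,
      values * 2^matrix(rnorm(length(values), 0, config@noiseDispersion),
                        nrow(values)))
  }
  colnames(values) <- config@stageLabels
  reference <- ReferenceTimecourse(values, config@stageLabels,
                                   config@referenceTimes, unit = "abundance")
  truth <- new("SimTruth",
               sampleTime = setNames(config@referenceTimes, config@stageLabels),
               geneClass = setNames(tab$class, tab$gene),
               halfLife = setNames(tab$halflife, tab$gene),
               onsetTime = config@onsetTime, seed = config@seed)
  list(reference = reference, truth = truth)
}

#' Simulate replicate query transcriptomes at a hidden true time
#'
#' Each replicate is the noise-free expected expression at `trueTime`,
#' optionally shifted by planted per-gene condition effects, scaled by a
#' library-size factor, and perturbed by multiplicative log-normal noise
#' (default mode) or Poisson counting noise (`mode = "counts"`).
#'
#' @param config a [SimulationConfig-class]; gene identities match any other
#'   simulation from the same config.
#' @param trueTime true developmental time, minutes AED (`>= 0`).
#' @param nReplicates number of replicate samples (`>= 1`).
#' @param seed integer seed for the noise draws.
#' @param noiseDispersion sd of log2 multiplicative noise; defaults to the
#'   config value.
#' @param effectLog2 optional named numeric of planted log2 condition effects
#'   added to the log2 mean of the named genes (a condition effect on top of
#'   timing).
#' @param libraryFactors per-replicate library-size multipliers (recycled).
#' @param mode `"abundance"` (continuous, default) or `"counts"` (Poisson
#'   with library-size scaling).
#' @param sampleNames optional column names.
#' @return A list with elements `query` (a
#'   [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#'   and `truth` ([SimTruth-class]).
#' @examples
#' cfg <- simulationConfig(nMaternal = 5, nZygotic = 2, nStable = 2, seed = 3)
#' q <- simulateQuery(cfg, trueTime = 100, nReplicates = 3, seed = 11)
#' dim(q$query)
#' @export
simulateQuery <- function(config, trueTime, nReplicates = 1L, seed = 1L,
                          noiseDispersion = NULL, effectLog2 = NULL,
                          libraryFactors = 1, mode = c("abundance", "counts"),
                          sampleNames = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  mode <- match.arg(mode)
  .checkScalarNumber(trueTime, "trueTime", nonneg = TRUE)
  nReplicates <- as.integer(nReplicates)
  if (nReplicates < 1L) stop("'nReplicates' must be >= 1")
  if (is.null(noiseDispersion)) noiseDispersion <- config@noiseDispersion
  .checkScalarNumber(noiseDispersion, "noiseDispersion", nonneg = TRUE)

  tab <- .realizeGenes(config)
  mu <- .meanExpression(tab, trueTime, config@onsetTime,
                        config@activationScale)[, 1L]
  if (!is.null(effectLog2)) {
    if (is.null(names(effectLog2)))
      stop("'effectLog2' must be named by gene id")
    unknown <- setdiff(names(effectLog2), tab$gene)
    if (length(unknown))
      stop("unknown gene id(s) in 'effectLog2': ",
           paste(unknown, collapse = ", "))
    mu[names(effectLog2)] <- mu[names(effectLog2)] * 2^effectLog2
  }
  libraryFactors <- rep_len(libraryFactors, nReplicates)
  if (any(libraryFactors <= 0)) stop("'libraryFactors' must be > 0")

  values <- .withSeed(seed, {
    vapply(seq_len(nReplicates), function(r) {
      m <- mu * libraryFactors[r]
      if (mode == "abundance") {
        if (noiseDispersion > 0)
          m <- m * 2^rnorm(length(m), 0, noiseDispersion)
        m
      } else {
        as.numeric(rpois(length(m), m))
      }
    }, numeric(length(mu)))
  })
  if (is.null(sampleNames))
    sampleNames <- sprintf("q%02d", seq_len(nReplicates))
  dimnames(values) <- list(tab$gene, sampleNames)
  query <- SummarizedExperiment(
    assays = list(abundance = values),
    colData = DataFrame(trueTime = rep(trueTime, nReplicates),
                        libraryFactor = libraryFactors,
                        row.names = sampleNames))
  metadata(query)$unit <- if (mode == "counts") "counts" else "abundance"
  truth <- new("SimTruth",
               sampleTime = setNames(rep(trueTime, nReplicates), sampleNames),
               geneClass = setNames(tab$class, tab$gene),
               halfLife = setNames(tab$halflife, tab$gene),
               effectLog2 = if (is.null(effectLog2))
                 setNames(numeric(), character()) else effectLog2,
               onsetTime = config@onsetTime, seed = as.integer(seed))
  list(query = query, truth = truth)
}

#' Ground-truth accessors
#'
#' @param truth a [SimTruth-class].
#' @return `trueTimes`: named numeric of true sample times; `trueClasses`: a
#'   [GeneClasses-class]; `trueHalfLives`: named numeric of maternal
#'   half-lives (minutes).
#' @export
trueTimes <- function(truth) truth@sampleTime

#' @rdname trueTimes
#' @export
trueClasses <- function(truth) {
  cl <- truth@geneClass
  geneClasses(maternal = names(cl)[cl == "maternal"],
              zygotic = names(cl)[cl == "zygotic"],
              stable = names(cl)[cl == "stable"],
              source = "simulation truth")
}

#' @rdname trueTimes
#' @export
trueHalfLives <- function(truth) {
  hl <- truth@halfLife
  hl[truth@geneClass[names(hl)] == "maternal"]
}
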