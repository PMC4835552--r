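# Shared fixtures and independent oracles, built in code at test time.

smallConfig <- function(seed = 1L, ...) {
  simulationConfig(nMaternal = 30L, nZygotic = 8L, nStable = 6L,
                   seed = seed, ...)
}

refAssay <- function(x) SummarizedExperiment::assay(x, 1L)

# Independent brute-force ruler filter: applies the three predicates gene by
# gene, plainly, without reusing any package internals.
bruteForceRuler <- function(reference, classes, minFirstStageExpr = 1,
                            monotoneTolerance = 0.05, minTotalDecline = 2) {
  vals <- refAssay(reference)
  cl <- geneClassLabels(classes)
  keep <- character()
  for (g in rownames(vals)) {
    if (!g %in% names(cl) || cl[[g]] != "maternal") next
    v <- as.numeric(vals[g, ])
    if (v[1L] < minFirstStageExpr) next
    mono <- TRUE
    for (j in seq_len(length(v) - 1L))
      if (v[j + 1L] > v[j] * (1 + monotoneTolerance)) mono <- FALSE
    if (!mono) next
    dec <- if (v[length(v)] > 0) v[1L] / v[length(v)]
           else if (v[1L] > 0) Inf else 1
    if (dec < minTotalDecline) next
    keep <- c(keep, g)
  }
  keep[order(vals[keep, 1L], decreasing = TRUE)]
}

# Exact two-sided sign-test p-value by direct binomial enumeration.
enumSignP <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

# The standard stage-matched residual workflow used across tests: pool the
# replicates, normalize the pooled profile to the reference via ruler genes,
# match at the discrete best stage, and take residual fold-changes.
residualWorkflow <- function(query, reference, ruler, pseudocount = 0.5) {
  pooled <- matrix(rowMeans(refAssay(query)), ncol = 1L,
                   dimnames = list(rownames(query), "pooled"))
  np <- normalizeToReference(pooled, reference, ruler, interpolate = FALSE)
  est <- estimateStage(np, reference, ruler, interpolate = FALSE)[[1L]]
  matched <- stageMatchedProfile(reference, est, interpolate = FALSE)
  list(est = est,
       residual = residualFoldChanges(np, matched, pseudocount = pseudocount))
}
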