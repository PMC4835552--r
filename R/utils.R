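# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be a finite integer")
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
  }
  force(code)
}

# Coerce an expression container to a plain gene x sample matrix with dimnames.
.exprValues <- function(x, arg = deparse(substitute(x))) {
  if (is(x, "SummarizedExperiment")) {
    m <- as.matrix(assay(x, 1L))
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.numeric(x) && !is.null(names(x))) {
    m <- matrix(x, ncol = 1L, dimnames = list(names(x), "profile"))
  } else if (is.data.frame(x)) {
    m <- as.matrix(x)
  } else {
    stop(sprintf("'%s' must be a matrix, SummarizedExperiment or named numeric", arg))
  }
  if (is.null(rownames(m))) stop(sprintf("'%s' must have gene ids as rownames", arg))
  if (is.null(colnames(m))) colnames(m) <- paste0("sample", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

# Gene universe of any package object that carries gene ids.
.geneIds <- function(x) {
  if (is(x, "SummarizedExperiment")) return(rownames(x))
  if (is(x, "GeneClasses")) return(names(geneClassLabels(x)))
  if (is(x, "FoldChangeTable")) return(names(foldChanges(x)))
  if (is(x, "RulerSet")) return(rulerGenes(x))
  if (is.matrix(x) || is.data.frame(x)) return(rownames(x))
  if (is.numeric(x) && !is.null(names(x))) return(names(x))
  stop("cannot extract gene ids from object of class ", class(x)[1L])
}

.subsetGenes <- function(x, genes) {
  if (is(x, "SummarizedExperiment")) return(x[genes, , drop = FALSE])
  if (is(x, "GeneClasses")) {
    cl <- geneClassLabels(x)
    return(new("GeneClasses", labels = cl[genes], source = x@source, params = x@params))
  }
  if (is(x, "FoldChangeTable")) {
    return(new("FoldChangeTable", log2fc = foldChanges(x)[genes],
               pseudocount = x@pseudocount, conditions = x@conditions))
  }
  if (is(x, "RulerSet")) {
    return(new("RulerSet", genes = intersect(rulerGenes(x), genes),
               params = x@params, provenance = x@provenance))
  }
  if (is.matrix(x) || is.data.frame(x)) return(x[genes, , drop = FALSE])
  if (is.numeric(x)) return(x[genes])
  stop("cannot subset object of class ", class(x)[1L])
}

# Geometric (log-linear in time) interpolation of reference columns at times
# `tout`. Exact for first-order decay: log2 m(t) is linear in t.
# Returns a genes x length(tout) matrix. Zeros interpolate to zero.
.geomInterp <- function(values, times, tout) {
  stopifnot(ncol(values) == length(times))
  tout <- pmin(pmax(tout, times[1L]), times[length(times)])
  k <- findInterval(tout, times, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(times) - 1L)
  out <- matrix(NA_real_, nrow(values), length(tout),
                dimnames = list(rownames(values), NULL))
  lv <- log(values)  # -Inf at zeros, handled below
  for (j in seq_along(tout)) {
    kj <- k[j]
    w <- (tout[j] - times[kj]) / (times[kj + 1L] - times[kj])
    if (w <= 0) out[, j] <- values[, kj]
    else if (w >= 1) out[, j] <- values[, kj + 1L]
    else out[, j] <- exp((1 - w) * lv[, kj] + w * lv[, kj + 1L])
  }
  out
}

.log2p <- function(x, pseudocount) log2(x + pseudocount)

# Compact fingerprint of a reference time-course, used to refuse comparisons
# of stage estimates made against different references.
.referenceId <- function(reference) {
  paste(nrow(reference),
        paste(stageLabels(reference), collapse = ","),
        paste(format(stageTimes(reference), trim = TRUE), collapse = ","),
        sep = "|")
}

.checkScalarNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
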