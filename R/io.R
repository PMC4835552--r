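#' @include AllClasses.R
NULL

# Read a TSV with '#' comment lines, reporting ragged rows by line number.
.readTsv <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- count.fields(path, sep = "\t", comment.char = "#",
                         quote = "\"")
  fields <- fields[!is.na(fields)]
  if (length(fields) == 0L) stop("empty file: ", path)
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])
    stop(sprintf("ragged table in %s: row(s) %s have a different field count",
                 path, paste(head(bad, 5L), collapse = ", ")))
  }
  read.delim(path, header = header, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = NA, quote = "\"")
}

#' Read / write a gene x sample expression matrix
#'
#' Tab-separated text with the gene id in the first column and a header row
#' of sample ids. Values must be non-negative; ids are stripped of
#' surrounding whitespace; duplicated gene or sample ids, ragged rows,
#' non-numeric or negative entries raise descriptive errors.
#'
#' @param path file path.
#' @param unit unit tag attached to the matrix (`"rpkm"`, `"abundance"`,
#'   `"counts"`).
#' @return `readExpressionMatrix` returns a
#'   [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with a single `abundance` assay; `writeExpressionMatrix` invisibly
#'   returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' writeExpressionMatrix(m, tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path, unit = c("abundance", "rpkm", "counts")) {
  unit <- match.arg(unit)
  df <- .readTsv(path, header = TRUE)
  if (ncol(df) < 2L) stop("expression matrix needs a gene column plus >=1 sample")
  genes <- trimws(as.character(df[[1L]]))
  samples <- trimws(colnames(df)[-1L])
  if (anyDuplicated(genes))
    stop("duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)])[1:min(5, sum(duplicated(genes)))],
               collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric value(s), e.g. gene '%s' sample '%s' (row %d)",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]], bad[1L, 1L]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)
    stop(sprintf("negative value for gene '%s' in sample '%s'",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(genes, samples)
  se <- SummarizedExperiment(assays = list(abundance = vals))
  metadata(se)$unit <- unit
  se
}

#' @rdname readExpressionMatrix
#' @param x matrix or `SummarizedExperiment` to write.
#' @param idColumn header name of the gene id column.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "gene_id") {
  m <- .exprValues(x, "x")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a stage table
#'
#' Two tab-separated columns: stage label and time in minutes AED, in
#' developmental order; `#` comment lines allowed.
#'
#' @param path file path.
#' @return named numeric vector of stage times (names = labels).
#' @export
readStageTable <- function(path) {
  df <- .readTsv(path, header = FALSE)
  if (ncol(df) != 2L) stop("stage table must have two columns: label<TAB>minutes")
  labels <- trimws(as.character(df[[1L]]))
  times <- suppressWarnings(as.numeric(df[[2L]]))
  if (tolower(labels[1L]) %in% c("stage", "label") && is.na(times[1L])) {
    labels <- labels[-1L]; times <- times[-1L]
  }
  if (anyNA(times)) stop("non-numeric stage time(s) in ", path)
  if (anyDuplicated(labels)) stop("duplicated stage label(s)")
  if (any(diff(times) <= 0)) stop("stage times must be strictly increasing")
  setNames(times, labels)
}

#' @rdname readStageTable
#' @param stageTimes named numeric of stage times.
#' @export
writeStageTable <- function(stageTimes, path) {
  write.table(data.frame(names(stageTimes), unname(stageTimes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference time-course from matrix + stage table files
#'
#' The matrix columns are matched to the stage-table labels (reordered if
#' necessary); any mismatch is an error.
#'
#' @param matrixPath expression matrix TSV (see [readExpressionMatrix()]).
#' @param stagePath stage table TSV (see [readStageTable()]).
#' @param unit unit tag.
#' @return A [ReferenceTimecourse-class].
#' @export
readReferenceTimecourse <- function(matrixPath, stagePath,
                                    unit = c("abundance", "rpkm", "counts")) {
  se <- readExpressionMatrix(matrixPath, match.arg(unit))
  st <- readStageTable(stagePath)
  missing <- setdiff(names(st), colnames(se))
  if (length(missing))
    stop("stage(s) missing from matrix columns: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(se), names(st))
  if (length(extra))
    stop("matrix column(s) not in stage table: ", paste(extra, collapse = ", "))
  vals <- assay(se, 1L)[, names(st), drop = FALSE]
  ReferenceTimecourse(vals, names(st), unname(st), unit = match.arg(unit))
}

#' Read / write a gene list
#'
#' One gene id per line; `#` starts a comment (full-line or trailing);
#' surrounding whitespace is stripped and empty lines dropped.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:min(5, length(ids))], collapse = ", "))
  ids
}

#' @rdname readGeneList
#' @param genes character vector of gene ids.
#' @param comments optional character vector written as leading `#` lines.
#' @export
writeGeneList <- function(genes, path, comments = character()) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(genes, con)
  invisible(path)
}

#' Read maternal/zygotic gene classes from published-style gene lists
#'
#' @param maternalPath,zygoticPath gene-list files (one id per line, `#`
#'   comments allowed). A gene appearing in both lists is an error.
#' @param source free-text provenance recorded on the result.
#' @return A [GeneClasses-class].
#' @export
readGeneClasses <- function(maternalPath, zygoticPath, source = "") {
  maternal <- readGeneList(maternalPath)
  zygotic <- readGeneList(zygoticPath)
  overlap <- intersect(maternal, zygotic)
  if (length(overlap))
    stop("gene(s) listed as both maternal and zygotic: ",
         paste(head(overlap, 5L), collapse = ", "))
  if (!nzchar(source))
    source <- paste(basename(maternalPath), basename(zygoticPath), sep = " + ")
  geneClasses(maternal = maternal, zygotic = zygotic, source = source)
}

#' Read / write a half-life table
#'
#' Tab-separated `gene<TAB>half-life` with half-lives in minutes; an optional
#' header row is detected and skipped. All half-lives must be finite and
#' strictly positive.
#'
#' @param path file path.
#' @return named numeric vector of half-lives (minutes).
#' @export
readHalfLives <- function(path) {
  df <- .readTsv(path, header = FALSE)
  if (ncol(df) != 2L) stop("half-life table must have two columns: gene<TAB>minutes")
  genes <- trimws(as.character(df[[1L]]))
  hl <- suppressWarnings(as.numeric(df[[2L]]))
  if (is.na(hl[1L]) && nrow(df) > 1L) { genes <- genes[-1L]; hl <- hl[-1L] }
  if (anyNA(hl)) stop("non-numeric half-life value(s) in ", path)
  if (anyDuplicated(genes)) stop("duplicated gene id(s) in half-life table")
  bad <- genes[!is.finite(hl) | hl <= 0]
  if (length(bad))
    stop("non-positive or non-finite half-life for gene(s): ",
         paste(head(bad, 5L), collapse = ", "))
  setNames(hl, genes)
}

#' @rdname readHalfLives
#' @param halfLives named numeric vector (minutes).
#' @export
writeHalfLives <- function(halfLives, path) {
  stopifnot(!is.null(names(halfLives)))
  write.table(data.frame(names(halfLives), unname(halfLives)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict objects to their common gene universe
#'
#' Takes two or more objects carrying gene ids (expression matrices,
#' `SummarizedExperiment`s, [GeneClasses-class], [FoldChangeTable-class],
#' [RulerSet-class], named numeric half-life tables) and restricts each to
#' the genes present in all of them, in a common order (the order of the
#' first object). A per-input report of dropped genes is attached as the
#' `"report"` attribute.
#'
#' @param ... two or more named or unnamed objects.
#' @return list of restricted objects (same classes, common gene order),
#'   with attribute `report`: a data.frame of input/kept/dropped counts.
#' @examples
#' a <- matrix(1:6, 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' b <- matrix(1:4, 2, dimnames = list(c("g2", "g1"), c("t1", "t2")))
#' out <- intersectGenes(a = a, b = b)
#' attr(out, "report")
#' @export
intersectGenes <- function(...) {
  objects <- list(...)
  if (length(objects) < 2L) stop("need at least two objects")
  if (is.null(names(objects))) names(objects) <- paste0("object", seq_along(objects))
  ids <- lapply(objects, .geneIds)
  common <- Reduce(intersect, ids[-1L], ids[[1L]])
  if (length(common) == 0L) stop("empty gene intersection across inputs")
  common <- ids[[1L]][ids[[1L]] %in% common]  # order of the first object
  out <- lapply(objects, .subsetGenes, genes = common)
  attr(out, "report") <- data.frame(
    object = names(objects),
    n_input = vapply(ids, length, integer(1L)),
    n_kept = length(common),
    n_dropped = vapply(ids, length, integer(1L)) - length(common),
    row.names = NULL)
  out
}

#' Read / write a simulation configuration
#'
#' Flat key/value YAML holding every [SimulationConfig-class] field.
#'
#' @param path file path.
#' @return `readSimulationConfig` returns a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(simulationConfig, x)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class].
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  fields <- c("nMaternal", "nZygotic", "nStable", "halflifeLog2Mean",
              "halflifeLog2Sd", "onsetTime", "activationScale",
              "baselineLog2Mean", "baselineLog2Sd", "noiseDispersion",
              "referenceTimes", "stageLabels", "seed")
  yaml::write_yaml(setNames(lapply(fields, slot, object = config), fields),
                   path)
  invisible(path)
}

#' Read / write simulation ground truth
#'
#' The gene table (`gene`, `class`, `halflife`, `effect_log2`) is written to
#' `genesPath`; the sample table (`sample`, `true_time`) to `samplesPath`.
#' Onset time and seed are recorded as `#` header comments of the gene table.
#'
#' @param truth a [SimTruth-class].
#' @param genesPath,samplesPath output/input file paths.
#' @return `readSimTruth` returns a [SimTruth-class].
#' @export
writeSimTruth <- function(truth, genesPath, samplesPath) {
  stopifnot(is(truth, "SimTruth"))
  con <- file(genesPath, "w")
  writeLines(c(sprintf("# onset_time=%.10g", truth@onsetTime),
               sprintf("# seed=%d", truth@seed)), con)
  close(con)
  eff <- rep(0, length(truth@geneClass))
  names(eff) <- names(truth@geneClass)
  eff[names(truth@effectLog2)] <- truth@effectLog2
  df <- data.frame(gene = names(truth@geneClass),
                   class = unname(truth@geneClass),
                   halflife = unname(truth@halfLife[names(truth@geneClass)]),
                   effect_log2 = unname(eff))
  suppressWarnings(write.table(df, genesPath, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  write.table(data.frame(sample = names(truth@sampleTime),
                         true_time = unname(truth@sampleTime)),
              samplesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genesPath)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(genesPath, samplesPath) {
  hdr <- readLines(genesPath, n = 10L, warn = FALSE)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("missing '# ", key, "=' header in ", genesPath)
    as.numeric(sub(paste0("^# ", key, "="), "", ln[1L]))
  }
  genes <- .readTsv(genesPath, header = TRUE)
  samples <- .readTsv(samplesPath, header = TRUE)
  eff <- setNames(genes$effect_log2, genes$gene)
  eff <- eff[eff != 0]
  new("SimTruth",
      sampleTime = setNames(as.numeric(samples$true_time), samples$sample),
      geneClass = setNames(genes$class, genes$gene),
      halfLife = setNames(as.numeric(genes$halflife), genes$gene),
      effectLog2 = eff,
      onsetTime = getval("onset_time"), seed = as.integer(getval("seed")))
}
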