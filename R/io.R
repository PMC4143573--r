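#' Read / write growth curves as TSV
#'
#' The on-disk format is a two-column TSV with \code{time_h} and
#' \code{od600}; strain and temperature live in the file name or a manifest
#' and are supplied by the caller on read.
#'
#' @param path TSV file path.
#' @param strain,temperature labels attached to the curve on read.
#' @return [readGrowthCurve()] returns a [GrowthCurve-class];
#'   [writeGrowthCurve()] returns \code{path} invisibly.
#' @export
readGrowthCurve <- function(path, strain, temperature) {
  d <- utils::read.delim(path)
  stopifnot(all(c("time_h", "od600") %in% names(d)))
  GrowthCurve(strain, temperature, d$time_h, d$od600)
}

#' @rdname readGrowthCurve
#' @param curve a [GrowthCurve-class].
#' @export
writeGrowthCurve <- function(curve, path) {
  stopifnot(is(curve, "GrowthCurve"))
  utils::write.table(
    data.frame(time_h = curve@times, od600 = curve@od),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read / write an expression matrix with sample metadata
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample; the metadata TSV has columns \code{sample}, \code{strain},
#' \code{condition}, \code{replicate}. An optional flags TSV mirrors the
#' matrix layout with detection calls.
#'
#' @param matrixPath,metaPath,flagsPath TSV paths (\code{flagsPath} optional).
#' @param scale intensity scale of the stored values.
#' @return [readExpressionMatrix()] returns a [ThermalExpressionSet-class].
#' @export
readExpressionMatrix <- function(matrixPath, metaPath, flagsPath = NULL,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  m <- utils::read.delim(matrixPath, check.names = FALSE)
  genes <- as.character(m[[1L]])
  mat <- as.matrix(m[, -1L, drop = FALSE])
  rownames(mat) <- genes
  meta <- utils::read.delim(metaPath)
  stopifnot(all(c("sample", "strain", "condition", "replicate") %in% names(meta)))
  idx <- match(colnames(mat), meta$sample)
  if (anyNA(idx))
    .stopf("metadata missing for sample(s): %s",
           paste(colnames(mat)[is.na(idx)], collapse = ", "))
  meta <- meta[idx, ]
  flags <- NULL
  if (!is.null(flagsPath)) {
    f <- utils::read.delim(flagsPath, check.names = FALSE)
    flags <- as.matrix(f[, -1L, drop = FALSE])
    rownames(flags) <- as.character(f[[1L]])
    flags <- flags[genes, colnames(mat), drop = FALSE]
  }
  ThermalExpressionSet(mat, strain = meta$strain, condition = meta$condition,
                       replicate = meta$replicate, flags = flags,
                       scale = scale)
}

#' @rdname readExpressionMatrix
#' @param x a [ThermalExpressionSet-class].
#' @param dir output directory; \code{matrix.tsv}, \code{samples.tsv} and
#'   (when flags exist) \code{flags.tsv} are written there.
#' @export
writeExpressionMatrix <- function(x, dir) {
  stopifnot(is(x, "ThermalExpressionSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- assay(x, "exprs")
  utils::write.table(
    data.frame(gene = rownames(e), e, check.names = FALSE),
    file.path(dir, "matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(sampleInfo(x), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- detectionFlags(x)
  if (!is.null(fl))
    utils::write.table(
      data.frame(gene = rownames(fl), fl, check.names = FALSE),
      file.path(dir, "flags.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
  invisible(dir)
}

#' Read a fold-change table from TSV
#'
#' First column = gene id, remaining columns = per-strain linear fold
#' changes.
#'
#' @param path TSV path.
#' @return A [FoldChangeTable-class].
#' @export
readFoldChangeTable <- function(path) {
  FoldChangeTable(utils::read.delim(path, check.names = FALSE))
}

#' Read a long-format Cq table from TSV
#'
#' Expected columns: \code{gene}, \code{sample}, \code{cq}, \code{role}
#' (\code{standard}/\code{unknown}), plus \code{dilution} for standards and
#' \code{strain}, \code{condition} for unknowns. The shape
#' [qpcrRelativeExpression()] consumes.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readCqTable <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("gene", "sample", "cq", "role") %in% names(d)))
  d
}

#' Read phenotype observations from TSV
#'
#' Expected columns: \code{strain}, \code{temperature},
#' \code{expression_ratio}, \code{td_ratio} (camelCase accepted too).
#'
#' @param path TSV path.
#' @return data.frame ready for [fitPhenotypeRegression()].
#' @export
readPhenotypeObservations <- function(path) {
  .normalizeObsNames(utils::read.delim(path))
}

#' Write a screen result to disk
#'
#' Writes the per-gene audit as \code{audit.tsv} and, when the jsonlite
#' package is available, a \code{summary.json} with the stage gene sets and
#' parameters.
#'
#' @param result a [ScreenResult-class].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeScreenResult <- function(result, dir) {
  stopifnot(is(result, "ScreenResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(screenAudit(result), file.path(dir, "audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(stage1 = result@stage1, stage2 = result@stage2,
           stage3 = result@stage3,
           toleranceOrder = result@toleranceOrder,
           parameters = result@parameters[!vapply(result@parameters, is.function,
                                                  logical(1))]),
      file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(dir)
}
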