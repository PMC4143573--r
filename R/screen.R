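#' Percentile-shift normalisation
#'
#' Log2-transforms linear intensities, then subtracts from each sample
#' (column) the chosen percentile of its own log2 values. After the shift,
#' that percentile of every sample is exactly 0, which removes per-sample
#' global intensity differences: two samples differing only by a global
#' scale factor become identical.
#'
#' @param x a linear-scale [ThermalExpressionSet-class], or a positive
#'   numeric matrix (genes x samples).
#' @param percentile percentile to anchor at 0 (default 75).
#'
#' @return The same type as \code{x}, on the log2 scale.
#' @examples
#' m <- matrix(2^(1:6), 3, 2, dimnames = list(paste0("G", 1:3), c("a", "b")))
#' percentileShiftNormalize(m)
#' @rdname percentileShiftNormalize
#' @export
setMethod("percentileShiftNormalize", "matrix",
  function(x, percentile = 75) {
    if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
      .stopf("'percentile' must lie in (0, 100)")
    if (any(!is.finite(x)) || any(x <= 0))
      .stopf("percentile-shift normalisation needs strictly positive linear intensities")
    l2 <- log2(x)
    shifts <- apply(l2, 2L, stats::quantile, probs = percentile / 100,
                    names = FALSE)
    sweep(l2, 2L, shifts, "-")
  })

#' @rdname percentileShiftNormalize
#' @export
setMethod("percentileShiftNormalize", "ThermalExpressionSet",
  function(x, percentile = 75) {
    if (intensityScale(x) != "linear")
      .stopf("input is already on the log2 scale; normalisation expects linear intensities")
    assay(x, "exprs") <- percentileShiftNormalize(assay(x, "exprs"), percentile)
    metadata(x)$scale <- "log2"
    validObject(x)
    x
  })

#' Low-intensity gene filter
#'
#' Flags the genes ranking in the lowest \code{fraction} of every sample
#' (the permissive reading: a gene expressed above the floor in even one
#' sample is kept, so heat-induced genes that are low in controls survive).
#' Per sample, the low set is the \code{floor(fraction * nGenes)} smallest
#' values.
#'
#' @param x a [ThermalExpressionSet-class] or numeric matrix; the ranking is
#'   scale-invariant, so linear or log2 input give the same mask.
#' @param fraction fraction of each sample treated as the low tail, in
#'   \[0, 1).
#'
#' @return Named logical vector, TRUE = keep.
#' @rdname lowIntensityFilter
#' @export
setMethod("lowIntensityFilter", "matrix",
  function(x, fraction = 0.2) {
    if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
      .stopf("'fraction' must lie in [0, 1)")
    k <- floor(fraction * nrow(x))
    if (k == 0L) {
      keep <- rep(TRUE, nrow(x))
    } else {
      lowEverywhere <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x))) {
        r <- rank(x[, j], ties.method = "min")
        lowEverywhere <- lowEverywhere & (r <= k)
      }
      keep <- !lowEverywhere
    }
    names(keep) <- rownames(x)
    keep
  })

#' @rdname lowIntensityFilter
#' @export
setMethod("lowIntensityFilter", "ThermalExpressionSet",
  function(x, fraction = 0.2) lowIntensityFilter(assay(x, "exprs"), fraction))

#' Detection-flag filter
#'
#' Keeps a gene when its detection call is in \code{allowed} (present or
#' marginal by default) in at least half of the samples. Data without a
#' flags assay pass unfiltered.
#'
#' @param x a [ThermalExpressionSet-class].
#' @param allowed flag labels counting as detected.
#'
#' @return Named logical vector, TRUE = keep.
#' @rdname flagFilter
#' @export
setMethod("flagFilter", "ThermalExpressionSet",
  function(x, allowed = c("present", "marginal")) {
    bad <- setdiff(allowed, .FLAG_LEVELS)
    if (length(bad))
      .stopf("unknown flag label(s): %s", paste(bad, collapse = ", "))
    fl <- detectionFlags(x)
    if (is.null(fl)) {
      keep <- rep(TRUE, nrow(x))
      names(keep) <- rownames(x)
      return(keep)
    }
    keep <- rowMeans(matrix(fl %in% allowed, nrow(fl))) >= 0.5
    names(keep) <- rownames(x)
    keep
  })

# log2 expression matrix regardless of stored scale
.log2exprs <- function(x) {
  e <- assay(x, "exprs")
  if (intensityScale(x) == "linear") log2(e) else e
}

.strainCols <- function(x, strain, condition) {
  cd <- colData(x)
  if (!strain %in% cd$strain) .stopf("unknown strain '%s'", strain)
  which(cd$strain == strain & cd$condition == condition)
}

#' Heat/control fold change per gene
#'
#' Fold change of heat-treated over non-treated control samples of one
#' strain, on the linear scale. The default \code{"geometric"} method is the
#' difference of mean log2 values, back-transformed (the geometric mean of
#' replicates, standard log-scale array practice); \code{"arithmetic"} is the
#' ratio of arithmetic means of linear intensities.
#'
#' @param x a [ThermalExpressionSet-class] (either scale).
#' @param strain strain label with >= 1 control and >= 1 heat sample.
#' @param method \code{"geometric"} (default) or \code{"arithmetic"}.
#'
#' @return Named numeric vector of per-gene fold changes (> 0).
#' @rdname foldChange
#' @export
setMethod("foldChange", "ThermalExpressionSet",
  function(x, strain, method = c("geometric", "arithmetic")) {
    method <- match.arg(method)
    heat <- .strainCols(x, strain, "heat")
    ctrl <- .strainCols(x, strain, "control")
    if (!length(heat) || !length(ctrl))
      .stopf("strain '%s' needs both control and heat samples", strain)
    l2 <- .log2exprs(x)
    if (method == "geometric") {
      fold <- 2^(rowMeans(l2[, heat, drop = FALSE]) -
                   rowMeans(l2[, ctrl, drop = FALSE]))
    } else {
      lin <- 2^l2
      fold <- rowMeans(lin[, heat, drop = FALSE]) /
        rowMeans(lin[, ctrl, drop = FALSE])
    }
    fold
  })

#' Fold-change table across strains
#'
#' Applies [foldChange()] to each strain and optionally attaches per-strain
#' t-test p-values from [differentialPValues()].
#'
#' @param x a [ThermalExpressionSet-class].
#' @param strains strain labels (default: all strains in the data).
#' @param method fold-change method, see [foldChange()].
#' @param pvalues if TRUE, attach t-test p-values (needs >= 2 replicates per
#'   condition).
#'
#' @return A [FoldChangeTable-class].
#' @export
foldChangeTable <- function(x, strains = NULL,
                            method = c("geometric", "arithmetic"),
                            pvalues = FALSE) {
  method <- match.arg(method)
  if (is.null(strains)) strains <- unique(colData(x)$strain)
  folds <- matrix(NA_real_, nrow(x), length(strains),
                  dimnames = list(rownames(x), strains))
  for (s in strains) folds[, s] <- foldChange(x, s, method)
  pv <- NULL
  if (pvalues) {
    pv <- matrix(NA_real_, nrow(x), length(strains),
                 dimnames = list(rownames(x), strains))
    for (s in strains) pv[, s] <- differentialPValues(x, s)
  }
  FoldChangeTable(folds, pv)
}

#' Per-gene two-sample t-test p-values (heat vs control)
#'
#' Classic pooled-variance two-sample t-test on log2 values, computed for
#' every gene of one strain. Degenerate rows with zero pooled variance get
#' p = 1 when the group means are equal (nothing to detect) and p = 0 when
#' they differ (the zero-noise limit of an arbitrarily large t statistic).
#' No multiple-testing correction is applied.
#'
#' @param x a [ThermalExpressionSet-class].
#' @param strain strain label with >= 2 replicates per condition.
#'
#' @return Named numeric vector of p-values.
#' @export
differentialPValues <- function(x, strain) {
  heat <- .strainCols(x, strain, "heat")
  ctrl <- .strainCols(x, strain, "control")
  n1 <- length(heat); n2 <- length(ctrl)
  if (n1 < 2L || n2 < 2L)
    .stopf("t-test undefined: strain '%s' needs >= 2 replicates per condition",
           strain)
  l2 <- .log2exprs(x)
  a <- l2[, heat, drop = FALSE]; b <- l2[, ctrl, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- ifelse(se == 0, ifelse(m1 == m2, 1, 0),
              2 * stats::pt(-abs((m1 - m2) / se), df = n1 + n2 - 2L))
  names(p) <- rownames(x)
  p
}

#' Differential-expression filter
#'
#' Keeps the genes whose heat-vs-control t-test p-value (see
#' [differentialPValues()]) is below \code{alpha} for the given strain.
#'
#' @param x a [ThermalExpressionSet-class].
#' @param strain strain label.
#' @param alpha p-value cutoff (default 0.05).
#'
#' @return Named logical vector, TRUE = keep.
#' @export
differentialFilter <- function(x, strain, alpha = 0.05) {
  differentialPValues(x, strain) < alpha
}

#' Stage 1: heat induction in both the tolerant and the reference strain
#'
#' Selects genes with a linear fold change strictly greater than
#' \code{threshold} in both strains (boundary values fail). With
#' \code{direction = "absolute"}, a fold below \code{1/threshold} also
#' qualifies.
#'
#' @param fc a [FoldChangeTable-class].
#' @param tolerant,reference strain labels present in \code{fc}.
#' @param threshold fold-change cutoff (default 1.5).
#' @param direction \code{"up"} (default, heat induction) or
#'   \code{"absolute"}.
#'
#' @return Character vector of gene ids.
#' @export
screenStage1 <- function(fc, tolerant, reference, threshold = 1.5,
                         direction = c("up", "absolute")) {
  direction <- match.arg(direction)
  f <- foldMatrix(fc)
  miss <- setdiff(c(tolerant, reference), colnames(f))
  if (length(miss)) .stopf("unknown strain(s): %s", paste(miss, collapse = ", "))
  pass1 <- function(v) {
    if (direction == "up") v > threshold else v > threshold | v < 1 / threshold
  }
  rownames(f)[pass1(f[, tolerant]) & pass1(f[, reference])]
}

#' Stage 2: cross-strain fold-change ratio
#'
#' Selects genes whose fold change in the tolerant strain exceeds
#' \code{threshold} times that in the reference strain, or whose reference
#' fold exceeds \code{threshold} times the sensitive strain's (inclusive
#' or) -- i.e. the heat response grows along the tolerance gradient
#' somewhere.
#'
#' @param fc a [FoldChangeTable-class].
#' @param tolerant,reference,sensitive three distinct strain labels in
#'   \code{fc}.
#' @param threshold ratio cutoff (default 1.5), strict.
#'
#' @return Character vector of gene ids.
#' @export
screenStage2 <- function(fc, tolerant, reference, sensitive, threshold = 1.5) {
  f <- foldMatrix(fc)
  strains <- c(tolerant, reference, sensitive)
  if (anyDuplicated(strains)) .stopf("the three strain roles must be distinct")
  miss <- setdiff(strains, colnames(f))
  if (length(miss)) .stopf("unknown strain(s): %s", paste(miss, collapse = ", "))
  rownames(f)[f[, tolerant] / f[, reference] > threshold |
                f[, reference] / f[, sensitive] > threshold]
}

#' Stage 3: rank concordance with the thermotolerance order
#'
#' Selects genes whose fold changes strictly decrease along the tolerance
#' ranking (most tolerant strain has the largest heat induction). Ties fail:
#' perfect rank concordance is required, which for any number of strains
#' equals a Spearman correlation of 1 with the (reversed) order.
#'
#' @param fc a [FoldChangeTable-class].
#' @param toleranceOrder strain labels, most tolerant first, covering all
#'   strains compared.
#'
#' @return Character vector of gene ids.
#' @export
screenStage3 <- function(fc, toleranceOrder) {
  f <- foldMatrix(fc)
  miss <- setdiff(toleranceOrder, colnames(f))
  if (length(miss)) .stopf("unknown strain(s): %s", paste(miss, collapse = ", "))
  if (length(toleranceOrder) < 2L)
    .stopf("'toleranceOrder' needs at least 2 strains")
  f <- f[, toleranceOrder, drop = FALSE]
  mono <- apply(f, 1L, function(v) all(diff(v) < 0))
  rownames(f)[mono]
}

#' Screen configuration
#'
#' Bundles the tunable parameters of [runScreen()]. Defaults follow the
#' original microarray protocol: 75th-percentile shift normalisation,
#' lowest-20% intensity filter, present/marginal detection flags, pooled
#' t-test at alpha 0.05 on the tolerant and reference strains, geometric-mean
#' fold changes, and strict 1.5-fold thresholds for stages 1 and 2. The
#' volcano fold threshold defaults to 1, a no-op on a ratio scale.
#'
#' @param fcThreshold stage-1 fold-change cutoff.
#' @param ratioThreshold stage-2 cross-strain ratio cutoff.
#' @param percentile normalisation percentile.
#' @param lowFraction low-intensity filter fraction in \[0, 1).
#' @param flagAllowed detection flags counting as detected.
#' @param differential apply the t-test filter?
#' @param alpha t-test p-value cutoff.
#' @param volcanoFold extra fold-change magnitude required alongside the
#'   t-test (1 = none).
#' @param fcMethod \code{"geometric"} or \code{"arithmetic"}.
#' @param direction stage-1 direction, \code{"up"} or \code{"absolute"}.
#'
#' @return Named list of parameters.
#' @export
screenConfig <- function(fcThreshold = 1.5, ratioThreshold = 1.5,
                         percentile = 75, lowFraction = 0.2,
                         flagAllowed = c("present", "marginal"),
                         differential = TRUE, alpha = 0.05, volcanoFold = 1,
                         fcMethod = c("geometric", "arithmetic"),
                         direction = c("up", "absolute")) {
  list(
    fcThreshold = fcThreshold, ratioThreshold = ratioThreshold,
    percentile = percentile, lowFraction = lowFraction,
    flagAllowed = flagAllowed, differential = differential, alpha = alpha,
    volcanoFold = volcanoFold, fcMethod = match.arg(fcMethod),
    direction = match.arg(direction)
  )
}

#' Three-stage screen on a prepared fold-change table
#'
#' Runs stages 1-3 on fold changes that are already computed (e.g. a
#' published table), bypassing preprocessing: stage 1 keeps genes induced
#' more than \code{fcThreshold}-fold in both the tolerant and the reference
#' strain; stage 2, evaluated within stage 1, keeps genes whose fold-change
#' ratio tolerant/reference or reference/sensitive exceeds
#' \code{ratioThreshold}; stage 3, within stage 2, keeps genes whose folds
#' strictly decrease along \code{toleranceOrder}.
#'
#' @param fc a [FoldChangeTable-class].
#' @param tolerant,reference,sensitive distinct strain labels.
#' @param fcThreshold,ratioThreshold stage cutoffs (default 1.5, strict).
#' @param toleranceOrder tolerance ranking, most tolerant first; defaults to
#'   \code{c(tolerant, reference, sensitive)}.
#' @param direction stage-1 direction, see [screenStage1()].
#' @param parameters extra entries recorded in the result's parameter list.
#'
#' @return A [ScreenResult-class] with a per-gene audit.
#' @examples
#' res <- screenFoldChanges(yeastHeatShockFolds(),
#'   tolerant = "NFRI3236", reference = "S288C", sensitive = "NFRI3155")
#' stageGenes(res, 3)
#' @export
screenFoldChanges <- function(fc, tolerant, reference, sensitive,
                              fcThreshold = 1.5, ratioThreshold = 1.5,
                              toleranceOrder = c(tolerant, reference, sensitive),
                              direction = c("up", "absolute"),
                              parameters = list()) {
  direction <- match.arg(direction)
  f <- foldMatrix(fc)
  genes <- rownames(f)

  s1 <- screenStage1(fc, tolerant, reference, fcThreshold, direction)
  s2 <- intersect(s1, screenStage2(fc, tolerant, reference, sensitive,
                                   ratioThreshold))
  s3 <- intersect(s2, screenStage3(fc, toleranceOrder))

  audit <- data.frame(
    gene = genes,
    foldTolerant = f[, tolerant],
    foldReference = f[, reference],
    foldSensitive = f[, sensitive],
    ratioTolRef = f[, tolerant] / f[, reference],
    ratioRefSens = f[, reference] / f[, sensitive],
    passStage1 = genes %in% s1,
    passStage2 = genes %in% screenStage2(fc, tolerant, reference, sensitive,
                                         ratioThreshold),
    passStage3 = genes %in% screenStage3(fc, toleranceOrder),
    inStage1 = genes %in% s1,
    inStage2 = genes %in% s2,
    inStage3 = genes %in% s3,
    row.names = NULL
  )
  pv <- fc@pvalues
  if (length(pv))
    for (s in c(tolerant, reference, sensitive))
      audit[[paste0("p", s)]] <- pv[, s]

  new("ScreenResult",
    stage1 = s1, stage2 = s2, stage3 = s3, audit = audit,
    parameters = c(list(
      tolerant = tolerant, reference = reference, sensitive = sensitive,
      fcThreshold = fcThreshold, ratioThreshold = ratioThreshold,
      direction = direction
    ), parameters),
    toleranceOrder = toleranceOrder
  )
}

#' Run the full thermotolerance screen on an expression matrix
#'
#' The complete pipeline on linear-scale intensities:
#' percentile-shift normalisation, detection-flag and low-intensity filters,
#' an optional per-strain t-test filter (applied to the tolerant and
#' reference strains; both must pass), heat/control fold changes per strain,
#' and the three selection stages of [screenFoldChanges()]. The result's
#' audit covers every gene that reached the fold-change stage; stage 3 is
#' always a subset of stage 2, which is a subset of stage 1.
#'
#' @param x a linear-scale [ThermalExpressionSet-class] containing the three
#'   role strains.
#' @param tolerant,reference,sensitive distinct strain labels, ordered most
#'   to least thermotolerant.
#' @param config parameter list from [screenConfig()].
#'
#' @return A [ScreenResult-class].
#' @examples
#' strains <- list(
#'   StrainSpec("T", 0.9, 0.6, 0.4), StrainSpec("R", 0.5, 0.6, 0.35),
#'   StrainSpec("S", 0.2, 0.6, 0.25))
#' sim <- simulateExpressionMatrix(strains, nGenes = 200, nReplicates = 2,
#'   plantedInduction = c(T = 3.7, R = 2.2, S = 1.4), noiseSd = 0.05, seed = 1)
#' res <- runScreen(sim$expression, "T", "R", "S")
#' identical(stageGenes(res, 3), plantedGene(sim$truth))
#' @rdname runScreen
#' @export
setMethod("runScreen", "ThermalExpressionSet",
  function(x, tolerant, reference, sensitive, config = screenConfig()) {
    roles <- c(tolerant, reference, sensitive)
    if (anyDuplicated(roles)) .stopf("the three strain roles must be distinct")
    miss <- setdiff(roles, colData(x)$strain)
    if (length(miss))
      .stopf("strain(s) not in the data: %s", paste(miss, collapse = ", "))

    keep <- flagFilter(x, config$flagAllowed) &
      lowIntensityFilter(x, config$lowFraction)
    norm <- percentileShiftNormalize(x, config$percentile)

    pvals <- NULL
    if (isTRUE(config$differential)) {
      pvals <- vapply(c(tolerant, reference),
                      function(s) differentialPValues(norm, s),
                      numeric(nrow(norm)))
      diffKeep <- rowSums(pvals < config$alpha) == ncol(pvals)
      if (config$volcanoFold > 1) {
        for (s in c(tolerant, reference)) {
          fcs <- foldChange(norm, s, config$fcMethod)
          diffKeep <- diffKeep &
            (fcs > config$volcanoFold | fcs < 1 / config$volcanoFold)
        }
      }
      keep <- keep & diffKeep
    }

    if (!any(keep)) {
      warning("no genes survive preprocessing; returning an empty screen result")
      return(new("ScreenResult",
        stage1 = character(), stage2 = character(), stage3 = character(),
        audit = data.frame(gene = character()),
        parameters = c(config, list(tolerant = tolerant,
                                    reference = reference,
                                    sensitive = sensitive, nCandidates = 0L)),
        toleranceOrder = roles
      ))
    }

    cand <- norm[keep, ]
    fc <- foldChangeTable(cand, strains = roles, method = config$fcMethod)
    res <- screenFoldChanges(fc, tolerant, reference, sensitive,
      fcThreshold = config$fcThreshold,
      ratioThreshold = config$ratioThreshold,
      direction = config$direction,
      parameters = c(config, list(nCandidates = sum(keep)))
    )
    if (!is.null(pvals)) {
      idx <- match(res@audit$gene, rownames(x))
      res@audit$pTolerant <- pvals[idx, 1L]
      res@audit$pReference <- pvals[idx, 2L]
    }
    res
  })
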