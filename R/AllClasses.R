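#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' Strain specification for the synthetic-data generator
#'
#' Describes one yeast strain as the generator sees it: a dimensionless
#' thermotolerance coefficient in \[0, 1\] (1 = fully thermotolerant), specific
#' growth rates at the permissive (30 degC) and elevated temperature (per hour),
#' and the logistic growth-curve parameters (initial and carrying-capacity
#' OD600).
#'
#' @slot name strain label.
#' @slot tolerance thermotolerance coefficient in \[0, 1\].
#' @slot mu30 specific growth rate at 30 degC (1/h), positive.
#' @slot muHot specific growth rate at the high temperature (1/h); must satisfy
#'   \code{0 < muHot <= mu30} (heat never speeds growth up).
#' @slot odInit initial OD600, in (0, odMax).
#' @slot odMax carrying-capacity OD600.
#'
#' @seealso [StrainSpec()] for the constructor.
#' @name StrainSpec-class
#' @aliases StrainSpec-class
#' @exportClass StrainSpec
setClass("StrainSpec",
  slots = c(
    name = "character", tolerance = "numeric",
    mu30 = "numeric", muHot = "numeric",
    odInit = "numeric", odMax = "numeric"
  )
)

setValidity("StrainSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty label")
  for (s in c("tolerance", "mu30", "muHot", "odInit", "odMax")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@tolerance < 0 || object@tolerance > 1)
    msg <- c(msg, "'tolerance' must lie in [0, 1]")
  if (object@mu30 <= 0) msg <- c(msg, "'mu30' must be > 0")
  if (object@muHot <= 0 || object@muHot > object@mu30)
    msg <- c(msg, "'muHot' must satisfy 0 < muHot <= mu30")
  if (object@odInit <= 0 || object@odInit >= object@odMax)
    msg <- c(msg, "'odInit' must satisfy 0 < odInit < odMax")
  if (length(msg)) msg else TRUE
})

#' Create a StrainSpec
#'
#' @param name strain label.
#' @param tolerance thermotolerance coefficient in \[0, 1\].
#' @param mu30 specific growth rate at 30 degC (1/h).
#' @param muHot specific growth rate at the elevated temperature (1/h).
#' @param odInit initial OD600 (default 0.1, the study's inoculation density).
#' @param odMax carrying-capacity OD600 (default 2).
#'
#' @return A [StrainSpec-class] object.
#' @examples
#' StrainSpec("NFRI3236", tolerance = 0.9, mu30 = 0.60, muHot = 0.40)
#' @export
StrainSpec <- function(name, tolerance, mu30, muHot, odInit = 0.1, odMax = 2) {
  new("StrainSpec",
    name = as.character(name), tolerance = as.numeric(tolerance),
    mu30 = as.numeric(mu30), muHot = as.numeric(muHot),
    odInit = as.numeric(odInit), odMax = as.numeric(odMax)
  )
}

#' Ground truth of a synthetic expression experiment
#'
#' Records which gene carries the planted thermotolerance-correlated heat
#' induction, the true heat/control fold planted per strain, the true
#' thermotolerance ranking (most to least tolerant) and the log2-scale noise SD
#' used. The planted induction must strictly increase with tolerance, i.e.
#' strictly decrease along \code{strainOrder}.
#'
#' @slot plantedGene gene identifier of the planted gene.
#' @slot induction named numeric, true heat/control fold per strain.
#' @slot strainOrder strain labels, most tolerant first.
#' @slot noiseSd log2-scale standard deviation of expression noise (>= 0).
#'
#' @name SyntheticTruth-class
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(
    plantedGene = "character", induction = "numeric",
    strainOrder = "character", noiseSd = "numeric"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (length(object@plantedGene) != 1L)
    msg <- c(msg, "'plantedGene' must be a single gene id")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be a single number >= 0")
  if (is.null(names(object@induction)) ||
      !setequal(names(object@induction), object@strainOrder))
    msg <- c(msg, "'induction' must be named by exactly the strains in 'strainOrder'")
  else {
    ind <- object@induction[object@strainOrder]
    if (any(diff(ind) >= 0))
      msg <- c(msg, "planted induction must strictly decrease along the tolerance ranking")
  }
  if (anyDuplicated(object@strainOrder))
    msg <- c(msg, "'strainOrder' must not contain duplicate strains")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticTruth-class identifier of the planted gene.
#' @param x,object a \code{SyntheticTruth}.
#' @export
plantedGene <- function(x) x@plantedGene

#' @describeIn SyntheticTruth-class named per-strain true induction folds.
#' @export
plantedInduction <- function(x) x@induction

#' @describeIn SyntheticTruth-class true tolerance ranking, most tolerant first.
#' @export
strainOrder <- function(x) x@strainOrder

#' One OD600 growth curve
#'
#' Optical-density time series for one strain at one temperature. Times are in
#' hours and strictly increasing; OD600 readings are strictly positive.
#'
#' @slot strain strain label.
#' @slot temperature temperature label (e.g. \code{"30C"}, \code{"39C"},
#'   or the generator's \code{"low"}/\code{"high"}).
#' @slot times sampling times (h), strictly increasing, length >= 2.
#' @slot od OD600 values, positive, same length as \code{times}.
#'
#' @seealso [GrowthCurve()], [doublingTime()], [selectLinearPhase()]
#' @name GrowthCurve-class
#' @aliases GrowthCurve-class
#' @exportClass GrowthCurve
setClass("GrowthCurve",
  slots = c(
    strain = "character", temperature = "character",
    times = "numeric", od = "numeric"
  )
)

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@times) < 2L)
    msg <- c(msg, "a growth curve needs at least 2 time points")
  if (length(object@times) != length(object@od))
    msg <- c(msg, "'times' and 'od' must have equal length")
  if (any(!is.finite(object@times)) || any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be finite and strictly increasing")
  if (any(!is.finite(object@od)) || any(object@od <= 0))
    msg <- c(msg, "'od' values must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Create a GrowthCurve
#'
#' @param strain strain label.
#' @param temperature temperature label.
#' @param times sampling times in hours, strictly increasing.
#' @param od OD600 readings, positive.
#' @return A [GrowthCurve-class] object.
#' @examples
#' GrowthCurve("S288C", "30C", times = c(0, 1, 2, 3), od = c(0.1, 0.2, 0.4, 0.8))
#' @export
GrowthCurve <- function(strain, temperature, times, od) {
  new("GrowthCurve",
    strain = as.character(strain), temperature = as.character(temperature),
    times = as.numeric(times), od = as.numeric(od)
  )
}

#' Doubling-time estimate
#'
#' Result of [doublingTime()]: the doubling time T_d in hours, the index window
#' of the curve used, the coefficient of determination of the log2(OD)-vs-time
#' fit on that window, and the estimation mode (\code{"regression"} for the
#' log-linear least-squares fit, \code{"two-point"} for the classical two-point
#' formula \eqn{T_d = (t_2 - t_1) / \log_2(OD_2/OD_1)}).
#'
#' @slot strain,temperature labels copied from the input curve.
#' @slot td doubling time in hours (> 0).
#' @slot window integer start/end indices of the points used.
#' @slot r2 coefficient of determination of log2(OD) vs time on the window.
#' @slot mode \code{"regression"} or \code{"two-point"}.
#'
#' @name DoublingTimeEstimate-class
#' @aliases DoublingTimeEstimate-class
#' @exportClass DoublingTimeEstimate
setClass("DoublingTimeEstimate",
  slots = c(
    strain = "character", temperature = "character",
    td = "numeric", window = "integer", r2 = "numeric", mode = "character"
  )
)

setValidity("DoublingTimeEstimate", function(object) {
  msg <- character()
  if (length(object@td) != 1L || !is.finite(object@td) || object@td <= 0)
    msg <- c(msg, "'td' must be a single positive number")
  if (length(object@window) != 2L || diff(object@window) < 1L)
    msg <- c(msg, "'window' must span at least 2 points")
  if (length(object@r2) != 1L || object@r2 < 0 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (!object@mode %in% c("regression", "two-point"))
    msg <- c(msg, "'mode' must be 'regression' or 'two-point'")
  if (length(msg)) msg else TRUE
})

#' @describeIn DoublingTimeEstimate-class the doubling time in hours.
#' @param x a \code{DoublingTimeEstimate}.
#' @export
tdHours <- function(x) x@td

#' @describeIn DoublingTimeEstimate-class R^2 of the log-linear fit.
#' @export
fitQuality <- function(x) x@r2

#' Expression data for the thermotolerance screen
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose columns are
#' arrays/samples annotated with \code{strain}, \code{condition}
#' (\code{"control"} or \code{"heat"}) and \code{replicate}, and whose
#' \code{"exprs"} assay holds probe intensities. The metadata entry
#' \code{scale} records whether intensities are on the \code{"linear"}
#' (strictly positive) or \code{"log2"} scale. An optional \code{"flags"}
#' assay carries per-gene-per-sample detection calls
#' (\code{"present"}, \code{"marginal"}, \code{"absent"}).
#'
#' Every strain must have at least one control and one heat sample, so that a
#' heat/control fold change is defined for every strain.
#'
#' @seealso [ThermalExpressionSet()], [runScreen()]
#' @name ThermalExpressionSet-class
#' @aliases ThermalExpressionSet-class
#' @exportClass ThermalExpressionSet
setClass("ThermalExpressionSet", contains = "SummarizedExperiment")

.FLAG_LEVELS <- c("present", "marginal", "absent")

setValidity("ThermalExpressionSet", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("strain", "condition", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData must contain column(s): %s", paste(miss, collapse = ", ")))
  if (!all(cd$condition %in% c("control", "heat")))
    msg <- c(msg, "'condition' must be 'control' or 'heat'")
  else {
    tab <- table(cd$strain, cd$condition)
    if (!all(c("control", "heat") %in% colnames(tab)) || any(tab == 0))
      msg <- c(msg, "every strain needs at least one control and one heat sample")
  }
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "an assay named 'exprs' is required")
  else {
    sc <- intensityScale(object)
    if (!sc %in% c("linear", "log2"))
      msg <- c(msg, "metadata 'scale' must be 'linear' or 'log2'")
    e <- assay(object, "exprs")
    if (any(!is.finite(e)))
      msg <- c(msg, "'exprs' must be finite")
    else if (identical(sc, "linear") && any(e <= 0))
      msg <- c(msg, "linear-scale intensities must be strictly positive")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if ("flags" %in% assayNames(object)) {
    fl <- assay(object, "flags")
    if (!all(fl %in% .FLAG_LEVELS))
      msg <- c(msg, sprintf("detection flags must be one of: %s",
                            paste(.FLAG_LEVELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThermalExpressionSet
#'
#' @param exprs numeric matrix, genes x samples, with unique rownames (gene
#'   ids). Strictly positive when \code{scale = "linear"}.
#' @param strain,condition,replicate per-sample annotations
#'   (\code{condition} in \code{"control"}/\code{"heat"}).
#' @param flags optional character matrix of detection calls
#'   (\code{"present"}, \code{"marginal"}, \code{"absent"}), same dimensions
#'   as \code{exprs}.
#' @param scale \code{"linear"} (default) or \code{"log2"}.
#'
#' @return A [ThermalExpressionSet-class].
#' @examples
#' m <- matrix(2^rnorm(40, 8), 10, 4,
#'   dimnames = list(paste0("G", 1:10), paste0("s", 1:4)))
#' tes <- ThermalExpressionSet(m,
#'   strain = rep("S288C", 4),
#'   condition = c("control", "control", "heat", "heat"),
#'   replicate = c(1, 2, 1, 2))
#' @export
ThermalExpressionSet <- function(exprs, strain, condition, replicate,
                                 flags = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste(strain, condition, replicate, sep = "_")
  assays <- list(exprs = exprs)
  if (!is.null(flags)) {
    flags <- as.matrix(flags)
    dimnames(flags) <- dimnames(exprs)
    assays$flags <- flags
  }
  cd <- DataFrame(
    strain = as.character(strain), condition = as.character(condition),
    replicate = as.character(replicate), row.names = colnames(exprs)
  )
  se <- SummarizedExperiment(assays = assays, colData = cd)
  obj <- new("ThermalExpressionSet", se)
  metadata(obj)$scale <- scale
  validObject(obj)
  obj
}

#' @describeIn ThermalExpressionSet-class the intensity scale flag
#'   (\code{"linear"} or \code{"log2"}).
#' @param x a \code{ThermalExpressionSet}.
#' @export
intensityScale <- function(x) {
  sc <- metadata(x)$scale
  if (is.null(sc)) "linear" else sc
}

#' @describeIn ThermalExpressionSet-class per-sample annotation as a
#'   data.frame (sample, strain, condition, replicate).
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample = rownames(cd), cd, row.names = NULL)
}

#' @describeIn ThermalExpressionSet-class detection-flag matrix, or NULL when
#'   the data carry no flags.
#' @export
detectionFlags <- function(x) {
  if ("flags" %in% assayNames(x)) assay(x, "flags") else NULL
}

#' Per-gene, per-strain heat/control fold changes
#'
#' Linear-scale fold changes (heat over non-treated control), one row per gene
#' and one column per strain, with optional per-gene-per-strain t-test
#' p-values.
#'
#' @slot folds numeric matrix, genes x strains, strictly positive.
#' @slot pvalues numeric matrix of the same shape (0 x 0 when absent).
#'
#' @seealso [FoldChangeTable()], [foldChangeTable()], [screenFoldChanges()]
#' @name FoldChangeTable-class
#' @aliases FoldChangeTable-class
#' @exportClass FoldChangeTable
setClass("FoldChangeTable",
  slots = c(folds = "matrix", pvalues = "matrix")
)

setValidity("FoldChangeTable", function(object) {
  msg <- character()
  f <- object@folds
  if (is.null(rownames(f)) || is.null(colnames(f)))
    return("'folds' must have gene rownames and strain colnames")
  if (anyDuplicated(rownames(f)))
    msg <- c(msg, "duplicate gene ids in 'folds'")
  if (anyDuplicated(colnames(f)))
    msg <- c(msg, "duplicate strain labels in 'folds'")
  if (any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "fold changes must be finite and > 0")
  p <- object@pvalues
  if (length(p) && !identical(dim(p), dim(f)))
    msg <- c(msg, "'pvalues' must match the shape of 'folds'")
  if (length(msg)) msg else TRUE
})

#' Create a FoldChangeTable
#'
#' @param folds numeric matrix (genes x strains) of linear heat/control fold
#'   changes, with rownames and colnames; or a data.frame whose first column
#'   is the gene id.
#' @param pvalues optional matching matrix of t-test p-values.
#' @return A [FoldChangeTable-class].
#' @examples
#' FoldChangeTable(matrix(c(3.68, 2.18, 1.35), 1,
#'   dimnames = list("FMP21", c("NFRI3236", "S288C", "NFRI3155"))))
#' @export
FoldChangeTable <- function(folds, pvalues = NULL) {
  if (is.data.frame(folds)) {
    genes <- as.character(folds[[1L]])
    folds <- as.matrix(folds[, -1L, drop = FALSE])
    rownames(folds) <- genes
  }
  new("FoldChangeTable",
    folds = folds,
    pvalues = if (is.null(pvalues)) matrix(numeric(), 0, 0) else pvalues
  )
}

#' @describeIn FoldChangeTable-class the fold-change matrix.
#' @param x a \code{FoldChangeTable}.
#' @export
foldMatrix <- function(x) x@folds

#' @describeIn FoldChangeTable-class strain labels (column names).
#' @export
strainNames <- function(x) colnames(x@folds)

#' Result of the three-stage thermotolerance screen
#'
#' Gene sets surviving each stage (stage 3 is a subset of stage 2, which is a
#' subset of stage 1), a per-gene audit table recording every computed quantity
#' and per-stage pass/fail, the parameters used, and the tolerance ordering the
#' rank-concordance stage was run against.
#'
#' @slot stage1,stage2,stage3 character vectors of surviving gene ids.
#' @slot audit data.frame with one row per gene tested.
#' @slot parameters named list of thresholds and modes used.
#' @slot toleranceOrder strain labels, most tolerant first.
#'
#' @seealso [runScreen()], [screenFoldChanges()]
#' @name ScreenResult-class
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
  slots = c(
    stage1 = "character", stage2 = "character", stage3 = "character",
    audit = "data.frame", parameters = "list", toleranceOrder = "character"
  )
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (!all(object@stage2 %in% object@stage1))
    msg <- c(msg, "stage2 genes must be a subset of stage1")
  if (!all(object@stage3 %in% object@stage2))
    msg <- c(msg, "stage3 genes must be a subset of stage2")
  if (nrow(object@audit) &&
      !all(c(object@stage1, object@stage2, object@stage3) %in% object@audit$gene))
    msg <- c(msg, "audit must cover every selected gene")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenResult-class genes surviving a given stage (default the
#'   final stage 3).
#' @param x a \code{ScreenResult}.
#' @param stage 1, 2 or 3.
#' @export
stageGenes <- function(x, stage = 3) {
  stopifnot(stage %in% 1:3)
  slot(x, paste0("stage", stage))
}

#' @describeIn ScreenResult-class the per-gene audit data.frame.
#' @export
screenAudit <- function(x) x@audit

#' @describeIn ScreenResult-class the parameter list the screen ran with.
#' @export
screenParameters <- function(x) x@parameters

#' qPCR external standard curve
#'
#' Least-squares line of quantification cycle (Cq) versus log10 of relative
#' template concentration from a serial dilution of purified PCR product.
#' A valid assay has negative slope; the amplification efficiency is
#' \eqn{E = 10^{-1/slope} - 1} (1 = perfect doubling each cycle, giving a
#' slope of \eqn{-1/\log_{10} 2 \approx -3.3219} cycles per decade).
#'
#' @slot gene target gene label.
#' @slot slope cycles per log10(concentration), negative.
#' @slot intercept Cq at relative concentration 1.
#' @slot efficiency amplification efficiency, > 0.
#' @slot r2 coefficient of determination of the fit.
#'
#' @seealso [fitStandardCurve()], [quantifyCq()]
#' @name StandardCurve-class
#' @aliases StandardCurve-class
#' @exportClass StandardCurve
setClass("StandardCurve",
  slots = c(
    gene = "character", slope = "numeric", intercept = "numeric",
    efficiency = "numeric", r2 = "numeric"
  )
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (!is.finite(object@slope) || object@slope >= 0)
    msg <- c(msg, "'slope' must be finite and negative")
  if (!is.finite(object@efficiency) || object@efficiency <= 0)
    msg <- c(msg, "'efficiency' must be > 0")
  if (object@r2 < 0 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn StandardCurve-class amplification efficiency
#'   \eqn{10^{-1/slope} - 1}.
#' @param x a \code{StandardCurve}.
#' @export
amplificationEfficiency <- function(x) x@efficiency

#' @describeIn StandardCurve-class slope in cycles per decade of concentration.
#' @export
curveSlope <- function(x) x@slope

#' Phenotype-expression regression fit
#'
#' Ordinary least squares of the qPCR expression ratio (heat/control) on the
#' doubling-time ratio T_d(30 degC)/T_d(high) across strains, the study's
#' thermotolerance phenotype. Reports slope, intercept, the coefficient of
#' determination R^2, the strain count, and flags fits on the minimal n = 3
#' strain cohort.
#'
#' @slot gene,temperature labels.
#' @slot slope,intercept OLS coefficients.
#' @slot r2 coefficient of determination in \[0, 1\].
#' @slot n number of strains.
#' @slot pvalue p-value of the slope (verbose output; not the headline result).
#' @slot lowN TRUE when n == 3.
#'
#' @seealso [fitPhenotypeRegression()]
#' @name PhenotypeFit-class
#' @aliases PhenotypeFit-class
#' @exportClass PhenotypeFit
setClass("PhenotypeFit",
  slots = c(
    gene = "character", temperature = "character",
    slope = "numeric", intercept = "numeric", r2 = "numeric",
    n = "integer", pvalue = "numeric", lowN = "logical"
  )
)

setValidity("PhenotypeFit", function(object) {
  msg <- character()
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (object@n < 3L)
    msg <- c(msg, "a reported fit needs n >= 3 strains")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhenotypeFit-class the coefficient of determination.
#' @param x a \code{PhenotypeFit}.
#' @export
rSquared <- function(x) x@r2
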