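#' Fit a qPCR external standard curve
#'
#' Least-squares line of Cq versus log10(relative concentration) over a
#' serial dilution of purified PCR product. The amplification efficiency is
#' \eqn{E = 10^{-1/slope} - 1}; a perfect assay doubles the template every
#' cycle (E = 1, slope \eqn{-1/\log_{10}2 \approx -3.3219}).
#'
#' @param series data.frame with columns \code{concentration} (relative, in
#'   (0, 1\], distinct) and \code{cq} (cycles); >= 3 points. The
#'   \code{standards} element of [simulateQpcr()] has this shape.
#' @param gene target gene label recorded on the curve.
#'
#' @return A [StandardCurve-class].
#' @examples
#' std <- simulateQpcr(1, efficiency = 1, cqNoiseSd = 0)$standards
#' curveSlope(fitStandardCurve(std))  # -1/log10(2)
#' @export
fitStandardCurve <- function(series, gene = "target") {
  stopifnot(is.data.frame(series),
            all(c("concentration", "cq") %in% names(series)))
  conc <- series$concentration
  cq <- series$cq
  if (length(conc) < 3L)
    .stopf("a standard curve needs at least 3 dilution points")
  if (any(!is.finite(conc)) || any(conc <= 0))
    .stopf("standard concentrations must be positive")
  if (anyDuplicated(conc))
    .stopf("standard concentrations must be distinct (average technical replicates first)")
  if (any(!is.finite(cq)))
    .stopf("Cq values must be finite")

  lc <- log10(conc)
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    .stopf("invalid assay: Cq must decrease with template concentration (slope = %.4g)",
           slope)
  r2 <- .linearR2(lc, cq)
  new("StandardCurve",
    gene = as.character(gene), slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    efficiency = 10^(-1 / slope) - 1, r2 = r2
  )
}

#' Read a relative concentration off a standard curve
#'
#' Inverts the fitted line: \eqn{c = 10^{(Cq - intercept)/slope}}. Strictly
#' decreasing in Cq; at \code{cq == intercept} the concentration is 1 by
#' construction. At zero measurement noise this is the exact inverse of the
#' amplification model used by [simulateQpcr()].
#'
#' @param cq Cq value(s) in cycles.
#' @param curve a [StandardCurve-class].
#'
#' @return Relative concentration(s), positive.
#' @export
quantifyCq <- function(cq, curve) {
  stopifnot(is(curve, "StandardCurve"))
  10^((cq - curve@intercept) / curve@slope)
}

#' Reference-normalised expression rate
#'
#' Expression rate of the target gene relative to the reference gene (ACT1
#' in the original assay): \code{target / reference}. A common rescaling of
#' both concentrations cancels, which is what makes rates comparable across
#' samples.
#'
#' @param targetConc,referenceConc relative concentrations, > 0.
#' @return The dimensionless rate.
#' @export
normalizedRate <- function(targetConc, referenceConc) {
  if (any(!is.finite(targetConc)) || any(targetConc <= 0))
    .stopf("'targetConc' must be > 0")
  if (any(!is.finite(referenceConc)) || any(referenceConc <= 0))
    .stopf("'referenceConc' must be > 0")
  targetConc / referenceConc
}

#' Heat/control expression ratio
#'
#' Ratio of the reference-normalised expression rate after heat treatment to
#' that in the non-treated control.
#'
#' @param heatRate,controlRate expression rates (> 0), e.g. from
#'   [normalizedRate()].
#' @return The dimensionless ratio.
#' @export
expressionRatio <- function(heatRate, controlRate) {
  if (any(!is.finite(heatRate)) || any(heatRate <= 0) ||
      any(!is.finite(controlRate)) || any(controlRate <= 0))
    .stopf("expression rates must be > 0")
  heatRate / controlRate
}

#' Delta-delta-Cq expression ratio (comparative mode)
#'
#' The standard-curve-free shortcut: with target and reference efficiencies
#' \eqn{E_t, E_r}, the heat/control ratio is
#' \deqn{(1+E_t)^{-\Delta Cq_{target}} / (1+E_r)^{-\Delta Cq_{ref}}}
#' with \eqn{\Delta Cq = Cq_{heat} - Cq_{control}}. Provided for comparison
#' with the external-standard-curve route, which is the primary mode.
#'
#' @param cqTargetHeat,cqTargetControl target-gene Cq values.
#' @param cqRefHeat,cqRefControl reference-gene Cq values.
#' @param effTarget,effRef amplification efficiencies in (0, 1].
#' @return The dimensionless heat/control expression ratio.
#' @export
deltaDeltaCqRatio <- function(cqTargetHeat, cqTargetControl,
                              cqRefHeat, cqRefControl,
                              effTarget = 1, effRef = 1) {
  if (any(c(effTarget, effRef) <= 0) || any(c(effTarget, effRef) > 1))
    .stopf("efficiencies must lie in (0, 1]")
  (1 + effTarget)^(-(cqTargetHeat - cqTargetControl)) /
    (1 + effRef)^(-(cqRefHeat - cqRefControl))
}

#' Reference-gene stability check
#'
#' Compares the heat/control expression ratios of the primary reference gene
#' (ACT1) with those of a second accepted reference (ALG9) across matched
#' conditions. A stable primary reference has ACT1/ALG9 ratio near 1
#' everywhere; the check passes when |log2(ratio)| stays within
#' \code{tolerance} in every condition.
#'
#' @param refRatios expression ratios of the primary reference gene.
#' @param altRatios paired ratios of the comparison reference gene.
#' @param condition optional labels of the paired conditions.
#' @param tolerance |log2| bound (default 0.5, i.e. within 1.41-fold).
#'
#' @return A list: \code{perCondition} data.frame (condition, ratio, log2),
#'   \code{log2Mean}, \code{log2Sd}, \code{tolerance}, \code{pass}.
#' @examples
#' referenceStability(c(1.0, 1.1), c(1.0, 1.0))$pass
#' @export
referenceStability <- function(refRatios, altRatios, condition = NULL,
                               tolerance = 0.5) {
  if (length(refRatios) != length(altRatios))
    .stopf("reference and comparison ratios must be paired (equal length)")
  if (any(refRatios <= 0) || any(altRatios <= 0))
    .stopf("expression ratios must be > 0")
  if (is.null(condition)) condition <- paste0("condition", seq_along(refRatios))
  r <- refRatios / altRatios
  l2 <- log2(r)
  list(
    perCondition = data.frame(condition = condition, ratio = r, log2 = l2),
    log2Mean = mean(l2),
    log2Sd = stats::sd(l2),
    tolerance = tolerance,
    pass = all(abs(l2) <= tolerance)
  )
}

#' Relative quantification of a Cq table
#'
#' Convenience pipeline over one long-format Cq table: fits a standard curve
#' per gene from the \code{role == "standard"} rows (averaging technical
#' replicates per dilution), quantifies the unknown samples, normalises each
#' sample's target genes by the reference gene, and forms heat/control
#' expression ratios per gene and strain.
#'
#' @param cqTable data.frame with columns \code{gene}, \code{sample},
#'   \code{cq}, \code{role} (\code{"standard"}/\code{"unknown"}); standards
#'   additionally need \code{dilution}, unknowns \code{strain} and
#'   \code{condition} (\code{"control"}/\code{"heat"}).
#' @param reference reference gene label (default \code{"ACT1"}).
#'
#' @return A list: \code{curves} (per-gene [StandardCurve-class]),
#'   \code{rates} (data.frame gene, sample, strain, condition, rate),
#'   \code{ratios} (data.frame gene, strain, ratio).
#' @export
qpcrRelativeExpression <- function(cqTable, reference = "ACT1") {
  need <- c("gene", "sample", "cq", "role")
  stopifnot(is.data.frame(cqTable), all(need %in% names(cqTable)))
  std <- cqTable[cqTable$role == "standard", ]
  unk <- cqTable[cqTable$role == "unknown", ]
  if (!nrow(std)) .stopf("no standard rows in the Cq table")
  if (!reference %in% unk$gene)
    .stopf("reference gene '%s' has no unknown measurements", reference)

  curves <- lapply(split(std, std$gene), function(d) {
    agg <- stats::aggregate(cq ~ dilution, d, mean)
    fitStandardCurve(
      data.frame(concentration = agg$dilution, cq = agg$cq),
      gene = d$gene[1L]
    )
  })

  # mean Cq over technical replicates, then quantify
  unkAgg <- stats::aggregate(cq ~ gene + sample + strain + condition, unk, mean)
  unkAgg$conc <- mapply(function(g, cq) {
    if (is.null(curves[[g]])) .stopf("no standard curve for gene '%s'", g)
    quantifyCq(cq, curves[[g]])
  }, unkAgg$gene, unkAgg$cq)

  refConc <- unkAgg[unkAgg$gene == reference,
                    c("sample", "conc")]
  rates <- unkAgg[unkAgg$gene != reference, ]
  idx <- match(rates$sample, refConc$sample)
  if (anyNA(idx))
    .stopf("reference gene missing in sample(s): %s",
           paste(unique(rates$sample[is.na(idx)]), collapse = ", "))
  rates$rate <- normalizedRate(rates$conc, refConc$conc[idx])

  ratioRows <- do.call(rbind, lapply(
    split(rates, list(rates$gene, rates$strain), drop = TRUE),
    function(d) {
      h <- d$rate[d$condition == "heat"]
      c0 <- d$rate[d$condition == "control"]
      if (!length(h) || !length(c0)) return(NULL)
      data.frame(gene = d$gene[1L], strain = d$strain[1L],
                 ratio = expressionRatio(exp(mean(log(h))), exp(mean(log(c0)))))
    }))
  rownames(ratioRows) <- NULL
  list(curves = curves,
       rates = rates[, c("gene", "sample", "strain", "condition", "rate")],
       ratios = ratioRows)
}
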