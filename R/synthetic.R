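#' Simulate an OD600 growth curve
#'
#' Generates a logistic growth trajectory
#' \deqn{OD(t) = \frac{K \, OD_0 e^{\mu t}}{K + OD_0 (e^{\mu t} - 1)}}
#' with growth rate \eqn{\mu} chosen by temperature (\code{mu30} at
#' \code{"low"}, \code{muHot} at \code{"high"}), plus additive Gaussian OD
#' noise truncated away from zero so every reading stays positive. Setting
#' \code{odMax} very large recovers pure exponential growth
#' \eqn{OD_0 e^{\mu t}}, the regime in which the doubling time equals
#' \eqn{\ln 2 / \mu}.
#'
#' @param strain a [StrainSpec-class].
#' @param temperature \code{"low"} (30 degC) or \code{"high"}.
#' @param times sampling times in hours, strictly increasing, non-negative.
#' @param noiseSd SD of additive OD noise (OD600 units), >= 0.
#' @param seed integer seed; identical inputs and seed reproduce the curve
#'   bit for bit.
#'
#' @return A [GrowthCurve-class].
#' @examples
#' s <- StrainSpec("A", tolerance = 0.8, mu30 = 0.6, muHot = 0.4)
#' simulateGrowthCurve(s, "high", times = 0:8, noiseSd = 0)
#' @export
simulateGrowthCurve <- function(strain, temperature = c("low", "high"),
                                times, noiseSd = 0.005, seed = 1L) {
  temperature <- match.arg(temperature)
  stopifnot(is(strain, "StrainSpec"))
  if (length(times) == 0L)
    .stopf("'times' must contain at least one time point")
  if (any(!is.finite(times)) || any(times < 0) ||
      (length(times) > 1L && any(diff(times) <= 0)))
    .stopf("'times' must be non-negative and strictly increasing")
  if (!is.finite(noiseSd) || noiseSd < 0)
    .stopf("'noiseSd' must be >= 0")

  mu <- if (temperature == "low") strain@mu30 else strain@muHot
  K <- strain@odMax
  od0 <- strain@odInit
  g <- exp(mu * times)
  od <- K * od0 * g / (K + od0 * (g - 1))
  if (noiseSd > 0) {
    set.seed(streamSeed(seed, paste("growth", strain@name, temperature,
                                    sep = "|")))
    od <- pmax(od + stats::rnorm(length(od), 0, noiseSd), 1e-6)
  }
  GrowthCurve(strain@name, temperature, times, od)
}

#' Simulate an expression matrix with a planted thermotolerance gene
#'
#' Builds a control and a heat sample group (\code{nReplicates} biological
#' replicates each, the study design uses duplicates) for every strain. Each
#' gene has a baseline log2 abundance drawn once and shared across all
#' samples; background genes therefore have expected heat/control fold change
#' 1. One gene -- the planted gene -- has its heat samples shifted by
#' \code{log2(plantedInduction[strain])}, so its true fold change per strain is
#' the planted induction. Multiplicative log-normal noise
#' (i.i.d. N(0, \code{noiseSd}) on the log2 scale) is added to every
#' measurement.
#'
#' The planted induction must strictly increase with strain tolerance: the
#' planted gene is the ground-truth rank-concordant gene the screen should
#' recover. Its baseline is pinned at \code{baselineMean} so the benchmark
#' exercises the screen logic rather than the detection floor of the
#' low-intensity filter.
#'
#' @param strains list of [StrainSpec-class] (>= 2, distinct names and
#'   tolerances).
#' @param nGenes number of genes (>= 2).
#' @param nReplicates biological replicates per strain and condition (>= 2).
#' @param plantedInduction named numeric, true heat/control fold per strain;
#'   must be keyed by every strain and strictly increase with tolerance.
#' @param noiseSd log2-scale noise SD, >= 0.
#' @param seed integer seed.
#' @param baselineMean,baselineSd log2-scale distribution of gene baselines.
#'
#' @return A list with elements \code{expression}
#'   (a [ThermalExpressionSet-class], linear scale) and \code{truth}
#'   (a [SyntheticTruth-class]).
#' @examples
#' strains <- list(
#'   StrainSpec("NFRI3236", 0.9, 0.60, 0.40),
#'   StrainSpec("S288C",    0.5, 0.52, 0.33),
#'   StrainSpec("NFRI3155", 0.2, 0.54, 0.24))
#' sim <- simulateExpressionMatrix(strains,
#'   nGenes = 100, nReplicates = 2,
#'   plantedInduction = c(NFRI3236 = 3.68, S288C = 2.18, NFRI3155 = 1.35),
#'   noiseSd = 0.1, seed = 7)
#' plantedGene(sim$truth)
#' @export
simulateExpressionMatrix <- function(strains, nGenes = 1000L, nReplicates = 2L,
                                     plantedInduction, noiseSd = 0.1,
                                     seed = 1L, baselineMean = 8,
                                     baselineSd = 2) {
  if (length(strains) < 2L)
    .stopf("the cross-strain screen needs at least 2 strains")
  stopifnot(all(vapply(strains, is, logical(1), "StrainSpec")))
  names <- unname(vapply(strains, function(s) s@name, character(1)))
  tol <- unname(vapply(strains, function(s) s@tolerance, numeric(1)))
  if (anyDuplicated(names)) .stopf("strain names must be distinct")
  if (anyDuplicated(tol)) .stopf("strain tolerances must be distinct")
  if (nGenes < 2L) .stopf("'nGenes' must be >= 2")
  if (nReplicates < 2L) .stopf("'nReplicates' must be >= 2")
  if (!all(names %in% names(plantedInduction)))
    .stopf("'plantedInduction' must be keyed by every strain")
  if (!is.finite(noiseSd) || noiseSd < 0) .stopf("'noiseSd' must be >= 0")
  plantedInduction <- plantedInduction[names]
  ord <- names[order(-tol)]
  if (any(diff(plantedInduction[ord]) >= 0))
    .stopf("'plantedInduction' must strictly increase with strain tolerance")

  set.seed(streamSeed(seed, "expression"))
  geneIds <- sprintf("G%05d", seq_len(nGenes))
  baseline <- stats::rnorm(nGenes, baselineMean, baselineSd)
  planted <- sample.int(nGenes, 1L)
  baseline[planted] <- baselineMean

  nSamp <- 2L * nReplicates * length(names)
  l2 <- matrix(NA_real_, nGenes, nSamp)
  strainCol <- condCol <- repCol <- character(nSamp)
  j <- 0L
  for (s in names) {
    for (cond in c("control", "heat")) {
      for (r in seq_len(nReplicates)) {
        j <- j + 1L
        mu <- baseline
        if (cond == "heat")
          mu[planted] <- mu[planted] + log2(plantedInduction[[s]])
        l2[, j] <- mu + stats::rnorm(nGenes, 0, noiseSd)
        strainCol[j] <- s
        condCol[j] <- cond
        repCol[j] <- paste0("r", r)
      }
    }
  }
  rownames(l2) <- geneIds
  colnames(l2) <- paste(strainCol, condCol, repCol, sep = "_")

  tes <- ThermalExpressionSet(2^l2, strain = strainCol, condition = condCol,
                              replicate = repCol, scale = "linear")
  truth <- new("SyntheticTruth",
    plantedGene = geneIds[planted],
    induction = plantedInduction,
    strainOrder = ord,
    noiseSd = noiseSd
  )
  validObject(truth)
  list(expression = tes, truth = truth)
}

#' Simulate qPCR measurements and a serial-dilution standard series
#'
#' The quantification cycle follows the amplification model
#' \deqn{Cq(c) = Cq_0 - \frac{\log c}{\log(1 + E)}}
#' where \eqn{E} is the amplification efficiency (1 = perfect doubling: one
#' extra cycle per halving of template). The standard series measures the
#' 10-fold dilutions of the purified product (1/10 to 1/10000 by default);
#' technical replicates (duplicates by default) are averaged per dilution,
#' the aggregation also applied to unknowns.
#'
#' @param trueConc relative concentration of the unknown, > 0.
#' @param efficiency amplification efficiency in (0, 1].
#' @param cq0 cycles at relative concentration 1.
#' @param dilutionFactors dilutions of the standard, positive and distinct.
#' @param cqNoiseSd SD of Cq measurement noise in cycles, >= 0.
#' @param nReplicates technical replicates averaged per measurement (>= 1).
#' @param seed integer seed.
#'
#' @return A list with \code{standards} (data.frame: concentration, cq) and
#'   \code{cq}, the replicate-averaged Cq of the unknown.
#' @examples
#' simulateQpcr(0.5, efficiency = 1, cq0 = 20, cqNoiseSd = 0)$cq  # 21 cycles
#' @export
simulateQpcr <- function(trueConc, efficiency = 1, cq0 = 20,
                         dilutionFactors = c(1e-1, 1e-2, 1e-3, 1e-4),
                         cqNoiseSd = 0, nReplicates = 2L, seed = 1L) {
  if (!is.finite(trueConc) || trueConc <= 0)
    .stopf("'trueConc' must be > 0")
  if (!is.finite(efficiency) || efficiency <= 0 || efficiency > 1)
    .stopf("'efficiency' must lie in (0, 1]")
  if (any(!is.finite(dilutionFactors)) || any(dilutionFactors <= 0))
    .stopf("'dilutionFactors' must be positive")
  if (anyDuplicated(dilutionFactors))
    .stopf("'dilutionFactors' must be distinct")
  if (!is.finite(cqNoiseSd) || cqNoiseSd < 0)
    .stopf("'cqNoiseSd' must be >= 0")
  if (nReplicates < 1L) .stopf("'nReplicates' must be >= 1")

  cqModel <- function(c) cq0 - log(c) / log(1 + efficiency)
  set.seed(streamSeed(seed, "qpcr"))
  measure <- function(c) {
    mean(cqModel(c) + stats::rnorm(nReplicates, 0, cqNoiseSd))
  }
  standards <- data.frame(
    concentration = dilutionFactors,
    cq = vapply(dilutionFactors, measure, numeric(1))
  )
  list(standards = standards, cq = measure(trueConc))
}

#' Simulate a strain cohort for phenotype-expression regression
#'
#' Generates per-strain (doubling-time ratio, expression ratio) pairs from the
#' linear model \eqn{y = a + b x + \epsilon} with the noise SD chosen so the
#' population coefficient of determination equals \code{r2pop}:
#' \eqn{\sigma^2 = b^2 \mathrm{Var}(x) (1 - R^2) / R^2}, with Var(x) the
#' population variance of the fixed design points. T_d ratios span the range
#' observed in yeast panels grown at 30 degC versus heat (about 0.4-0.95).
#'
#' @param nStrains number of strains (>= 3; default 8, a typical panel size).
#' @param slope,intercept true regression coefficients.
#' @param r2pop population R^2 in (0, 1).
#' @param tdRatios optional design points; default evenly spaced in
#'   \[0.4, 0.95\].
#' @param seed integer seed.
#'
#' @return data.frame with columns strain, temperature, tdRatio,
#'   expressionRatio.
#' @examples
#' simulatePhenotypeCohort(nStrains = 8, slope = 10, r2pop = 0.8, seed = 3)
#' @export
simulatePhenotypeCohort <- function(nStrains = 8L, slope = 10, intercept = 1,
                                    r2pop = 0.8, tdRatios = NULL, seed = 1L) {
  if (nStrains < 3L) .stopf("'nStrains' must be >= 3")
  if (!is.finite(r2pop) || r2pop <= 0 || r2pop >= 1)
    .stopf("'r2pop' must lie in (0, 1)")
  x <- if (is.null(tdRatios)) seq(0.4, 0.95, length.out = nStrains)
       else as.numeric(tdRatios)
  if (length(x) != nStrains) .stopf("'tdRatios' must have length 'nStrains'")
  varx <- mean((x - mean(x))^2)
  if (varx == 0) .stopf("design points must not be constant")
  sigma <- sqrt(slope^2 * varx * (1 - r2pop) / r2pop)
  set.seed(streamSeed(seed, "phenotype"))
  y <- pmax(intercept + slope * x + stats::rnorm(nStrains, 0, sigma), 0.01)
  data.frame(
    strain = sprintf("S%02d", seq_len(nStrains)),
    temperature = "37C",
    tdRatio = x,
    expressionRatio = y
  )
}
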