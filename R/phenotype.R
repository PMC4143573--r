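#' Regress expression ratios on the thermotolerance phenotype
#'
#' Ordinary least squares of the heat/control expression ratio on the
#' doubling-time ratio T_d(30 degC)/T_d(high) across strains, both on linear
#' scales (set \code{logScale = TRUE} for a log-log fit). The headline
#' statistic is the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, which for a simple regression equals
#' the squared sample correlation. Fits on the minimal three-strain cohort
#' are flagged \code{lowN}.
#'
#' @param observations data.frame with one row per strain and columns
#'   \code{strain}, \code{expressionRatio} (or \code{expression_ratio}) and
#'   \code{tdRatio} (or \code{td_ratio}); >= 3 distinct strains.
#' @param gene,temperature labels recorded on the result.
#' @param logScale fit log(expression ratio) on log(T_d ratio)?
#'
#' @return A [PhenotypeFit-class].
#' @examples
#' obs <- data.frame(strain = paste0("S", 1:5),
#'   tdRatio = c(0.4, 0.5, 0.6, 0.7, 0.8),
#'   expressionRatio = 2 * c(0.4, 0.5, 0.6, 0.7, 0.8) + 1)
#' rSquared(fitPhenotypeRegression(obs))  # 1: collinear points
#' @export
fitPhenotypeRegression <- function(observations, gene = NA_character_,
                                   temperature = NA_character_,
                                   logScale = FALSE) {
  obs <- .normalizeObsNames(observations)
  n <- nrow(obs)
  if (n < 3L) .stopf("regression needs at least 3 strains (got %d)", n)
  if (anyDuplicated(obs$strain)) .stopf("duplicate strain labels")
  if (any(obs$expressionRatio <= 0) || any(obs$tdRatio <= 0))
    .stopf("ratios must be > 0")
  x <- obs$tdRatio
  y <- obs$expressionRatio
  if (logScale) { x <- log(x); y <- log(y) }
  if (stats::sd(x) == 0)
    .stopf("undefined fit: no variance in the doubling-time ratios")

  fit <- stats::lm(y ~ x)
  # summary() warns on residual-free fits; collinear inputs are legitimate here
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::sd(y) == 0) 0 else sm$r.squared
  new("PhenotypeFit",
    gene = as.character(gene), temperature = as.character(temperature),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2, n = as.integer(n),
    pvalue = if (stats::sd(y) == 0) 1 else unname(sm$coefficients[2L, 4L]),
    lowN = n == 3L
  )
}

.normalizeObsNames <- function(observations) {
  stopifnot(is.data.frame(observations))
  obs <- observations
  map <- c(expression_ratio = "expressionRatio", td_ratio = "tdRatio")
  for (old in names(map))
    if (old %in% names(obs) && !map[[old]] %in% names(obs))
      names(obs)[names(obs) == old] <- map[[old]]
  need <- c("strain", "expressionRatio", "tdRatio")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    .stopf("observations must contain column(s): %s", paste(miss, collapse = ", "))
  obs
}

#' Compare phenotype-expression fits across temperatures
#'
#' Tabulates R^2 per temperature and flags the strongest association
#' (descriptively; no inferential claim is attached). Ties are flagged; a
#' single temperature is passed through with a warning.
#'
#' @param results named list (names = temperature labels) of
#'   [PhenotypeFit-class] objects or bare R^2 values.
#'
#' @return data.frame with columns temperature, r2, strongest, tied.
#' @examples
#' compareTemperatures(list("37C" = 0.787, "39C" = 0.418))
#' @export
compareTemperatures <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  r2 <- vapply(results, function(r)
    if (is(r, "PhenotypeFit")) r@r2 else as.numeric(r), numeric(1))
  if (length(r2) < 2L)
    warning("only one temperature supplied; nothing to compare")
  top <- r2 == max(r2)
  data.frame(
    temperature = names(results),
    r2 = unname(r2),
    strongest = unname(top),
    tied = sum(top) > 1L,
    row.names = NULL
  )
}
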