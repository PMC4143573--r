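#' Select the log-linear (exponential) phase of a growth curve
#'
#' Scans every contiguous window of at least \code{minPoints} points and
#' returns the one maximising the coefficient of determination of log2(OD)
#' versus time. Ties (within 1e-10) are broken toward the longer, then the
#' earlier, window, so a pure exponential curve selects its full range.
#'
#' @param curve a [GrowthCurve-class] with at least \code{minPoints} points.
#' @param minPoints minimum window length, >= 3.
#'
#' @return Integer vector \code{c(start, end)} of point indices.
#' @examples
#' gc <- GrowthCurve("A", "30C", 0:4, 0.1 * 2^(0:4))
#' selectLinearPhase(gc)  # full range: the whole curve is log-linear
#' @rdname selectLinearPhase
#' @export
setMethod("selectLinearPhase", "GrowthCurve",
  function(curve, minPoints = 3L) {
    minPoints <- as.integer(minPoints)
    if (minPoints < 3L) .stopf("'minPoints' must be >= 3")
    n <- length(curve@times)
    if (n < minPoints)
      .stopf("curve has %d points but 'minPoints' is %d", n, minPoints)
    if (diff(range(curve@od)) == 0)
      .stopf("no growth: OD is constant over the whole curve")

    l2 <- log2(curve@od)
    best <- NULL
    bestR2 <- -Inf
    for (len in minPoints:n) {
      for (start in seq_len(n - len + 1L)) {
        end <- start + len - 1L
        r2 <- .linearR2(curve@times[start:end], l2[start:end])
        better <- r2 > bestR2 + 1e-10 ||
          (abs(r2 - bestR2) <= 1e-10 && !is.null(best) &&
             (len > diff(best) + 1L ||
                (len == diff(best) + 1L && start < best[1L])))
        if (is.null(best) || better) {
          best <- c(start, end)
          bestR2 <- max(bestR2, r2)
        }
      }
    }
    as.integer(best)
  })

#' Doubling time from an OD600 growth curve
#'
#' In \code{"regression"} mode (the default), T_d is the reciprocal of the
#' slope of the least-squares fit of log2(OD) versus time over the selected
#' window; for a two-point window this reduces exactly to the classical
#' formula \deqn{T_d = \frac{t_2 - t_1}{\log_2(OD_2 / OD_1)}.}
#' In \code{"two-point"} mode that formula is applied to the window
#' endpoints directly. When \code{window} is NULL the log-linear phase is
#' selected with [selectLinearPhase()] (regression mode) or the full range
#' endpoints are used (two-point mode).
#'
#' T_d depends only on OD ratios and time differences, so it is invariant
#' under multiplicative rescaling of OD and under shifting all times.
#'
#' @param curve a [GrowthCurve-class].
#' @param window optional integer \code{c(start, end)} window of points.
#' @param mode \code{"regression"} or \code{"two-point"}.
#' @param minPoints passed to [selectLinearPhase()] when selecting a window.
#'
#' @return A [DoublingTimeEstimate-class].
#' @examples
#' gc <- GrowthCurve("A", "30C", c(0, 1.5), c(0.1, 0.2))
#' tdHours(doublingTime(gc, mode = "two-point"))  # 1.5 h: one doubling
#' @rdname doublingTime
#' @export
setMethod("doublingTime", "GrowthCurve",
  function(curve, window = NULL, mode = c("regression", "two-point"),
           minPoints = 3L) {
    mode <- match.arg(mode)
    n <- length(curve@times)
    if (is.null(window)) {
      window <- if (mode == "regression" && n >= max(3L, minPoints))
        selectLinearPhase(curve, minPoints) else c(1L, n)
    }
    window <- as.integer(window)
    if (length(window) != 2L || window[1L] < 1L || window[2L] > n ||
        diff(window) < 1L)
      .stopf("'window' must be valid start/end indices within the curve")
    idx <- window[1L]:window[2L]
    t <- curve@times[idx]
    l2 <- log2(curve@od[idx])

    if (mode == "two-point") {
      od1 <- curve@od[window[1L]]; od2 <- curve@od[window[2L]]
      if (od2 <= od1)
        .stopf("not growing: OD at the window end (%.4g) must exceed the start (%.4g)",
               od2, od1)
      td <- (t[length(t)] - t[1L]) / log2(od2 / od1)
      r2 <- if (length(idx) > 2L) .linearR2(t, l2) else 1
    } else {
      fit <- stats::lm.fit(cbind(1, t), l2)
      slope <- fit$coefficients[2L]
      if (!is.finite(slope) || slope <= 0)
        .stopf("not growing: log2(OD) slope over the window is not positive")
      td <- 1 / slope
      r2 <- .linearR2(t, l2)
    }
    new("DoublingTimeEstimate",
      strain = curve@strain, temperature = curve@temperature,
      td = unname(td), window = window, r2 = r2, mode = mode
    )
  })

#' Doubling-time ratio: the thermotolerance phenotype
#'
#' Forms the ratio T_d(30 degC) / T_d(high temperature) for one strain.
#' Because heat slows growth, the ratio typically lies in (0, 1\]; larger
#' values mean the strain loses less speed under heat, i.e. is more
#' thermotolerant.
#'
#' @param tdLow doubling time at the permissive temperature:
#'   a [DoublingTimeEstimate-class] or a positive number (hours).
#' @param tdHigh doubling time at the elevated temperature, same types.
#' @param strain,highTemperature labels; taken from the estimates when
#'   omitted.
#'
#' @return One-row data.frame with columns strain, highTemperature, ratio.
#' @examples
#' tdRatio(1.15, 1.75, strain = "NFRI3236", highTemperature = "39C")
#' @export
tdRatio <- function(tdLow, tdHigh, strain = NULL, highTemperature = NULL) {
  val <- function(x) if (is(x, "DoublingTimeEstimate")) x@td else as.numeric(x)
  low <- val(tdLow); high <- val(tdHigh)
  if (!is.finite(low) || low <= 0 || !is.finite(high) || high <= 0)
    .stopf("both doubling times must be > 0")
  if (is.null(strain) && is(tdLow, "DoublingTimeEstimate"))
    strain <- tdLow@strain
  if (is.null(highTemperature) && is(tdHigh, "DoublingTimeEstimate"))
    highTemperature <- tdHigh@temperature
  data.frame(
    strain = if (is.null(strain)) NA_character_ else as.character(strain),
    highTemperature = if (is.null(highTemperature)) NA_character_
                      else as.character(highTemperature),
    ratio = low / high
  )
}

#' Rank strains by thermotolerance
#'
#' Sorts strains by their doubling-time ratio, descending (most tolerant
#' first). Exact ties keep the stable input order and are flagged in the
#' \code{tied} column.
#'
#' @param ratios data.frame with columns \code{strain} and \code{ratio}
#'   (e.g. rows built by [tdRatio()]), >= 2 distinct strains.
#'
#' @return The input rows reordered, with added \code{rank} and \code{tied}
#'   columns.
#' @examples
#' r <- rbind(
#'   tdRatio(1.15, 1.75, "NFRI3236", "39C"),
#'   tdRatio(1.28, 2.90, "NFRI3155", "39C"),
#'   tdRatio(1.34, 2.11, "S288C", "39C"))
#' rankThermotolerance(r)$strain
#' @export
rankThermotolerance <- function(ratios) {
  stopifnot(is.data.frame(ratios), all(c("strain", "ratio") %in% names(ratios)))
  if (nrow(ratios) < 2L) .stopf("ranking needs at least 2 strains")
  if (anyDuplicated(ratios$strain))
    .stopf("duplicate strain labels: %s",
           paste(unique(ratios$strain[duplicated(ratios$strain)]), collapse = ", "))
  ord <- order(-ratios$ratio)  # stable: ties keep input order
  out <- ratios[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$ratio) | duplicated(out$ratio, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
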