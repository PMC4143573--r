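#' @include AllClasses.R
NULL

#' @rdname selectLinearPhase
#' @export
setGeneric("selectLinearPhase", function(curve, minPoints = 3L)
  standardGeneric("selectLinearPhase"))

#' @rdname doublingTime
#' @export
setGeneric("doublingTime", function(curve, window = NULL,
                                    mode = c("regression", "two-point"),
                                    minPoints = 3L)
  standardGeneric("doublingTime"))

#' @rdname percentileShiftNormalize
#' @export
setGeneric("percentileShiftNormalize", function(x, percentile = 75)
  standardGeneric("percentileShiftNormalize"))

#' @rdname lowIntensityFilter
#' @export
setGeneric("lowIntensityFilter", function(x, fraction = 0.2)
  standardGeneric("lowIntensityFilter"))

#' @rdname flagFilter
#' @export
setGeneric("flagFilter", function(x, allowed = c("present", "marginal"))
  standardGeneric("flagFilter"))

#' @rdname foldChange
#' @export
setGeneric("foldChange", function(x, strain,
                                  method = c("geometric", "arithmetic"))
  standardGeneric("foldChange"))

#' @rdname runScreen
#' @export
setGeneric("runScreen", function(x, tolerant, reference, sensitive,
                                 config = screenConfig())
  standardGeneric("runScreen"))
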