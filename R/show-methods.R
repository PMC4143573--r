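setMethod("show", "StrainSpec", function(object) {
  cat(sprintf(
    "StrainSpec '%s': tolerance %.2f, mu30 %.3g/h, muHot %.3g/h, OD %.3g -> %.3g\n",
    object@name, object@tolerance, object@mu30, object@muHot,
    object@odInit, object@odMax))
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve '%s' at %s: %d points, t = %.2g..%.2g h, OD %.3g..%.3g\n",
              object@strain, object@temperature, length(object@times),
              min(object@times), max(object@times),
              min(object@od), max(object@od)))
})

setMethod("show", "DoublingTimeEstimate", function(object) {
  cat(sprintf(
    "DoublingTimeEstimate '%s' at %s: Td = %.3f h (%s, points %d-%d, R2 = %.4f)\n",
    object@strain, object@temperature, object@td, object@mode,
    object@window[1L], object@window[2L], object@r2))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: planted gene %s, noise SD %.3g (log2)\n",
              object@plantedGene, object@noiseSd))
  cat("  tolerance order:", paste(object@strainOrder, collapse = " > "), "\n")
  cat("  planted folds:  ",
      paste(sprintf("%s=%.3g", object@strainOrder,
                    object@induction[object@strainOrder]), collapse = ", "),
      "\n")
})

setMethod("show", "ThermalExpressionSet", function(object) {
  callNextMethod()
  cat(sprintf("scale: %s; strains: %s\n", intensityScale(object),
              paste(unique(colData(object)$strain), collapse = ", ")))
})

setMethod("show", "FoldChangeTable", function(object) {
  cat(sprintf("FoldChangeTable: %d genes x %d strains (%s)%s\n",
              nrow(object@folds), ncol(object@folds),
              paste(colnames(object@folds), collapse = ", "),
              if (length(object@pvalues)) ", with p-values" else ""))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %d -> %d -> %d genes through stages 1-3\n",
              length(object@stage1), length(object@stage2),
              length(object@stage3)))
  cat("  tolerance order:", paste(object@toleranceOrder, collapse = " > "),
      "\n")
  if (length(object@stage3))
    cat("  stage-3 genes: ", paste(object@stage3, collapse = ", "), "\n")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve '%s': slope %.4f cycles/decade, intercept %.2f, efficiency %.3f, R2 %.4f\n",
    object@gene, object@slope, object@intercept, object@efficiency,
    object@r2))
})

setMethod("show", "PhenotypeFit", function(object) {
  cat(sprintf(
    "PhenotypeFit%s%s: R2 = %.3f (n = %d strains%s), slope %.3g, intercept %.3g\n",
    if (is.na(object@gene)) "" else paste0(" ", object@gene),
    if (is.na(object@temperature)) "" else paste0(" @", object@temperature),
    object@r2, object@n, if (object@lowN) ", low n" else "",
    object@slope, object@intercept))
})
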