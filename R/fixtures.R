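# Accessors for the small published yeast datasets bundled under extdata.

.extdata <- function(file) {
  system.file("extdata", file, package = "ThermoScreen", mustWork = TRUE)
}

#' Published microarray fold changes for the three candidate genes
#'
#' Heat/control fold changes of FMP21 (YBR269C), YER034W and PRM5 (YIL117C)
#' measured by microarray in three S. cerevisiae strains of decreasing
#' thermotolerance: NFRI 3236 (thermotolerant), S288C (standard) and
#' NFRI 3155 (thermosensitive). These three genes are the published screen's
#' final candidates; the table is the worked-example input for
#' [screenFoldChanges()].
#'
#' @return A [FoldChangeTable-class] (3 genes x 3 strains).
#' @examples
#' foldMatrix(yeastHeatShockFolds())
#' @export
yeastHeatShockFolds <- function() {
  readFoldChangeTable(.extdata("yeast_heat_fold_changes.tsv"))
}

#' Published doubling times of the three screened strains
#'
#' Doubling times (h) of NFRI 3236, S288C and NFRI 3155 grown in YPD at
#' 30 degC and 39 degC. At 30 degC the strains are near-indistinguishable
#' (1.15-1.34 h); at 39 degC they separate (1.75-2.90 h), which is the
#' thermotolerance phenotype.
#'
#' @return data.frame with columns strain, temperature, td_h.
#' @examples
#' yeastDoublingTimes()
#' @export
yeastDoublingTimes <- function() {
  utils::read.delim(.extdata("yeast_doubling_times.tsv"))
}

#' Published qPCR expression ratios of FMP21
#'
#' Heat/control expression ratios of FMP21 (ACT1-normalised, real-time
#' RT-PCR) in the three screened strains: 8.50 in NFRI 3236, 4.50 in S288C,
#' 3.47 in NFRI 3155 -- concordant with the strains' thermotolerance order.
#'
#' @return data.frame with columns gene, strain, ratio.
#' @examples
#' yeastQpcrRatios()
#' @export
yeastQpcrRatios <- function() {
  utils::read.delim(.extdata("yeast_fmp21_qpcr_ratios.tsv"))
}
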