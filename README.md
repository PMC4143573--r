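# ThermoScreen

Cross-strain expression screening for thermotolerance genes in
*Saccharomyces cerevisiae*.

Yeast strains differ in how well they keep growing at elevated temperature.
A gene whose heat induction *scales with* a strain's thermotolerance is a
candidate effector of the trait. ThermoScreen implements the quantitative
chain used to find and verify such genes, for anyone phenotyping a strain
panel and screening expression data against it:

- **Growth kinetics** — doubling times from OD600 curves,
  `T_d = (t2 − t1)/log2(OD2/OD1)` (two-point mode) or the reciprocal slope
  of the log2(OD)-vs-time regression over an automatically selected
  log-linear window; the thermotolerance phenotype is the ratio
  `T_d(30°C)/T_d(high)`.
- **Expression screen** — on a `SummarizedExperiment`-based container:
  75th-percentile shift normalisation, lowest-20 % intensity and
  present/marginal flag filters, per-gene pooled t-test (p < 0.05), then
  three selection stages on heat/control fold changes: (1) fold > 1.5 in
  both the tolerant and the reference strain, (2) cross-strain fold ratio
  > 1.5 (tolerant/reference or reference/sensitive), (3) strict rank
  concordance with the tolerance order.
- **qPCR quantification** — external standard curves (Cq vs log10
  concentration; efficiency `10^(−1/slope) − 1`), reference-gene (ACT1)
  normalisation, heat/control expression ratios, and an ACT1-vs-ALG9
  reference-stability check.
- **Phenotype correlation** — OLS of expression ratio on T_d ratio across
  strains, summarised by R².
- **Synthetic data** — growth curves (logistic with exponential limit),
  expression matrices with one planted tolerance-concordant gene among
  null background genes, and qPCR measurements, all seeded and
  reproducible, so every stage is testable against ground truth.

## Worked example

The bundled fold-change table holds the published microarray fold changes
of three candidate genes in three strains of decreasing thermotolerance
(NFRI 3236 → S288C → NFRI 3155). Running the three-stage screen on it:

```r
library(ThermoScreen)

res <- screenFoldChanges(yeastHeatShockFolds(),
  tolerant = "NFRI3236", reference = "S288C", sensitive = "NFRI3155")
res
#> ScreenResult: 3 -> 3 -> 3 genes through stages 1-3
#>   tolerance order: NFRI3236 > S288C > NFRI3155
#>   stage-3 genes:  FMP21, YER034W, PRM5
screenAudit(res)[, c("gene", "foldTolerant", "foldReference",
                     "foldSensitive", "inStage3")]
#>      gene foldTolerant foldReference foldSensitive inStage3
#> 1   FMP21         3.68          2.18          1.35     TRUE
#> 2 YER034W         3.10          1.51          0.49     TRUE
#> 3    PRM5        48.21         23.05         15.07     TRUE
```

All three genes survive: each is induced more than 1.5-fold in both the
tolerant and reference strain (YER034W's 0.49 in the sensitive strain is
irrelevant to stage 1), each has a cross-strain fold ratio above 1.5, and
each row decreases strictly along the tolerance order.

The phenotype side, from the strains' published doubling times:

```r
td <- yeastDoublingTimes()
get <- function(s, t) td$td_h[td$strain == s & td$temperature == t]
ratios <- do.call(rbind, lapply(unique(td$strain), function(s)
  tdRatio(get(s, "30C"), get(s, "39C"), strain = s, highTemperature = "39C")))
rankThermotolerance(ratios)
#>     strain highTemperature     ratio rank  tied
#> 1 NFRI3236             39C 0.6571429    1 FALSE
#> 2    S288C             39C 0.6350711    2 FALSE
#> 3 NFRI3155             39C 0.4413793    3 FALSE
```

The T_d ratio (30 °C over 39 °C) ranks NFRI 3236 most tolerant — it keeps
66 % of its growth speed under heat, the sensitive strain only 44 %. The
published FMP21 qPCR ratios (`yeastQpcrRatios()`: 8.50 > 4.50 > 3.47)
follow the same order.

On the qPCR side, a zero-noise simulated dilution series round-trips its
amplification efficiency exactly:

```r
fitStandardCurve(simulateQpcr(1, efficiency = 0.9, cqNoiseSd = 0)$standards,
                 gene = "FMP21")
#> StandardCurve 'FMP21': slope -3.5874 cycles/decade, intercept 20.00,
#>   efficiency 0.900, R2 1.0000
```

And a synthetic 8-strain cohort built with population R² = 0.8 is recovered
with the expected sampling spread:

```r
obs <- simulatePhenotypeCohort(nStrains = 8, slope = 10, r2pop = 0.8, seed = 1)
fitPhenotypeRegression(obs, gene = "FMP21", temperature = "37C")
#> PhenotypeFit FMP21 @37C: R2 = 0.726 (n = 8 strains), slope 7.39, intercept 2.93
```

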