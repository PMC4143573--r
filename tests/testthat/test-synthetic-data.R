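test_that("growth generator reproduces the exponential limit and logistic closed form", {
  s <- StrainSpec("A", 0.8, mu30 = log(2) / 1.5, muHot = log(2) / 3,
                  odInit = 0.1, odMax = 1e12)
  gc <- simulateGrowthCurve(s, "low", times = c(0, 1.5), noiseSd = 0)
  expect_equal(gc@od, c(0.1, 0.2), tolerance = 1e-9)

  # identical rates at both temperatures give identical curves
  sym <- StrainSpec("B", 0.5, mu30 = 0.5, muHot = 0.5)
  low <- simulateGrowthCurve(sym, "low", 0:6, noiseSd = 0)
  high <- simulateGrowthCurve(sym, "high", 0:6, noiseSd = 0)
  expect_identical(low@od, high@od)

  # logistic value at t = 5 against direct evaluation of the closed form
  s2 <- StrainSpec("C", 0.5, mu30 = 0.6, muHot = 0.3, odInit = 0.1, odMax = 2)
  gc2 <- simulateGrowthCurve(s2, "low", times = c(0, 5), noiseSd = 0)
  expected <- 2 * 0.1 * exp(0.6 * 5) / (2 + 0.1 * (exp(0.6 * 5) - 1))
  expect_equal(gc2@od[2], expected, tolerance = 1e-12)

  expect_error(simulateGrowthCurve(s, "low", numeric(0)), "time")
  expect_error(simulateGrowthCurve(s, "low", c(2, 1)), "increasing")
})

test_that("generators are bitwise reproducible for identical inputs and seed", {
  s <- StrainSpec("A", 0.8, 0.6, 0.4)
  g1 <- simulateGrowthCurve(s, "high", 0:8, noiseSd = 0.01, seed = 42)
  g2 <- simulateGrowthCurve(s, "high", 0:8, noiseSd = 0.01, seed = 42)
  expect_identical(g1@od, g2@od)
  g3 <- simulateGrowthCurve(s, "high", 0:8, noiseSd = 0.01, seed = 43)
  expect_false(identical(g1@od, g3@od))

  panel <- strainPanel()
  e1 <- simulateExpressionMatrix(panel, nGenes = 50, nReplicates = 2,
                                 plantedInduction = tablePanelInduction(),
                                 noiseSd = 0.1, seed = 7)
  e2 <- simulateExpressionMatrix(panel, nGenes = 50, nReplicates = 2,
                                 plantedInduction = tablePanelInduction(),
                                 noiseSd = 0.1, seed = 7)
  expect_identical(SummarizedExperiment::assay(e1$expression),
                   SummarizedExperiment::assay(e2$expression))
  expect_identical(plantedGene(e1$truth), plantedGene(e2$truth))

  q1 <- simulateQpcr(0.3, 0.9, cqNoiseSd = 0.2, seed = 11)
  q2 <- simulateQpcr(0.3, 0.9, cqNoiseSd = 0.2, seed = 11)
  expect_identical(q1, q2)
})

test_that("zero-noise expression matrix carries the planted folds exactly", {
  panel <- strainPanel()
  ind <- tablePanelInduction()
  sim <- simulateExpressionMatrix(panel, nGenes = 100, nReplicates = 2,
                                  plantedInduction = ind, noiseSd = 0, seed = 3)
  pg <- plantedGene(sim$truth)
  for (s in names(ind)) {
    fc <- foldChange(sim$expression, s)
    expect_equal(unname(fc[pg]), unname(ind[s]), tolerance = 1e-12)
    # every background gene sits exactly at fold 1
    expect_equal(unname(fc[setdiff(names(fc), pg)]),
                 rep(1, 99), tolerance = 1e-12)
  }
  expect_identical(strainOrder(sim$truth), c("NFRI3236", "S288C", "NFRI3155"))
})

test_that("background genes are unbiased: mean fold near 1 across seeds", {
  panel <- strainPanel()[1:2]
  folds <- vapply(1:400, function(seed) {
    sim <- simulateExpressionMatrix(panel, nGenes = 10, nReplicates = 2,
                                    plantedInduction = c(NFRI3236 = 2,
                                                         S288C = 1.5),
                                    noiseSd = 0.1, seed = seed)
    bg <- setdiff(rownames(sim$expression), plantedGene(sim$truth))[1]
    unname(foldChange(sim$expression, "NFRI3236")[bg])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("expression generator validates its preconditions", {
  panel <- strainPanel()
  ind <- tablePanelInduction()
  expect_error(simulateExpressionMatrix(panel[1], nGenes = 10,
                                        plantedInduction = ind["NFRI3236"]),
               "2 strains")
  expect_error(simulateExpressionMatrix(panel, nGenes = 1,
                                        plantedInduction = ind), "nGenes")
  expect_error(simulateExpressionMatrix(panel, nGenes = 10, nReplicates = 1,
                                        plantedInduction = ind),
               "nReplicates")
  # induction must rise with tolerance (the planted gene is rank-concordant)
  bad <- c(NFRI3236 = 1.2, S288C = 2.0, NFRI3155 = 1.5)
  expect_error(simulateExpressionMatrix(panel, nGenes = 10,
                                        plantedInduction = bad),
               "tolerance")
})

test_that("qPCR generator follows the amplification model", {
  # perfect doubling: one extra cycle per halving
  expect_equal(simulateQpcr(0.5, efficiency = 1, cq0 = 20,
                            cqNoiseSd = 0)$cq, 21)
  # 10-fold dilutions at perfect efficiency: spacing log2(10) cycles
  std <- simulateQpcr(1, efficiency = 1, cqNoiseSd = 0)$standards
  expect_equal(std$concentration, c(1e-1, 1e-2, 1e-3, 1e-4))
  expect_equal(unique(round(diff(std$cq), 9)), round(log2(10), 9))
  expect_error(simulateQpcr(-1, 1), "trueConc")
  expect_error(simulateQpcr(1, 1.5), "efficiency")
})

test_that("phenotype cohort generator hits the requested population R2 design", {
  obs <- simulatePhenotypeCohort(nStrains = 8, slope = 10, r2pop = 0.8,
                                 seed = 1)
  expect_identical(nrow(obs), 8L)
  expect_true(all(obs$expressionRatio > 0))
  # noise SD implied by the design: b^2 Var(x) (1-R2)/R2
  x <- obs$tdRatio
  varx <- mean((x - mean(x))^2)
  sigma <- sqrt(100 * varx * 0.25)
  resid <- obs$expressionRatio - (1 + 10 * x)
  expect_lt(abs(sd(resid) / sigma - 1), 1)  # same order; one draw only
  expect_error(simulatePhenotypeCohort(nStrains = 2), "nStrains")
})
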