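test_that("standard-curve fitting recovers slope and efficiency exactly at zero noise", {
  std <- simulateQpcr(1, efficiency = 1, cqNoiseSd = 0)$standards
  curve <- fitStandardCurve(std)
  expect_equal(curveSlope(curve), -1 / log10(2), tolerance = 1e-9)
  expect_equal(amplificationEfficiency(curve), 1, tolerance = 1e-9)
  expect_equal(curve@r2, 1, tolerance = 1e-9)

  for (eff in c(0.8, 0.9, 1.0)) {
    s <- simulateQpcr(1, efficiency = eff, cqNoiseSd = 0)$standards
    expect_lt(abs(amplificationEfficiency(fitStandardCurve(s)) - eff), 1e-6)
  }
})

test_that("degenerate standard series are rejected", {
  flat <- data.frame(concentration = c(1e-1, 1e-2, 1e-3), cq = c(20, 20, 20))
  expect_error(fitStandardCurve(flat), "invalid assay")
  rising <- data.frame(concentration = c(1e-1, 1e-2, 1e-3), cq = c(20, 18, 16))
  expect_error(fitStandardCurve(rising), "invalid assay")
  short <- data.frame(concentration = c(1e-1, 1e-2), cq = c(20, 23))
  expect_error(fitStandardCurve(short), "3 dilution")
  dup <- data.frame(concentration = c(1e-1, 1e-1, 1e-2), cq = c(20, 20.1, 23))
  expect_error(fitStandardCurve(dup), "distinct")
})

test_that("quantification inverts the amplification model", {
  sim <- simulateQpcr(1, efficiency = 0.9, cqNoiseSd = 0)
  curve <- fitStandardCurve(sim$standards)
  # cq at the intercept reads concentration 1; one slope step reads 0.1
  expect_equal(quantifyCq(curve@intercept, curve), 1, tolerance = 1e-12)
  # one |slope| step above the intercept is one decade down in template
  expect_equal(quantifyCq(curve@intercept - curve@slope, curve), 0.1,
               tolerance = 1e-12)
  expect_equal(quantifyCq(curve@intercept + curve@slope, curve), 10,
               tolerance = 1e-12)
  # strictly decreasing in Cq
  expect_true(all(diff(quantifyCq(seq(18, 30, by = 0.5), curve)) < 0))
  # round-trip through the generator at zero noise
  for (conc in c(0.7, 0.05, 0.002)) {
    m <- simulateQpcr(conc, efficiency = 0.9, cqNoiseSd = 0)
    expect_equal(quantifyCq(m$cq, curve), conc, tolerance = 1e-9)
  }
})

test_that("rates and ratios are scale-invariant ratios", {
  expect_equal(normalizedRate(2, 2), 1)
  expect_equal(normalizedRate(4, 2), 2 * normalizedRate(2, 2))
  expect_equal(normalizedRate(3 * 7, 2 * 7), normalizedRate(3, 2))
  expect_error(normalizedRate(1, 0), "> 0")
  expect_equal(expressionRatio(1.5, 1.5), 1)
  expect_error(expressionRatio(-1, 2), "> 0")
})

test_that("standard-curve quantification recovers a planted heat/control ratio", {
  # target induced r-fold by heat; reference gene flat; both assays eff 0.9
  r <- 8.5
  tCurve <- fitStandardCurve(
    simulateQpcr(1, efficiency = 0.9, cqNoiseSd = 0)$standards, gene = "FMP21")
  rCurve <- fitStandardCurve(
    simulateQpcr(1, efficiency = 1.0, cqNoiseSd = 0)$standards, gene = "ACT1")
  cqOf <- function(conc, eff, cq0 = 20) cq0 - log(conc) / log(1 + eff)
  tHeat <- quantifyCq(cqOf(0.02 * r, 0.9), tCurve)
  tCtrl <- quantifyCq(cqOf(0.02, 0.9), tCurve)
  refH <- quantifyCq(cqOf(0.3, 1.0), rCurve)
  refC <- quantifyCq(cqOf(0.3, 1.0), rCurve)
  ratio <- expressionRatio(normalizedRate(tHeat, refH),
                           normalizedRate(tCtrl, refC))
  expect_equal(ratio, r, tolerance = 1e-9)

  # delta-delta-Cq shortcut agrees when given the true efficiencies
  dd <- deltaDeltaCqRatio(cqOf(0.02 * r, 0.9), cqOf(0.02, 0.9),
                          cqOf(0.3, 1.0), cqOf(0.3, 1.0),
                          effTarget = 0.9, effRef = 1.0)
  expect_equal(dd, r, tolerance = 1e-9)
})

test_that("qpcrRelativeExpression runs the full table pipeline", {
  cqOf <- function(conc, eff = 1, cq0 = 20) conc ^ 0 * (cq0 - log(conc) / log(1 + eff))
  dil <- c(1e-1, 1e-2, 1e-3, 1e-4)
  mkStd <- function(gene) data.frame(
    gene = gene, sample = paste0("std", seq_along(dil)), cq = cqOf(dil),
    role = "standard", dilution = dil, strain = NA, condition = NA)
  mkUnk <- function(gene, strain, condition, conc) data.frame(
    gene = gene, sample = paste(strain, condition, sep = "_"), cq = cqOf(conc),
    role = "unknown", dilution = NA, strain = strain, condition = condition)
  tab <- rbind(
    mkStd("FMP21"), mkStd("ACT1"),
    mkUnk("FMP21", "S288C", "control", 0.01),
    mkUnk("FMP21", "S288C", "heat", 0.045),
    mkUnk("ACT1", "S288C", "control", 0.2),
    mkUnk("ACT1", "S288C", "heat", 0.2))
  out <- qpcrRelativeExpression(tab, reference = "ACT1")
  expect_named(out$curves, c("ACT1", "FMP21"))
  expect_equal(out$ratios$ratio[out$ratios$gene == "FMP21"], 4.5,
               tolerance = 1e-9)
})

test_that("reference-gene stability check applies the log2 tolerance", {
  ok <- referenceStability(c(1, 1.1, 0.95), c(1, 1.1, 0.95))
  expect_true(ok$pass)
  expect_equal(ok$log2Mean, 0)

  bad <- referenceStability(c(2, 2.2), c(1, 1.1))
  expect_false(bad$pass)
  expect_equal(abs(bad$perCondition$log2), c(1, 1), tolerance = 1e-12)

  # mildly noisy but stable pair passes nearly always
  passes <- vapply(1:100, function(seed) {
    set.seed(seed)
    dev <- 2^rnorm(4, 0, 0.1)
    referenceStability(dev, rep(1, 4))$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)

  expect_error(referenceStability(c(1, 2), 1), "paired")
})
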