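test_that("percentile-shift normalisation anchors each sample's percentile at 0", {
  # sample with log2 values 1..5: the 75th-percentile element maps to 0
  m <- matrix(2^(1:5), 5, 1, dimnames = list(paste0("G", 1:5), "s1"))
  n1 <- percentileShiftNormalize(m)
  expect_equal(quantile(n1[, 1], 0.75, names = FALSE), 0, tolerance = 1e-12)
  expect_equal(unname(n1[, 1]), (1:5) - 4, tolerance = 1e-12)

  # two samples differing by a global x8 factor normalise identically
  set.seed(1)
  a <- 2^rnorm(50, 8)
  m2 <- cbind(s1 = a, s2 = 8 * a)
  rownames(m2) <- paste0("G", 1:50)
  n2 <- percentileShiftNormalize(m2)
  expect_equal(n2[, 1], n2[, 2], tolerance = 1e-12)

  # post-condition on every column of a random matrix
  m3 <- matrix(2^rnorm(600, 8, 2), 100, 6,
               dimnames = list(paste0("G", 1:100), paste0("s", 1:6)))
  n3 <- percentileShiftNormalize(m3)
  for (j in 1:6)
    expect_equal(quantile(n3[, j], 0.75, names = FALSE), 0, tolerance = 1e-12)

  expect_error(percentileShiftNormalize(matrix(c(-1, 2), 1)), "positive")
})

test_that("normalisation removes per-sample scale without touching fold changes", {
  tes <- randomTES(80, seed = 5)
  scales <- 2^runif(ncol(tes), -3, 3)
  scaled <- ThermalExpressionSet(
    sweep(SummarizedExperiment::assay(tes), 2, scales, "*"),
    strain = sampleInfo(tes)$strain, condition = sampleInfo(tes)$condition,
    replicate = sampleInfo(tes)$replicate)
  for (s in c("T", "R", "S"))
    expect_equal(foldChange(percentileShiftNormalize(scaled), s),
                 foldChange(percentileShiftNormalize(tes), s),
                 tolerance = 1e-9)
})

test_that("low-intensity filter removes only genes low in every sample", {
  m <- matrix(2^rnorm(40, 8), 10, 4,
              dimnames = list(paste0("G", 1:10), paste0("s", 1:4)))
  # fraction 0: everything kept
  expect_true(all(lowIntensityFilter(m, 0)))

  # a gene ranked last in all samples is removed at fraction 0.2 (10 genes)
  m[1, ] <- min(m) / 10
  expect_false(lowIntensityFilter(m, 0.2)[["G1"]])

  # low in one sample but not in others: kept
  m2 <- m
  m2[2, ] <- max(m)  # high everywhere ...
  m2[2, 1] <- min(m2) / 100  # ... except sample 1
  keep <- lowIntensityFilter(m2, 0.2)
  expect_true(keep[["G2"]])

  # cross-check the mask against per-sample rank sets
  k <- floor(0.2 * nrow(m2))
  lowEverywhere <- Reduce(`&`, lapply(1:4, function(j)
    rank(m2[, j], ties.method = "min") <= k))
  expect_identical(unname(keep), unname(!lowEverywhere))
})

test_that("flag filter applies the at-least-half rule and tolerates missing flags", {
  tes <- randomTES(10, seed = 2)
  expect_true(all(flagFilter(tes)))  # no flags: everything passes

  fl <- matrix("present", 10, ncol(tes))
  fl[1, ] <- "absent"                      # absent everywhere: removed
  fl[2, ] <- rep(c("present", "absent"), length.out = ncol(tes))  # half: kept
  fl[3, 1:(ncol(tes) - 1)] <- "absent"     # detected in <half: removed
  tesF <- ThermalExpressionSet(SummarizedExperiment::assay(tes),
    strain = sampleInfo(tes)$strain, condition = sampleInfo(tes)$condition,
    replicate = sampleInfo(tes)$replicate, flags = fl)
  keep <- flagFilter(tesF)
  expect_identical(unname(keep[1:3]), c(FALSE, TRUE, FALSE))
  expect_true(all(keep[4:10]))

  expect_error(flagFilter(tesF, allowed = c("present", "detected")),
               "unknown flag")
})

test_that("fold changes follow the geometric-mean contract", {
  # identical heat and control groups: fold 1 everywhere
  m <- matrix(2^rnorm(20, 8), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:4)))
  m[, 3:4] <- m[, 1:2]
  tes <- ThermalExpressionSet(m, strain = rep("A", 4),
                              condition = c("control", "control", "heat", "heat"),
                              replicate = c(1, 2, 1, 2))
  expect_equal(unname(foldChange(tes, "A")), rep(1, 5), tolerance = 1e-12)

  # control log2 {1,3}, heat log2 {4,6}: geometric fold 2^(5-2) = 8
  m2 <- matrix(2^c(1, 3, 4, 6), 1, 4,
               dimnames = list("G1", paste0("s", 1:4)))
  tes2 <- ThermalExpressionSet(m2, strain = rep("A", 4),
                               condition = c("control", "control", "heat", "heat"),
                               replicate = c(1, 2, 1, 2))
  expect_equal(unname(foldChange(tes2, "A")), 8, tolerance = 1e-12)
  # arithmetic mode: (16+64)/(2+8) = 8 here too, different in general
  expect_equal(unname(foldChange(tes2, "A", method = "arithmetic")),
               (16 + 64) / (2 + 8), tolerance = 1e-12)
  expect_error(foldChange(tes2, "missing"), "unknown strain")
})

test_that("t-test filter matches stats::t.test and handles degenerate rows", {
  tes <- randomTES(60, nReps = 3, seed = 8)
  p <- differentialPValues(tes, "T")
  e <- log2(SummarizedExperiment::assay(tes))
  cd <- sampleInfo(tes)
  for (g in sample(rownames(tes), 10)) {
    ref <- t.test(e[g, cd$strain == "T" & cd$condition == "heat"],
                  e[g, cd$strain == "T" & cd$condition == "control"],
                  var.equal = TRUE)$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }

  # degenerate rows: constant and equal -> p = 1; constant but shifted -> p = 0
  m <- matrix(2^8, 2, 4, dimnames = list(c("same", "shift"), paste0("s", 1:4)))
  m["shift", 3:4] <- 2^10
  tesD <- ThermalExpressionSet(m, strain = rep("A", 4),
                               condition = c("control", "control", "heat", "heat"),
                               replicate = c(1, 2, 1, 2))
  pD <- differentialPValues(tesD, "A")
  expect_identical(unname(pD), c(1, 0))
  expect_identical(unname(differentialFilter(tesD, "A")), c(FALSE, TRUE))

  # fewer than 2 replicates per condition is refused
  tes1 <- ThermalExpressionSet(m[, c(1, 3)], strain = rep("A", 2),
                               condition = c("control", "heat"),
                               replicate = c(1, 1))
  expect_error(differentialPValues(tes1, "A"), "2 replicates")
})

test_that("screen stages enforce strict thresholds and rank concordance", {
  fc <- yeastHeatShockFolds()
  f <- foldMatrix(fc)

  # stage 1 on tolerant + reference: all three published genes pass
  expect_setequal(screenStage1(fc, "NFRI3236", "S288C"),
                  c("FMP21", "YER034W", "PRM5"))
  # boundary folds fail the strict inequality
  b <- FoldChangeTable(matrix(c(1.5, 1.5, 1.0), 1,
                              dimnames = list("B", colnames(f))))
  expect_length(screenStage1(b, "NFRI3236", "S288C"), 0)

  # stage 2: FMP21 via tolerant/reference = 3.68/2.18 > 1.5
  expect_true("FMP21" %in%
    screenStage2(fc, "NFRI3236", "S288C", "NFRI3155"))
  flat <- FoldChangeTable(matrix(c(2, 2, 2), 1,
                                 dimnames = list("F", colnames(f))))
  expect_length(screenStage2(flat, "NFRI3236", "S288C", "NFRI3155"), 0)
  # second disjunct alone: reference/sensitive = 3.2/2.0 = 1.6
  alt <- FoldChangeTable(matrix(c(1.0, 3.2, 2.0), 1,
                                dimnames = list("A", colnames(f))))
  expect_identical(screenStage2(alt, "NFRI3236", "S288C", "NFRI3155"), "A")

  # stage 3: published rows are strictly decreasing along the tolerance order
  ord <- c("NFRI3236", "S288C", "NFRI3155")
  expect_setequal(screenStage3(fc, ord), c("FMP21", "YER034W", "PRM5"))
  nm <- FoldChangeTable(matrix(c(2, 3, 1), 1, dimnames = list("N", ord)))
  expect_length(screenStage3(nm, ord), 0)
  tie <- FoldChangeTable(matrix(c(3, 2, 2), 1, dimnames = list("T", ord)))
  expect_length(screenStage3(tie, ord), 0)
})

test_that("the assembled screen matches a brute-force per-gene oracle", {
  set.seed(21)
  for (i in 1:10) {
    tes <- randomTES(sample(40:120, 1), nReps = sample(2:3, 1),
                     withFlags = i %% 2 == 0, seed = 100 + i)
    # unstructured matrices can legitimately empty out during preprocessing
    res <- suppressWarnings(runScreen(tes, "T", "R", "S"))
    oracle <- bruteScreen(tes, "T", "R", "S")
    expect_setequal(stageGenes(res, 1), oracle$stage1)
    expect_setequal(stageGenes(res, 2), oracle$stage2)
    expect_setequal(stageGenes(res, 3), oracle$stage3)
    expect_true(all(stageGenes(res, 3) %in% stageGenes(res, 2)))
    expect_true(all(stageGenes(res, 2) %in% stageGenes(res, 1)))
  }
})

test_that("screen output is invariant to gene and sample order", {
  tes <- randomTES(60, seed = 31)
  res <- suppressWarnings(runScreen(tes, "T", "R", "S"))
  perm <- tes[sample(nrow(tes)), sample(ncol(tes))]
  resPerm <- suppressWarnings(runScreen(perm, "T", "R", "S"))
  for (k in 1:3)
    expect_setequal(stageGenes(resPerm, k), stageGenes(res, k))
})

test_that("an all-filtered matrix yields an empty result with a warning", {
  tes <- randomTES(10, seed = 41)
  fl <- matrix("absent", 10, ncol(tes))
  dead <- ThermalExpressionSet(SummarizedExperiment::assay(tes),
    strain = sampleInfo(tes)$strain, condition = sampleInfo(tes)$condition,
    replicate = sampleInfo(tes)$replicate, flags = fl)
  expect_warning(res <- runScreen(dead, "T", "R", "S"), "no genes")
  expect_length(stageGenes(res, 3), 0)
})

test_that("screen audit covers every candidate and records the quantities", {
  fc <- yeastHeatShockFolds()
  res <- screenFoldChanges(fc, "NFRI3236", "S288C", "NFRI3155")
  audit <- screenAudit(res)
  expect_setequal(audit$gene, rownames(foldMatrix(fc)))
  fm <- foldMatrix(fc)
  expect_equal(audit$ratioTolRef[audit$gene == "FMP21"],
               fm["FMP21", "NFRI3236"] / fm["FMP21", "S288C"],
               tolerance = 1e-12)
  expect_true(all(audit$inStage3 <= audit$inStage2))
  expect_true(all(audit$inStage2 <= audit$inStage1))
})
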