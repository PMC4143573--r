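# Shared fixtures and independent oracles, built in code at test time.

# Three-strain panel mirroring the screened cohort: growth rates chosen so the
# doubling times at 30C are ~1.2 h for all and separate under heat.
strainPanel <- function() {
  list(
    tolerant  = StrainSpec("NFRI3236", tolerance = 0.9, mu30 = 0.60,
                           muHot = 0.40),
    reference = StrainSpec("S288C",    tolerance = 0.5, mu30 = 0.52,
                           muHot = 0.33),
    sensitive = StrainSpec("NFRI3155", tolerance = 0.2, mu30 = 0.54,
                           muHot = 0.24)
  )
}

tablePanelInduction <- function() {
  c(NFRI3236 = 3.68, S288C = 2.18, NFRI3155 = 1.35)
}

# A random ThermalExpressionSet (3 strains x control/heat x nReps), optionally
# with random detection flags, for property tests.
randomTES <- function(nGenes, nReps = 2L, withFlags = FALSE, seed = 1L) {
  set.seed(seed)
  strains <- c("T", "R", "S")
  n <- length(strains) * 2L * nReps
  strain <- rep(strains, each = 2L * nReps)
  condition <- rep(rep(c("control", "heat"), each = nReps), length(strains))
  replicate <- rep(paste0("r", seq_len(nReps)), 2L * length(strains))
  m <- matrix(2^(rnorm(nGenes * n, 8, 2)), nGenes, n)
  rownames(m) <- sprintf("G%04d", seq_len(nGenes))
  colnames(m) <- paste(strain, condition, replicate, sep = "_")
  flags <- NULL
  if (withFlags)
    flags <- matrix(sample(c("present", "marginal", "absent"), nGenes * n,
                           replace = TRUE, prob = c(0.7, 0.15, 0.15)),
                    nGenes, n)
  ThermalExpressionSet(m, strain, condition, replicate, flags = flags)
}

# Brute-force per-gene screen oracle: scalar arithmetic and stats::t.test,
# no vectorised shortcuts. Mirrors the default runScreen() configuration.
bruteScreen <- function(tes, tolerant, reference, sensitive,
                        fcThreshold = 1.5, ratioThreshold = 1.5,
                        lowFraction = 0.2, alpha = 0.05,
                        differential = TRUE) {
  e <- SummarizedExperiment::assay(tes, "exprs")
  cd <- as.data.frame(SummarizedExperiment::colData(tes))
  fl <- detectionFlags(tes)
  genes <- rownames(e)

  # per-sample 75th percentile shift on log2
  l2 <- log2(e)
  for (j in seq_len(ncol(l2)))
    l2[, j] <- l2[, j] - quantile(l2[, j], 0.75, names = FALSE)

  k <- floor(lowFraction * nrow(e))
  lowSet <- lapply(seq_len(ncol(e)), function(j) {
    r <- rank(e[, j], ties.method = "min")
    names(r)[r <= k]
  })

  pooledT <- function(a, b) {
    out <- tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
    if (is.na(out)) out <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    out
  }

  fold1 <- function(g, s) {
    h <- l2[g, cd$strain == s & cd$condition == "heat"]
    c0 <- l2[g, cd$strain == s & cd$condition == "control"]
    2^(mean(h) - mean(c0))
  }

  stage1 <- stage2 <- stage3 <- character()
  for (g in genes) {
    if (!is.null(fl)) {
      ok <- mean(fl[g, ] %in% c("present", "marginal")) >= 0.5
      if (!ok) next
    }
    lowEverywhere <- all(vapply(lowSet, function(s) g %in% s, logical(1)))
    if (k > 0 && lowEverywhere) next
    if (differential) {
      sig <- TRUE
      for (s in c(tolerant, reference)) {
        a <- l2[g, cd$strain == s & cd$condition == "heat"]
        b <- l2[g, cd$strain == s & cd$condition == "control"]
        if (!(pooledT(a, b) < alpha)) { sig <- FALSE; break }
      }
      if (!sig) next
    }
    ft <- fold1(g, tolerant); fr <- fold1(g, reference); fs <- fold1(g, sensitive)
    if (ft > fcThreshold && fr > fcThreshold) {
      stage1 <- c(stage1, g)
      if (ft / fr > ratioThreshold || fr / fs > ratioThreshold) {
        stage2 <- c(stage2, g)
        if (ft > fr && fr > fs) stage3 <- c(stage3, g)
      }
    }
  }
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3)
}

# Exhaustive window search for the log-linear phase, independent of
# selectLinearPhase()'s loop structure: collects every window's R2 into a
# table and applies the max-R2 / longest / earliest rule by sorting.
bruteLinearPhase <- function(curve, minPoints = 3L) {
  t <- curve@times; l2 <- log2(curve@od); n <- length(t)
  rows <- list()
  for (start in seq_len(n)) for (end in seq_len(n)) {
    len <- end - start + 1L
    if (len < minPoints) next
    y <- l2[start:end]
    r2 <- if (sd(y) == 0) 0 else cor(t[start:end], y)^2
    rows[[length(rows) + 1L]] <- data.frame(start, end, len, r2)
  }
  d <- do.call(rbind, rows)
  d <- d[abs(d$r2 - max(d$r2)) <= 1e-10, ]
  d <- d[order(-d$len, d$start), ]
  c(d$start[1L], d$end[1L])
}
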