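makeStudy <- function(values, conditions, symbols = rownames(values)) {
  ExpressionStudy(values, symbols, conditions)
}

test_that("expression floor keeps exactly the features whose max exceeds it", {
  v <- rbind(allLow = rep(5.9, 4),
             oneHigh = c(6.01, 3, 3, 3),
             atFloor = rep(6, 4),
             high = rep(8, 4))
  st <- makeStudy(v, c("control", "control", "1d", "1d"))
  kept <- filterLowExpression(st, floor = 6)
  expect_identical(rownames(kept), c("oneHigh", "high"))
  expect_warning(filterLowExpression(st, floor = 100), "no features")
})

test_that("moderated statistics match the closed-form oracle to 1e-10", {
  set.seed(42)
  cond <- rep(c("control", "1d", "3d", "5d", "7d"), each = 3)
  geneSd <- exp(rnorm(50, 0, 0.6))  # heterogeneous true variances
  values <- matrix(rnorm(50 * 15, 8, rep(geneSd, 15)), 50, 15,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  values[1:10, cond != "control"] <- values[1:10, cond != "control"] + 1.5
  st <- makeStudy(values, cond)
  res <- fitModeratedModel(st)
  oracle <- moderatedOracle(values, factor(cond, levels = unique(cond)))
  expect_equal(priorDf(res), oracle$d0, tolerance = 1e-10)
  expect_equal(priorVar(res), oracle$s02, tolerance = 1e-10)
  ct <- contrastTable(res)
  for (cn in colnames(oracle$t)) {
    sub <- ct[ct$contrast == cn, ]
    expect_equal(setNames(sub$t, sub$feature),
                 setNames(oracle$t[, cn], rownames(values)), tolerance = 1e-10)
    expect_equal(setNames(sub$logFC, sub$feature),
                 setNames(oracle$logFC[, cn], rownames(values)),
                 tolerance = 1e-10)
  }
})

test_that("shared true variance drives the prior df large (pooling limit)", {
  set.seed(7)
  cond <- rep(c("control", "1d"), each = 10)
  values <- matrix(rnorm(400 * 20, 0, 1), 400, 20)  # identical variance 1
  rownames(values) <- sprintf("g%03d", 1:400)
  res <- fitModeratedModel(makeStudy(values, cond))
  expect_gt(priorDf(res), 20)
})

test_that("BH adjustment follows the step-up formula and its edge cases", {
  expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
  expect_equal(adjustFDR(0.007), 0.007)
  expect_error(adjustFDR(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- adjustFDR(runif(50))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("gene-level counting ignores unannotated features and collapses probes", {
  set.seed(3)
  cond <- rep(c("control", "1d", "3d", "5d", "7d"), each = 3)
  values <- matrix(rnorm(6 * 15, 8, 0.2), 6, 15,
                   dimnames = list(paste0("f", 1:6), NULL))
  values[1:3, cond == "3d"] <- values[1:3, cond == "3d"] + 5  # geneA, 2 probes
  values[4, cond == "1d"] <- values[4, cond == "1d"] + 5      # unannotated
  st <- ExpressionStudy(values, c("geneA", "geneA", "geneA", NA, "geneB", "geneB"),
                        cond)
  res <- fitModeratedModel(st)
  counts <- countSignificant(res, fdr = 0.05)
  expect_equal(counts$genes, 1)       # geneA once, f4 not annotated
  expect_gte(counts$features, 4)
  collapsed <- collapseToGenes(st, res)
  expect_setequal(rownames(collapsed), c("geneA", "geneB"))
  # kept probe is the smallest omnibus p among geneA's probes
  tab <- deTable(res)
  bestA <- tab$feature[tab$gene %in% "geneA"][which.min(tab$p[tab$gene %in% "geneA"])]
  expect_equal(unname(exprValues(collapsed)["geneA", ]),
               unname(values[bestA, ]))
})

test_that("null simulations keep the empirical FDR near nominal", {
  hits <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nGenes = 2000, deFraction = 0,
                            lowExprFraction = 0, probesPerGene = 1,
                            moduleSpec = list(), hubSpec = list(), seed = s)
    sim <- simulateTimecourseStudy(cfg)
    res <- fitModeratedModel(sim$study)
    mean(deTable(res)$fdr < 0.05)
  }, numeric(1))
  mcSd <- sd(hits) / sqrt(length(hits))
  expect_lte(mean(hits), 0.05 + 2 * mcSd)
})

test_that("lowering the FDR threshold never increases the significant count", {
  sim <- simulateTimecourseStudy(smallConfig(seed = 4))
  res <- fitModeratedModel(sim$study)
  counts <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                   function(a) countSignificant(res, a)$features, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("filtering first is equivalent to modelling the pre-filtered matrix", {
  cfg <- simulationConfig(nGenes = 120, lowExprFraction = 0.4, seed = 6)
  sim <- simulateTimecourseStudy(cfg)
  a <- fitModeratedModel(filterLowExpression(sim$study))
  pre <- sim$study[apply(exprValues(sim$study), 1, max) > 6, ]
  b <- fitModeratedModel(pre)
  expect_equal(deTable(a), deTable(b))
})
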