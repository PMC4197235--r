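test_that("identical condition means give r = 1; negated profiles fail the gate", {
  set.seed(1)
  cond <- rep(c("control", "1d", "3d", "5d"), each = 3)
  prof <- c(0, 2, 1, -1)
  mk <- function(sign) {
    v <- rbind(gA = 8 + sign * prof[match(cond, unique(cond))] + 0,
               gB = 7 + rnorm(12, 0, 0.1))
    ExpressionStudy(v, rownames(v), cond)
  }
  a <- mk(1)
  same <- profileConcordance(a, mk(1), rMin = 0.8)
  expect_equal(same$r[same$gene == "gA"], 1, tolerance = 1e-6)
  expect_true(same$pass[same$gene == "gA"])
  flipped <- profileConcordance(a, mk(-1), rMin = 0.8)
  expect_equal(flipped$r[flipped$gene == "gA"], -1, tolerance = 1e-6)
  expect_false(flipped$pass[flipped$gene == "gA"])
})

test_that("gene matching is case-insensitive and constants are excluded", {
  cond <- rep(c("control", "1d", "3d", "5d"), each = 2)
  va <- rbind(PTGIS = 8 + rep(c(0, 2, 1, 0.5), each = 2),
              flat = rep(5, 8))
  vb <- rbind(ptgis = 6 + rep(c(0, 2, 1, 0.5), each = 2) + rnorm(8, 0, 0.01),
              flat = rep(7, 8))
  a <- ExpressionStudy(va, rownames(va), cond)
  b <- ExpressionStudy(vb, rownames(vb), cond)
  out <- profileConcordance(a, b)
  expect_equal(out$gene, "PTGIS")
  expect_equal(attr(out, "excluded"), "flat")
})

test_that("planted concordant genes are recovered and false inclusions are rare", {
  cfg <- simulationConfig(nGenes = 300, lowExprFraction = 0, probesPerGene = 1,
                          moduleSpec = list(), hubSpec = list(), seed = 42)
  pair <- simulateConcordantPair(cfg, concordantFraction = 0.3,
                                 profileNoiseSd = 0.05)
  resA <- fitModeratedModel(pair$studyA)
  collA <- collapseToGenes(pair$studyA, resA)
  resB <- fitModeratedModel(pair$studyB)
  collB <- collapseToGenes(pair$studyB, resB)
  out <- profileConcordance(collA, collB, conditions = c("control", "1d", "3d", "5d"))
  planted <- trueConcordantGenes(pair$truth)
  recovery <- mean(planted %in% out$gene[out$pass])
  expect_gte(recovery, 0.9)
  nonDE <- setdiff(out$gene, trueDEGenes(pair$truth))
  falseRate <- mean(out$pass[out$gene %in% nonDE])
  # null 4-point profiles exceed r > 0.8 at roughly the null rate
  expect_lt(falseRate, 0.35)
})

test_that("null profiles pass r > 0.8 at the Monte-Carlo null rate", {
  set.seed(3)
  nullR <- replicate(1000, cor(rnorm(4), rnorm(4)))
  nullRate <- mean(nullR > 0.8)
  cfg <- simulationConfig(nGenes = 400, deFraction = 0, lowExprFraction = 0,
                          probesPerGene = 1, moduleSpec = list(),
                          hubSpec = list(), seed = 8)
  pair <- simulateConcordantPair(cfg, concordantFraction = 0,
                                 profileNoiseSd = 0.1)
  out <- profileConcordance(collapseToGenes(pair$studyA,
                                            fitModeratedModel(pair$studyA)),
                            collapseToGenes(pair$studyB,
                                            fitModeratedModel(pair$studyB)),
                            conditions = c("control", "1d", "3d", "5d"))
  expect_lt(abs(mean(out$pass) - nullRate), 3 * sqrt(nullRate / length(out$pass)) + 0.02)
})

test_that("fold-change concordance r, r2 and invariances behave", {
  x <- data.frame(gene = letters[1:10], condition = "1d",
                  log2FC = c(2, 1.5, 1, 0.5, 0, -0.5, -1, -1.5, -2, 0.25))
  yv <- x$log2FC + rnorm(10, 0, 0.2)
  y <- data.frame(gene = letters[1:10], condition = "1d", log2FC = yv)
  out <- foldChangeConcordance(x, y, "1d")
  expect_equal(out$r2, out$r^2, tolerance = 1e-12)
  expect_equal(out$r, cor(x$log2FC, yv), tolerance = 1e-12)
  # symmetry and affine invariance
  rev <- foldChangeConcordance(y, x, "1d")
  expect_equal(rev$r, out$r, tolerance = 1e-12)
  y2 <- transform(y, log2FC = 3 * log2FC + 1)
  expect_equal(foldChangeConcordance(x, y2, "1d")$r, out$r, tolerance = 1e-12)
  exact <- foldChangeConcordance(x, x, "1d")
  expect_equal(exact$r, 1)
  expect_error(foldChangeConcordance(x[1:2, ], y[1:2, ], "1d"), "at least 3")
})

test_that("an r of 0.77 squares to the reported 0.59", {
  set.seed(5)
  # construct a pair with sample correlation exactly 0.77
  x <- scale(rnorm(16))[, 1]
  e <- scale(resid(lm(rnorm(16) ~ x)))[, 1]
  yv <- 0.77 * x + sqrt(1 - 0.77^2) * e
  fx <- data.frame(gene = paste0("g", 1:16), condition = "1d", log2FC = x)
  fy <- data.frame(gene = paste0("g", 1:16), condition = "1d", log2FC = yv)
  out <- foldChangeConcordance(fx, fy, "1d")
  expect_equal(out$r, 0.77, tolerance = 1e-9)
  expect_equal(out$r2, 0.5929, tolerance = 1e-9)
})

test_that("planted fold-change correlation is recovered within the Fisher band", {
  inside <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(16, 0, 1.2)
    y <- 0.8 * x + rnorm(16, 0, 1.2 * sqrt(1 - 0.64))
    fx <- data.frame(gene = paste0("g", 1:16), condition = "1d", log2FC = x)
    fy <- data.frame(gene = paste0("g", 1:16), condition = "1d", log2FC = y)
    r <- foldChangeConcordance(fx, fy, "1d")$r
    z <- atanh(r); z0 <- atanh(0.8)
    abs(z - z0) <= 1.96 / sqrt(16 - 3)
  }, logical(1))
  expect_gte(mean(inside), 0.8)
})
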