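blockStudy <- function(nBlocks = 2, blockSize = 30, nNoise = 40, rho = 0.9,
                       n = 15, seed = 1) {
  set.seed(seed)
  genes <- c()
  values <- NULL
  labels <- integer()
  for (b in seq_len(nBlocks)) {
    latent <- rnorm(n)
    block <- t(vapply(seq_len(blockSize), function(i) {
      sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n)
    }, numeric(n)))
    values <- rbind(values, block)
    labels <- c(labels, rep(b, blockSize))
  }
  if (nNoise > 0) {
    values <- rbind(values, matrix(rnorm(nNoise * n), nNoise, n))
    labels <- c(labels, rep(0, nNoise))
  }
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  list(values = values, labels = setNames(labels, rownames(values)))
}

test_that("soft adjacency follows the power arithmetic", {
  x <- 1:10
  m <- rbind(a = x + 0, b = 2 * x + 1, c = rnorm(10))
  a <- softAdjacency(m, beta = 10, method = "pearson")
  expect_equal(a["a", "b"], 1)
  expect_equal(unname(diag(a)), rep(0, 3))
  r <- correlationMatrix(m, "pearson")
  expect_equal(a["a", "c"], abs(r["a", "c"])^10, tolerance = 1e-12)
  # raising beta never increases adjacency for |cor| < 1
  a6 <- softAdjacency(m, beta = 6, method = "pearson")
  expect_lte(a["a", "c"], a6["a", "c"])
})

test_that("TOM matches the brute-force triple loop and hand cases", {
  set.seed(8)
  a <- matrix(runif(36), 6, 6)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  tom <- topologicalOverlap(a)
  k <- rowSums(a)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    num <- sum(vapply(1:6, function(u) a[i, u] * a[u, j], numeric(1))) + a[i, j]
    expect_equal(tom[i, j], num / (min(k[i], k[j]) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # isolated pair with a_ij = 1: TOM = (0 + 1)/(1 + 1 - 1) = 1
  pairAdj <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(topologicalOverlap(pairAdj)[1, 2], 1)
  # no adjacency, no shared neighbours
  expect_equal(topologicalOverlap(matrix(0, 3, 3))[1, 2], 0)
})

test_that("TOM stays in [0,1] over random admissible adjacencies", {
  set.seed(9)
  for (rep in 1:10) {
    a <- matrix(runif(100), 10, 10)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- topologicalOverlap(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("planted two-block design is recovered (adjusted Rand over seeds)", {
  skip_if_not_installed("mclust")
  ari <- vapply(1:20, function(s) {
    bs <- blockStudy(seed = s)
    asg <- detectWeightedModules(bs$values, beta = 10, method = "spearman",
                                 minModuleSize = 20)
    mclust::adjustedRandIndex(moduleLabels(asg)[names(bs$labels)], bs$labels)
  }, numeric(1))
  expect_gte(mean(ari), 0.8)
})

test_that("identical duplicated blocks merge into one module", {
  set.seed(10)
  n <- 15
  latent <- rnorm(n)
  block <- t(vapply(1:25, function(i) latent + rnorm(n, 0, 0.05), numeric(n)))
  values <- rbind(block, block + matrix(rnorm(25 * n, 0, 0.05), 25, n))
  rownames(values) <- sprintf("g%03d", 1:50)
  asg <- detectWeightedModules(values, minModuleSize = 20)
  labs <- moduleLabels(asg)
  expect_equal(sum(unique(labs) != 0), 1)
})

test_that("module membership matches the closed-form t-test oracle", {
  bs <- blockStudy(nBlocks = 2, blockSize = 25, nNoise = 10, seed = 11)
  asg <- detectWeightedModules(bs$values, minModuleSize = 20)
  mm <- moduleMembership(bs$values, asg)
  n <- ncol(bs$values)
  me <- moduleEigengenes(asg)
  for (i in sample(nrow(mm), 10)) {
    g <- mm$gene[i]
    expected <- cor(bs$values[g, ], me[, paste0("ME", mm$module[i])],
                    method = "spearman")
    expect_equal(mm$MM[i], expected, tolerance = 1e-12)
    tstat <- expected * sqrt((n - 2) / (1 - expected^2))
    expect_equal(mm$p[i], 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }
  expect_true(all(abs(mm$MM) <= 1))
})

test_that("eigengene of a single-gene module is that gene's profile (MM = 1)", {
  x <- rnorm(12)
  e <- moduleEigengene(matrix(x, 1, 12, dimnames = list("g1", NULL)))
  expect_equal(abs(cor(e, x)), 1, tolerance = 1e-12)
  expect_gt(cor(e, x), 0)  # sign orientation
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
})

test_that("a gene equal to minus the eigengene has MM = -1", {
  set.seed(12)
  n <- 15
  latent <- rnorm(n)
  block <- t(vapply(1:24, function(i) latent + rnorm(n, 0, 0.1), numeric(n)))
  anti <- -latent + rnorm(n, 0, 0.01)
  values <- rbind(block, anti = anti)
  rownames(values) <- c(sprintf("g%02d", 1:24), "anti")
  asg <- detectWeightedModules(values, minModuleSize = 20,
                               method = "pearson")
  mm <- moduleMembershipTable(asg)
  expect_lt(mm$MM[mm$gene == "anti"], -0.95)
})

test_that("fewer genes than the minimum size leaves everything unassigned", {
  set.seed(13)
  values <- matrix(rnorm(10 * 15), 10, 15,
                   dimnames = list(paste0("g", 1:10), NULL))
  expect_warning(asg <- detectWeightedModules(values, minModuleSize = 20),
                 "fewer genes")
  expect_true(all(moduleLabels(asg) == 0))
})
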