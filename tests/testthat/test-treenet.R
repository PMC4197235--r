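test_that("a perfectly linear target collapses to a single leaf with the true slope", {
  set.seed(1)
  x <- rnorm(20)
  m <- rbind(x = x, y = 3 * x + 1, z = rnorm(20))
  tree <- buildModelTree("y", m)
  expect_true(tree$root$leaf)
  expect_equal(unname(leafPredictors(tree)["x"]), 3, tolerance = 1e-10)
  expect_equal(tree$relativeError, 0, tolerance = 1e-10)
})

test_that("a target independent of all predictors prunes to a constant leaf", {
  set.seed(2)
  m <- rbind(y = rnorm(30), a = rnorm(30), b = rnorm(30), c = rnorm(30))
  tree <- buildModelTree("y", m)
  expect_true(tree$root$leaf)
  expect_length(leafPredictors(tree), 0)
  expect_gt(tree$relativeError, 0.8)
})

test_that("a piecewise-linear target is split near the breakpoint with both slopes", {
  set.seed(3)
  x <- sort(runif(60, -2, 2))
  y <- ifelse(x <= 0, 2 * x, -2 * x)
  m <- rbind(x = x, y = y, noise = rnorm(60))
  tree <- buildModelTree("y", m)
  expect_false(tree$root$leaf)
  expect_equal(tree$root$var, "x")
  # pure-region leaves recover the generating slopes exactly
  leafSlopes <- unlist(lapply(collectLeaves(tree$root), function(l) l$model$coefs["x"]))
  expect_true(any(abs(leafSlopes - 2) < 0.05))
  expect_true(any(abs(leafSlopes + 2) < 0.05))
})

test_that("relative error matches a hand computation and its limits", {
  # 5 samples: y = (1,2,3,4,5), prediction fixed at mean 3
  y <- 1:5
  baseline <- mean(abs(y - mean(y)))  # = 1.2
  m <- rbind(y = y, x = c(1, 1, 1, 1, 1.0001))
  tree <- buildModelTree("y", m, minLeaf = 2)
  # x is uninformative: constant model predicts the mean
  expect_equal(tree$relativeError, mean(abs(y - 3)) / baseline, tolerance = 1e-6)
  flat <- rbind(y = rep(2, 10), x = rnorm(10))
  expect_equal(buildModelTree("y", flat)$relativeError, 0)
})

test_that("BY adjustment matches the hand-evaluated harmonic step-up", {
  expect_equal(adjustFDRBY(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  expect_equal(adjustFDRBY(0.04), 0.04)  # c(1) = 1
  p <- runif(30)
  expect_true(all(adjustFDRBY(p) >= adjustFDR(p) - 1e-12))
  expect_error(adjustFDRBY(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("a planted signed hub is recovered with correct UP/DOWN labels", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 15
    hub <- rnorm(n, 0, 1.5)
    deps <- list(d1 = 1.0, d2 = 0.8, d3 = -0.8, d4 = -1.0)
    m <- rbind(hub = hub,
               do.call(rbind, lapply(deps, function(sl) sl * hub + rnorm(n, 0, 0.2))),
               matrix(rnorm(10 * n), 10, n,
                      dimnames = list(paste0("bg", 1:10), NULL)))
    rownames(m)[2:5] <- names(deps)
    net <- inferDirectedNetwork(m, theta = 0.3, alpha = 0.05)
    found <- vapply(names(deps), function(d) {
      hit <- net[net$source == "hub" & net$target == d, ]
      nrow(hit) == 1 &&
        hit$direction == ifelse(deps[[d]] > 0, "UP", "DOWN")
    }, logical(1))
    all(found)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("independent genes yield at most the nominal false-edge rate", {
  totalEdges <- 0
  totalTested <- 0
  for (s in 1:25) {
    set.seed(100 + s)
    m <- matrix(rnorm(12 * 15), 12, 15,
                dimnames = list(paste0("g", 1:12), NULL))
    net <- inferDirectedNetwork(m, theta = 0.3, alpha = 0.05)
    totalEdges <- totalEdges + nrow(net)
    totalTested <- totalTested + 12
  }
  expect_lte(totalEdges / totalTested, 0.05)
})

test_that("edge monotonicity: theta and alpha move edge counts the right way", {
  set.seed(9)
  n <- 15
  hub <- rnorm(n, 0, 1.5)
  m <- rbind(hub = hub, d1 = hub + rnorm(n, 0, 0.3),
             d2 = -hub + rnorm(n, 0, 0.3),
             matrix(rnorm(6 * n, 0, 1), 6, n,
                    dimnames = list(paste0("bg", 1:6), NULL)))
  eLoose <- inferDirectedNetwork(m, theta = 0.9, alpha = 0.05)
  eTight <- inferDirectedNetwork(m, theta = 0.2, alpha = 0.05)
  expect_gte(nrow(eLoose), nrow(eTight))
  aLoose <- inferDirectedNetwork(m, theta = 0.3, alpha = 0.2)
  aTight <- inferDirectedNetwork(m, theta = 0.3, alpha = 0.001)
  expect_gte(nrow(aLoose), nrow(aTight))
})

test_that("the planted ptgis hub yields a DOWN edge to acta1a end to end", {
  cfg <- simulationConfig(nGenes = 80, lowExprFraction = 0, probesPerGene = 1,
                          moduleSpec = list(), seed = 31)
  sim <- simulateTimecourseStudy(cfg)
  res <- fitModeratedModel(sim$study)
  collapsed <- collapseToGenes(sim$study, res)
  genes <- c("ptgis", "ca2", "usp2a", "sgce", "acta1a",
             setdiff(rownames(collapsed), c("ptgis", "ca2", "usp2a", "sgce",
                                            "acta1a"))[1:10])
  net <- inferDirectedNetwork(collapsed[genes, ])
  edge <- net[net$source == "ptgis" & net$target == "acta1a", ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$direction, "DOWN")
})
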