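test_that("cohesiveness matches hand-counted cases", {
  clique5 <- edgeNetwork(cliqueEdges(paste0("g", 1:5)))
  # 10 internal edges, no boundary, penalty 2*5: 10/(10+0+10)
  expect_equal(cohesiveness(paste0("g", 1:5), clique5, penalty = 2), 0.5)
  expect_equal(cohesiveness(paste0("g", 1:5), clique5, penalty = 0), 1)
  lone <- GeneNetwork(c("a", "b"), data.frame(from = "a", to = "b", r = 1, mic = 1))
  expect_equal(cohesiveness("a", lone, penalty = 2), 0)       # w_in = 0
  expect_equal(cohesiveness(c("a", "b"), lone, penalty = 2), 1 / 5)  # 1/(1+0+4)
  iso <- GeneNetwork("a")
  expect_equal(cohesiveness("a", iso, penalty = 2), 0)
  expect_error(cohesiveness(character(), clique5), "empty")
})

test_that("match score is 1 on identity, 0 iff disjoint", {
  a <- paste0("g", 1:6)
  expect_equal(matchScore(a, a), 1)
  expect_equal(matchScore(a, paste0("h", 1:4)), 0)
  expect_equal(matchScore(a, paste0("g", 4:9)), 9 / 36)
})

test_that("two bridged cliques are recovered as two modules", {
  e <- rbind(cliqueEdges(paste0("a", 1:8)), cliqueEdges(paste0("b", 1:8)),
             data.frame(from = "a1", to = "b1"))
  net <- edgeNetwork(e)
  mods <- detectCohesiveModules(net, minSize = 5)
  expect_equal(nrow(mods), 2)
  sets <- lapply(mods$members, sort)
  expect_true(list(paste0("a", 1:8)) %in% sets)
  expect_true(list(paste0("b", 1:8)) %in% sets)
  # each clique is a local optimum: no single add/remove improves cohesiveness
  for (cl in list(paste0("a", 1:8), paste0("b", 1:8))) {
    f0 <- cohesiveness(cl, net, 2)
    others <- setdiff(networkNodes(net), cl)
    for (v in others) expect_lte(cohesiveness(c(cl, v), net, 2), f0)
    for (v in cl) expect_lte(cohesiveness(setdiff(cl, v), net, 2), f0)
  }
})

test_that("a complete graph collapses to a single module", {
  net <- edgeNetwork(cliqueEdges(paste0("g", 1:10)))
  mods <- detectCohesiveModules(net, minSize = 5)
  expect_equal(nrow(mods), 1)
  expect_setequal(mods$members[[1]], paste0("g", 1:10))
  expect_equal(mods$density[1], 1)
})

test_that("growth steps never decrease cohesiveness along the greedy path", {
  pp <- plantedPartitionNetwork(c(12, 12), 0.8, 0.05, seed = 21)
  mods <- detectCohesiveModules(pp$network, minSize = 5)
  for (i in seq_len(nrow(mods))) {
    f <- cohesiveness(mods$members[[i]], pp$network, 2)
    expect_gt(f, 0)
  }
})

test_that("merging overlapping clusters is order-independent (fixpoint)", {
  cl <- list(c("a", "b", "c", "d"), c("a", "b", "c", "e"), c("f", "g"))
  merged <- cardioNet:::mergeOverlapping(cl, overlap = 0.5)
  mergedRev <- cardioNet:::mergeOverlapping(rev(cl), overlap = 0.5)
  expect_setequal(lapply(merged, sort), lapply(mergedRev, sort))
  expect_equal(sort(lengths(merged)), c(2, 5))
})

test_that("module significance separates cohesive modules from ragged sets", {
  e <- rbind(cliqueEdges(paste0("a", 1:8)), cliqueEdges(paste0("b", 1:8)),
             data.frame(from = paste0("a", 1:6), to = paste0("b", 1:6)))
  net <- edgeNetwork(e)
  pGood <- moduleSignificance(paste0("a", 1:8), net)  # six boundary nodes, in >> out
  expect_lt(pGood, 0.05)
  # exchangeable null: equal in/out weights on every boundary node
  star <- edgeNetwork(data.frame(from = c("x1", "x1"), to = c("x2", "y1")))
  pNull <- moduleSignificance(c("x1", "x2"), star)
  expect_gt(pNull, 0.3)
  # no boundary: undefined
  expect_true(is.na(moduleSignificance(paste0("g", 1:5),
                                       edgeNetwork(cliqueEdges(paste0("g", 1:5))))))
})

test_that("U statistic matches a direct rank-sum computation", {
  pp <- plantedPartitionNetwork(c(6, 6), 0.9, 0.2, seed = 12)
  members <- names(pp$membership)[pp$membership == 1]
  w <- boundaryWeights(members, pp$network)
  ranks <- rank(c(w$inWeight, w$outWeight))
  n1 <- nrow(w)
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  wt <- suppressWarnings(wilcox.test(w$inWeight, w$outWeight,
                                     alternative = "greater", exact = FALSE))
  expect_equal(unname(wt$statistic), U)
})

test_that("planted-partition modules are recovered with high Jaccard", {
  jac <- vapply(1:20, function(s) {
    pp <- plantedPartitionNetwork(c(15, 15, 15), 0.9, 0.02, seed = s)
    mods <- detectCohesiveModules(pp$network, minSize = 5)
    trueSets <- split(names(pp$membership), pp$membership)
    mean(bestMatchJaccard(trueSets, mods$members))
  }, numeric(1))
  expect_gte(mean(jac), 0.8)
})
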