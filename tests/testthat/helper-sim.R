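# shared fixture builders: everything is generated in code at test time

smallConfig <- function(seed = 1, ...) {
  simulationConfig(nGenes = 80, lowExprFraction = 0, probesPerGene = 1,
                   moduleSpec = list(), hubSpec = list(), seed = seed, ...)
}

# unweighted network from an explicit edge list
edgeNetwork <- function(edges, extraNodes = character()) {
  GeneNetwork(unique(c(edges$from, edges$to, extraNodes)),
              data.frame(from = edges$from, to = edges$to, r = 1, mic = 1))
}

cliqueEdges <- function(nodes) {
  cmb <- combn(sort(nodes), 2)
  data.frame(from = cmb[1, ], to = cmb[2, ])
}

# planted-partition random graph: dense blocks, sparse background
plantedPartitionNetwork <- function(sizes, pin, pout, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(sum(sizes)))
  block <- rep(seq_along(sizes), sizes)
  cmb <- combn(seq_along(nodes), 2)
  same <- block[cmb[1, ]] == block[cmb[2, ]]
  keep <- runif(ncol(cmb)) < ifelse(same, pin, pout)
  net <- edgeNetwork(data.frame(from = nodes[cmb[1, keep]],
                                to = nodes[cmb[2, keep]]),
                     extraNodes = nodes)
  list(network = net, membership = setNames(block, nodes))
}

collectLeaves <- function(node) {
  if (node$leaf) return(list(node))
  c(collectLeaves(node$left), collectLeaves(node$right))
}

bestMatchJaccard <- function(trueSets, foundSets) {
  vapply(trueSets, function(ts) {
    if (!length(foundSets)) return(0)
    max(vapply(foundSets, function(fs) {
      length(intersect(ts, fs)) / length(union(ts, fs))
    }, numeric(1)))
  }, numeric(1))
}
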