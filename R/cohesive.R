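#' Cohesiveness of a node set
#'
#' f(V) = w_in / (w_in + w_bound + p |V|), where w_in counts edges inside V,
#' w_bound counts edges crossing the boundary (each edge has weight 1 in
#' unweighted mode) and p penalises every member, modelling unobserved
#' external connections.
#'
#' @param members node set (character).
#' @param network a \linkS4class{GeneNetwork}.
#' @param penalty per-node penalty p >= 0.
#' @return Cohesiveness in [0, 1].
#' @examples
#' net <- GeneNetwork(letters[1:5], data.frame(
#'   from = combn(letters[1:5], 2)[1, ], to = combn(letters[1:5], 2)[2, ],
#'   r = 1, mic = 1))
#' cohesiveness(letters[1:5], net, penalty = 2)  # 10/(10+0+10) = 0.5
#' @export
cohesiveness <- function(members, network, penalty = 2) {
  if (!length(members)) stop("empty node set")
  e <- networkEdges(network)
  inFrom <- e$from %in% members
  inTo <- e$to %in% members
  wIn <- sum(inFrom & inTo)
  wBound <- sum(xor(inFrom, inTo))
  denom <- wIn + wBound + penalty * length(members)
  if (denom == 0) 0 else wIn / denom
}

#' Overlap (match) score between two node sets
#'
#' omega(A, B) = |A intersect B|^2 / (|A| |B|); 1 for identical sets, 0 iff
#' disjoint.
#'
#' @param a,b node sets.
#' @return Match score in [0, 1].
#' @export
matchScore <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Detect overlapping cohesive modules
#'
#' Greedy seeded growth of cohesive groups, merging of heavily overlapping
#' groups, and size/density filtering:
#' \enumerate{
#' \item Seeds are unused nodes in decreasing degree order (ties broken
#'   lexicographically). From each seed the single add-or-remove step that
#'   most increases cohesiveness is applied until no step improves it.
#' \item Any pair of groups with match score >= \code{overlap} is merged;
#'   merging proceeds on connected components of the overlap graph and is
#'   repeated to a fixpoint, making the result independent of pair order.
#' \item Groups smaller than \code{minSize} or with edge density below
#'   \code{density} ("auto" = 0.5 for unweighted networks) are dropped.
#' }
#' The haircut step is retained as a parameter for fidelity with the original
#' procedure; at its default threshold 0 it is a no-op.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param minSize minimum module size.
#' @param density minimum edge density, or "auto".
#' @param penalty per-node penalty p of the cohesiveness objective.
#' @param haircut haircut threshold (0 disables).
#' @param overlap merge threshold omega.
#' @return data.frame(module, size, density, cohesiveness, p, members) with
#'   \code{members} a list column of node sets.
#' @export
detectCohesiveModules <- function(network, minSize = 5, density = "auto",
                                  penalty = 2, haircut = 0, overlap = 0.8) {
  nodes <- networkNodes(network)
  if (!length(nodes)) stop("empty network")
  adj <- adjacencyList(network)
  deg <- vapply(adj, length, integer(1))
  seeds <- nodes[order(-deg, nodes)]

  clusters <- list()
  used <- character()
  for (s in seeds) {
    if (s %in% used) next
    cl <- growCluster(s, adj, penalty)
    clusters[[length(clusters) + 1L]] <- cl
    used <- union(used, cl)
  }
  clusters <- unique(lapply(clusters, sort))
  clusters <- mergeOverlapping(clusters, overlap)
  if (haircut > 0) clusters <- lapply(clusters, applyHaircut, adj, haircut)

  thr <- if (identical(density, "auto")) 0.5 else density
  rows <- lapply(clusters, function(cl) {
    sz <- length(cl)
    ec <- countInternalEdges(cl, adj)
    dens <- if (sz > 1) ec / (sz * (sz - 1) / 2) else 0
    data.frame(size = sz, density = dens,
               cohesiveness = cohesiveness(cl, network, penalty),
               p = moduleSignificance(cl, network))
  })
  out <- do.call(rbind, rows)
  keep <- out$size >= minSize & out$density >= thr
  out <- out[keep, , drop = FALSE]
  clusters <- clusters[keep]
  ord <- order(out$p, -out$size)
  out <- out[ord, , drop = FALSE]
  out <- cbind(module = seq_len(nrow(out)), out)
  out$members <- clusters[ord]
  rownames(out) <- NULL
  out
}

adjacencyList <- function(network) {
  e <- networkEdges(network)
  adj <- setNames(vector("list", length(networkNodes(network))),
                  networkNodes(network))
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  adj
}

countInternalEdges <- function(members, adj) {
  sum(vapply(members, function(v) sum(adj[[v]] %in% members), numeric(1))) / 2
}

# grow a cluster from one seed by best single add/remove steps; each accepted
# step strictly increases cohesiveness, so termination is guaranteed
growCluster <- function(seed, adj, penalty) {
  members <- seed
  f <- cohesivenessAdj(members, adj, penalty)
  repeat {
    ext <- setdiff(sort(unique(unlist(adj[members]))), members)
    cand <- c(ext, if (length(members) > 1) members)
    action <- c(rep("add", length(ext)),
                if (length(members) > 1) rep("rm", length(members)))
    if (!length(cand)) break
    scores <- vapply(seq_along(cand), function(i) {
      m2 <- if (action[i] == "add") c(members, cand[i]) else setdiff(members, cand[i])
      cohesivenessAdj(m2, adj, penalty)
    }, numeric(1))
    best <- which(scores > f + 1e-12)
    if (!length(best)) break
    # highest score; prefer additions, then lexicographically smallest node
    best <- best[order(-scores[best], action[best] != "add", cand[best])][1]
    members <- if (action[best] == "add") c(members, cand[best])
               else setdiff(members, cand[best])
    f <- scores[best]
  }
  sort(members)
}

cohesivenessAdj <- function(members, adj, penalty) {
  wIn <- countInternalEdges(members, adj)
  degSum <- sum(vapply(members, function(v) length(adj[[v]]), numeric(1)))
  wBound <- degSum - 2 * wIn
  denom <- wIn + wBound + penalty * length(members)
  if (denom == 0) 0 else wIn / denom
}

mergeOverlapping <- function(clusters, overlap) {
  repeat {
    k <- length(clusters)
    if (k < 2) return(clusters)
    merged <- FALSE
    # overlap graph; union its connected components
    comp <- seq_len(k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (matchScore(clusters[[i]], clusters[[j]]) >= overlap) {
        ci <- comp[i]; cj <- comp[j]
        if (ci != cj) { comp[comp == cj] <- ci; merged <- TRUE }
      }
    }
    if (!merged) return(clusters)
    clusters <- unname(lapply(split(seq_len(k), comp), function(idx) {
      sort(unique(unlist(clusters[idx])))
    }))
  }
}

applyHaircut <- function(members, adj, threshold) {
  repeat {
    inDeg <- vapply(members, function(v) sum(adj[[v]] %in% members), numeric(1))
    cut <- members[inDeg < threshold * mean(inDeg)]
    if (!length(cut) || length(cut) == length(members)) return(members)
    members <- setdiff(members, cut)
  }
}

#' Boundary-separation significance of a module
#'
#' One-sided Mann-Whitney test comparing, over the module's boundary vertices
#' (members with at least one external edge), the in-module edge weight sums
#' against the out-of-module edge weight sums. A small p indicates that
#' boundary nodes are much more strongly tied to the module than to the rest
#' of the network. With no boundary vertices the p-value is undefined (NA).
#'
#' @param members module node set.
#' @param network a \linkS4class{GeneNetwork}.
#' @return p-value, or NA when undefined.
#' @export
moduleSignificance <- function(members, network) {
  w <- boundaryWeights(members, network)
  if (!nrow(w)) return(NA_real_)
  suppressWarnings(
    wilcox.test(w$inWeight, w$outWeight, alternative = "greater",
                exact = FALSE, correct = TRUE)$p.value)
}

#' @rdname moduleSignificance
#' @return \code{boundaryWeights}: data.frame(node, inWeight, outWeight) over
#'   boundary vertices.
#' @export
boundaryWeights <- function(members, network) {
  adj <- adjacencyList(network)
  members <- intersect(members, names(adj))
  inw <- vapply(members, function(v) sum(adj[[v]] %in% members), numeric(1))
  outw <- vapply(members, function(v) sum(!adj[[v]] %in% members), numeric(1))
  boundary <- outw > 0
  data.frame(node = members[boundary], inWeight = inw[boundary],
             outWeight = outw[boundary], row.names = NULL)
}
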