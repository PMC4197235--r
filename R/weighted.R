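#' Soft-thresholded adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta with zero diagonal (so connectivity sums
#' exclude self-adjacency). Raising the correlation to a power suppresses
#' weak, chance-level links without a hard cutoff. Constant genes have their
#' correlations treated as 0.
#'
#' @param study gene-level \linkS4class{ExpressionStudy} or genes x samples
#'   matrix (>= 4 samples).
#' @param beta soft-thresholding power (>= 1).
#' @param method correlation type, Spearman by default, pairwise-complete.
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @export
softAdjacency <- function(study, beta = 10, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  if (ncol(values) < 4) stop("need at least 4 samples")
  r <- correlationMatrix(values, method)
  r[!is.finite(r)] <- 0
  a <- abs(r)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i = sum_u a_iu and TOM_ii = 1: genes are strongly linked when they share
#' many correlated neighbours, even if their direct adjacency is modest.
#'
#' @param adjacency symmetric matrix with entries in [0, 1].
#' @return TOM matrix in [0, 1] with unit diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  stopifnot(isSymmetric(unname(a)), all(a >= -1e-12 & a <= 1 + 1e-12))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect weighted-network modules
#'
#' Soft adjacency -> TOM -> distance 1 - TOM -> average-linkage hierarchical
#' clustering -> dynamic hybrid cut in a reduced, documented form: the
#' dendrogram is cut statically at \code{cutHeight} (default 0.99); below the
#' cap a branch is split into its two children whenever both could stand as
#' modules of at least \code{minModuleSize} genes (recursively), surviving
#' branches of at least \code{minModuleSize} genes become modules, and
#' unlabeled genes
#' are assigned to the nearest module by average TOM distance provided they
#' lie no farther from it than the module's farthest current member (the
#' published heuristic's core scatter step is omitted). Module eigengenes (first principal component of
#' the standardised module submatrix, sign-oriented to correlate positively
#' with the module mean profile) are computed and modules whose eigengene
#' dissimilarity 1 - cor falls below \code{mergeHeight} are merged
#' iteratively. Final module labels are renumbered by decreasing size;
#' label 0 marks unassigned genes.
#'
#' @param study gene-level \linkS4class{ExpressionStudy} or genes x samples
#'   matrix.
#' @param beta soft power.
#' @param method correlation type for the adjacency ("spearman" or
#'   "pearson").
#' @param minModuleSize minimum module size.
#' @param mergeHeight eigengene-dissimilarity merge threshold.
#' @param cutHeight static cut height on the 1 - TOM dendrogram.
#' @return A \linkS4class{ModuleAssignment}.
#' @export
detectWeightedModules <- function(study, beta = 10,
                                  method = c("spearman", "pearson"),
                                  minModuleSize = 20, mergeHeight = 0.15,
                                  cutHeight = 0.99) {
  method <- match.arg(method)
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  genes <- rownames(values)
  if (nrow(values) < minModuleSize) {
    warning("fewer genes than the minimum module size; all unassigned")
    return(emptyAssignment(genes, values, method))
  }
  a <- softAdjacency(values, beta, method)
  tom <- topologicalOverlap(a)
  d <- 1 - tom
  hc <- hclust(as.dist(d), method = "average")
  clusters <- cutBranchesBySize(hc, cutHeight, minModuleSize)
  labels <- setNames(integer(length(genes)), genes)
  for (m in seq_along(clusters)) labels[clusters[[m]]] <- m
  eligible <- seq_along(clusters)

  # nearest-module assignment of unlabeled genes by average TOM distance;
  # a gene joins only if it lies no farther from the module than the module's
  # own periphery (its farthest current member)
  if (any(labels == 0L) && length(eligible)) {
    periphery <- vapply(seq_along(eligible), function(m) {
      idx <- which(labels == m)
      max(vapply(idx, function(g) mean(d[g, setdiff(idx, g)]), numeric(1)))
    }, numeric(1))
    for (g in which(labels == 0L)) {
      avg <- vapply(seq_along(eligible), function(m) {
        mean(d[g, labels == m])
      }, numeric(1))
      best <- which.min(avg)
      if (avg[best] <= periphery[best]) labels[g] <- best
    }
  }
  if (!any(labels != 0L)) return(emptyAssignment(genes, values, method))

  labels <- mergeByEigengene(labels, values, mergeHeight)
  labels <- relabelBySize(labels)
  me <- eigengeneMatrix(labels, values)
  mm <- membershipTable(labels, values, me, method)
  new("ModuleAssignment", labels = labels, eigengenes = me,
      membership = mm, corMethod = method)
}

# Reduced dynamic branch evaluation on an average-linkage dendrogram:
# branches above the height cap are never joined; below it, a branch is split
# into its two children whenever both are large enough to stand as modules on
# their own, recursively.  Returns clusters of size >= minSize (leaf indices).
cutBranchesBySize <- function(hc, cutHeight, minSize) {
  nm <- nrow(hc$merge)
  members <- vector("list", nm)
  for (i in seq_len(nm)) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) -m[1] else members[[m[1]]],
                      if (m[2] < 0) -m[2] else members[[m[2]]])
  }
  parent <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    m <- hc$merge[i, ]
    if (m[1] > 0) parent[m[1]] <- i
    if (m[2] > 0) parent[m[2]] <- i
  }
  tops <- which(hc$height <= cutHeight &
                (is.na(parent) | hc$height[parent] > cutHeight))
  splitRec <- function(i) {
    m <- hc$merge[i, ]
    ls <- if (m[1] < 0) 1L else length(members[[m[1]]])
    rs <- if (m[2] < 0) 1L else length(members[[m[2]]])
    if (ls >= minSize && rs >= minSize) c(splitRec(m[1]), splitRec(m[2]))
    else list(members[[i]])
  }
  clusters <- unlist(lapply(tops, splitRec), recursive = FALSE)
  clusters[lengths(clusters) >= minSize]
}

emptyAssignment <- function(genes, values, method) {
  new("ModuleAssignment",
      labels = setNames(integer(length(genes)), genes),
      eigengenes = matrix(numeric(), ncol(values), 0,
                          dimnames = list(colnames(values), NULL)),
      membership = data.frame(gene = character(), module = integer(),
                              MM = numeric(), p = numeric()),
      corMethod = method)
}

#' Module eigengene
#'
#' First principal component (unit norm) of the row-standardised module
#' submatrix, sign-oriented to correlate positively with the module's mean
#' standardised profile. A single-gene module's eigengene is that gene's
#' standardised profile (normalised).
#'
#' @param values genes x samples matrix (module members only).
#' @return Numeric per-sample eigengene of unit norm.
#' @export
moduleEigengene <- function(values) {
  z <- t(scale(t(values)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  meanProfile <- colMeans(z)
  if (sum(e * meanProfile) < 0) e <- -e
  setNames(e, colnames(values))
}

eigengeneMatrix <- function(labels, values) {
  mods <- sort(unique(labels[labels != 0]))
  me <- vapply(mods, function(m) {
    moduleEigengene(values[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(values)))
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(values), paste0("ME", mods)))
  me
}

mergeByEigengene <- function(labels, values, mergeHeight) {
  repeat {
    mods <- sort(unique(labels[labels != 0]))
    if (length(mods) < 2) return(labels)
    me <- eigengeneMatrix(labels, values)
    dis <- 1 - cor(me)
    diag(dis) <- Inf
    mn <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[mn[1], mn[2]] >= mergeHeight) return(labels)
    from <- mods[max(mn)]; to <- mods[min(mn)]
    labels[labels == from] <- to
  }
}

relabelBySize <- function(labels) {
  mods <- sort(table(labels[labels != 0]), decreasing = TRUE)
  map <- setNames(seq_along(mods), names(mods))
  out <- ifelse(labels == 0, 0L, as.integer(map[as.character(labels)]))
  setNames(out, names(labels))
}

membershipTable <- function(labels, values, me, method) {
  n <- ncol(values)
  assigned <- names(labels)[labels != 0]
  if (!length(assigned))
    return(data.frame(gene = character(), module = integer(),
                      MM = numeric(), p = numeric()))
  mm <- vapply(assigned, function(g) {
    cor(values[g, ], me[, paste0("ME", labels[[g]])], method = method)
  }, numeric(1))
  tstat <- mm * sqrt((n - 2) / pmax(1 - mm^2, .Machine$double.eps))
  data.frame(gene = assigned, module = unname(labels[assigned]),
             MM = unname(mm), p = 2 * pt(-abs(tstat), df = n - 2),
             row.names = NULL)
}

#' Signed module membership of every assigned gene
#'
#' MM_g = cor(x_g, eigengene of g's module) with the assignment's correlation
#' type; the two-sided p comes from t = MM sqrt((n-2)/(1-MM^2)) on n - 2
#' degrees of freedom. Negative MM marks genes anti-correlated with their
#' module's consensus profile. Unassigned genes are absent from the table.
#'
#' @param study the study the assignment was computed on.
#' @param assignment a \linkS4class{ModuleAssignment}.
#' @return data.frame(gene, module, MM, p).
#' @export
moduleMembership <- function(study, assignment) {
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  membershipTable(moduleLabels(assignment), values,
                  moduleEigengenes(assignment), assignment@corMethod)
}
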