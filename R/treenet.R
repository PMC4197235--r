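#' Build a model tree for one target gene
#'
#' M5'-style regression: recursive splitting on the predictor/threshold pair
#' maximising the standard-deviation reduction
#' SDR = sd(T) - sum_i |T_i|/|T| sd(T_i); splitting stops when a node's sd
#' falls below 5% of the root sd or fewer than 2 * minLeaf samples remain.
#' Each node carries a least-squares linear model over the predictors used in
#' splits within its subtree plus the target's strongest global correlates
#' (the global-similarity mode: a linear dependency over all samples is always
#' on offer), simplified by best-drop backward elimination under the
#' (n + 2v)/(n - v) penalised mean absolute error (a constant model is always
#' a candidate). Pruning replaces a subtree by its node model when the node's
#' penalised error does not exceed the subtree's. Predictions are smoothed
#' along the root path with the classic k = 15 blending.
#'
#' @param target target gene id.
#' @param study an \linkS4class{ExpressionStudy} (gene-level) or genes x
#'   samples matrix containing \code{target}.
#' @param minLeaf minimum samples per leaf.
#' @param smoothing smoothing constant k.
#' @param sdFraction stop splitting below this fraction of the root sd.
#' @return An object of class \code{modelTree} with elements \code{root}
#'   (recursive node list), \code{target}, \code{relativeError}.
#' @export
buildModelTree <- function(target, study, minLeaf = 4, smoothing = 15,
                           sdFraction = 0.05) {
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  if (!target %in% rownames(values)) stop("target not in study: ", target)
  y <- values[target, ]
  X <- t(values[setdiff(rownames(values), target), , drop = FALSE])
  if (length(y) < 2 * minLeaf)
    stop("need at least 2 * minLeaf samples")
  rootSd <- sd(y)
  if (!is.finite(rootSd) || rootSd == 0) {
    root <- list(leaf = TRUE, n = length(y),
                 model = list(intercept = mean(y), coefs = numeric()),
                 err = 0)
    tree <- structure(list(root = root, target = target, smoothing = smoothing),
                      class = "modelTree")
    tree$relativeError <- 0
    return(tree)
  }
  root <- splitNode(y, X, seq_along(y), minLeaf, sdFraction * rootSd)
  # global-similarity candidates: the target's strongest global correlates are
  # always offered to the node models alongside the subtree split variables
  globalCand <- topCorrelated(y, X, k = 3)
  root <- attachModels(root, y, X, globalCand)
  root <- pruneNode(root, y, X)
  tree <- structure(list(root = root, target = target, smoothing = smoothing),
                    class = "modelTree")
  tree$relativeError <- treeRelativeError(tree, study)
  tree
}

splitNode <- function(y, X, idx, minLeaf, sdStop) {
  node <- list(leaf = TRUE, idx = idx, n = length(idx))
  if (length(idx) < 2 * minLeaf || sd(y[idx]) < sdStop) return(node)
  best <- findBestSplit(y, X, idx, minLeaf)
  if (is.null(best)) return(node)
  left <- idx[X[idx, best$var] <= best$threshold]
  right <- setdiff(idx, left)
  node$leaf <- FALSE
  node$var <- best$var
  node$threshold <- best$threshold
  node$left <- splitNode(y, X, left, minLeaf, sdStop)
  node$right <- splitNode(y, X, right, minLeaf, sdStop)
  node
}

findBestSplit <- function(y, X, idx, minLeaf) {
  sdT <- sd(y[idx])
  n <- length(idx)
  best <- NULL
  bestSDR <- 1e-12
  for (v in colnames(X)) {
    xv <- X[idx, v]
    uv <- sort(unique(xv))
    if (length(uv) < 2) next
    for (ci in seq_len(length(uv) - 1)) {
      thr <- (uv[ci] + uv[ci + 1]) / 2
      leftN <- sum(xv <= thr)
      if (leftN < minLeaf || n - leftN < minLeaf) next
      sl <- sd(y[idx][xv <= thr])
      sr <- sd(y[idx][xv > thr])
      sdr <- sdT - (leftN / n) * sl - ((n - leftN) / n) * sr
      if (sdr > bestSDR) { bestSDR <- sdr; best <- list(var = v, threshold = thr) }
    }
  }
  best
}

subtreeVars <- function(node) {
  if (node$leaf) return(character())
  unique(c(node$var, subtreeVars(node$left), subtreeVars(node$right)))
}

# strongest global correlates of the target, screened for significance so
# that null predictors are not forced into the node models
topCorrelated <- function(y, X, k = 3, pScreen = 0.01) {
  r <- suppressWarnings(cor(X, y))[, 1]
  r[!is.finite(r)] <- 0
  n <- length(y)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-tstat, df = n - 2)
  cand <- colnames(X)[p < pScreen]
  cand[order(-abs(r[cand]))][seq_len(min(k, length(cand)))]
}

# fit the node's linear model: backward elimination over the subtree split
# predictors plus the global candidates, under penalised mean absolute error;
# a constant model is always considered
attachModels <- function(node, y, X, globalCand = character()) {
  vars <- union(subtreeVars(node), globalCand)
  node$model <- eliminateModel(y[node$idx], X[node$idx, , drop = FALSE], vars)
  node$err <- modelError(node$model, y[node$idx], X[node$idx, , drop = FALSE])
  if (!node$leaf) {
    node$left <- attachModels(node$left, y, X, globalCand)
    node$right <- attachModels(node$right, y, X, globalCand)
  }
  node
}

fitLinear <- function(yv, Xv, vars) {
  if (!length(vars)) return(list(intercept = mean(yv), coefs = numeric()))
  A <- cbind(1, Xv[, vars, drop = FALSE])
  cf <- qr.coef(qr(A), yv)
  cf[is.na(cf)] <- 0
  list(intercept = unname(cf[1]), coefs = setNames(unname(cf[-1]), vars))
}

predictLinear <- function(model, Xv) {
  p <- rep(model$intercept, nrow(Xv))
  for (v in names(model$coefs)) p <- p + model$coefs[[v]] * Xv[, v]
  p
}

modelError <- function(model, yv, Xv) {
  mean(abs(yv - predictLinear(model, Xv)))
}

# pruning factor 2 on the parameter count, as in the classic implementation
penalisedError <- function(model, yv, Xv) {
  n <- length(yv)
  v <- length(model$coefs) + 1
  pen <- if (n > v) (n + 2 * v) / (n - v) else 1e6
  modelError(model, yv, Xv) * pen
}

eliminateModel <- function(yv, Xv, vars) {
  model <- fitLinear(yv, Xv, vars)
  pe <- penalisedError(model, yv, Xv)
  repeat {
    if (!length(model$coefs)) break
    # best-drop backward elimination, deterministic
    cands <- lapply(names(model$coefs), function(drop) {
      fitLinear(yv, Xv, setdiff(names(model$coefs), drop))
    })
    cpes <- vapply(cands, penalisedError, numeric(1), yv = yv, Xv = Xv)
    best <- which.min(cpes)
    if (cpes[best] <= pe + 1e-12) { model <- cands[[best]]; pe <- cpes[best] }
    else break
  }
  model
}

# collapse a subtree to a leaf when the node model's penalised error is no
# worse than the subtree's; the subtree is charged for every leaf parameter
# and for each split threshold it spends
pruneNode <- function(node, y, X) {
  if (node$leaf) return(node)
  node$left <- pruneNode(node$left, y, X)
  node$right <- pruneNode(node$right, y, X)
  st <- subtreeStats(node)
  n <- node$n
  v <- st$params
  penalty <- if (n > v) (n + 2 * v) / (n - v) else 1e6
  subPE <- st$rawErr * penalty
  nodePE <- penalisedError(node$model, y[node$idx], X[node$idx, , drop = FALSE])
  if (nodePE <= subPE + 1e-12) {
    node <- list(leaf = TRUE, idx = node$idx, n = node$n,
                 model = node$model, err = node$err)
  }
  node
}

# sample-weighted raw error and parameter count (leaf coefficients +
# intercepts + one per split) of a subtree
subtreeStats <- function(node) {
  if (node$leaf) {
    return(list(rawErr = node$err, params = length(node$model$coefs) + 1))
  }
  l <- subtreeStats(node$left)
  r <- subtreeStats(node$right)
  list(rawErr = (node$left$n * l$rawErr + node$right$n * r$rawErr) / node$n,
       params = l$params + r$params + 1)
}

#' Predict from a model tree (with path smoothing)
#'
#' @param object a \code{modelTree}.
#' @param newdata samples x genes matrix (defaults to training data layout).
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.modelTree <- function(object, newdata, ...) {
  Xv <- as.matrix(newdata)
  vapply(seq_len(nrow(Xv)), function(i) {
    predictSmoothed(object$root, Xv[i, , drop = FALSE], object$smoothing)
  }, numeric(1))
}

predictSmoothed <- function(node, xrow, k) {
  if (node$leaf) return(predictLinear(node$model, xrow))
  child <- if (xrow[, node$var] <= node$threshold) node$left else node$right
  pChild <- predictSmoothed(child, xrow, k)
  pNode <- predictLinear(node$model, xrow)
  (child$n * pChild + k * pNode) / (child$n + k)
}

#' Relative error of a model tree
#'
#' Mean absolute prediction error divided by the mean absolute deviation of
#' the target from its mean; 0 for a perfect fit, ~1 for a constant-mean
#' predictor. A zero-variance target has relative error 0 by definition.
#'
#' @param tree a \code{modelTree}.
#' @param study the study it was trained on.
#' @return Relative error fraction (>= 0).
#' @export
treeRelativeError <- function(tree, study) {
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  y <- values[tree$target, ]
  X <- t(values[setdiff(rownames(values), tree$target), , drop = FALSE])
  baseline <- mean(abs(y - mean(y)))
  if (baseline == 0) return(0)
  pred <- predict.modelTree(tree, X)
  mean(abs(y - pred)) / baseline
}

#' Predictors used in a tree's leaf models
#'
#' @param tree a \code{modelTree}.
#' @return Named numeric vector of sample-size-weighted mean leaf
#'   coefficients, one per predictor with a nonzero coefficient in any leaf.
#' @export
leafPredictors <- function(tree) {
  acc <- new.env()
  walk <- function(node) {
    if (node$leaf) {
      for (v in names(node$model$coefs)) {
        cf <- node$model$coefs[[v]]
        if (abs(cf) > 1e-8) {
          prev <- if (exists(v, envir = acc, inherits = FALSE)) acc[[v]] else c(0, 0)
          acc[[v]] <- prev + c(cf * node$n, node$n)
        }
      }
    } else { walk(node$left); walk(node$right) }
  }
  walk(tree$root)
  vars <- ls(acc)
  setNames(vapply(vars, function(v) acc[[v]][1] / acc[[v]][2], numeric(1)), vars)
}

# relative error of the single-predictor OLS of y on each row of X
pairwiseRelativeError <- function(y, X) {
  baseline <- mean(abs(y - mean(y)))
  if (baseline == 0) return(rep(0, nrow(X)))
  apply(X, 1, function(x) {
    vx <- var(x)
    if (!is.finite(vx) || vx == 0) return(Inf)
    b <- cov(x, y) / vx
    a <- mean(y) - b * mean(x)
    mean(abs(y - a - b * x)) / baseline
  })
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' Step-up FDR control valid under arbitrary dependence, with harmonic
#' correction c(m) = sum_{i=1..m} 1/i:
#' adjusted_i = min_{j >= i} (m c(m) p_(j) / j), capped at 1.
#'
#' @param p raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @examples
#' adjustFDRBY(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
adjustFDRBY <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Infer a directed, signed association network with model trees
#'
#' For each target gene a model tree is trained on the remaining genes;
#' targets whose tree has relative error above \code{theta} contribute no
#' edges. Hypothetical evidences of association for a retained target are (a)
#' every predictor with a nonzero coefficient in the tree's leaf models
#' (localised similarity) and (b), when \code{globalEvidence} is TRUE, every
#' predictor whose single-predictor linear model over all samples meets the
#' same relative-error standard \code{theta} (global similarity; with
#' near-collinear co-regulated predictors the tree keeps one of them
#' essentially at random, and the global rule restores the rest). Each
#' evidence is scored by the two-sided t-test of the predictor-target Pearson
#' correlation (df = n - 2); p-values are Benjamini-Yekutieli adjusted jointly
#' and edges with adjusted p below \code{alpha} are kept. The reported slope
#' is the pairwise linear model of target on predictor, and the direction
#' label follows its sign: UP for a positive, DOWN for a negative
#' association.
#'
#' @param study gene-level \linkS4class{ExpressionStudy} or genes x samples
#'   matrix.
#' @param genes optional gene subset (>= 2 genes).
#' @param theta relative-error gate on target trees and global evidences.
#' @param alpha FDR level for BY-adjusted edge p-values.
#' @param minLeaf minimum samples per tree leaf.
#' @param globalEvidence also admit global pairwise linear dependencies
#'   meeting \code{theta} for retained targets.
#' @return data.frame(source, target, slope, direction, p, adj_p).
#' @export
inferDirectedNetwork <- function(study, genes = NULL, theta = 0.30,
                                 alpha = 0.05, minLeaf = 4,
                                 globalEvidence = TRUE) {
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  if (!is.null(genes)) values <- values[genes, , drop = FALSE]
  if (nrow(values) < 2) stop("need at least 2 genes")
  n <- ncol(values)
  recs <- list()
  for (target in rownames(values)) {
    tree <- buildModelTree(target, values, minLeaf = minLeaf)
    if (tree$relativeError > theta) next
    cand <- names(leafPredictors(tree))
    if (globalEvidence) {
      others <- setdiff(rownames(values), target)
      pre <- pairwiseRelativeError(values[target, ],
                                   values[others, , drop = FALSE])
      cand <- union(cand, others[pre <= theta])
    }
    for (v in cand) {
      r <- cor(values[v, ], values[target, ])
      if (!is.finite(r)) next
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      pval <- 2 * pt(-abs(tstat), df = n - 2)
      # the reported association is the pairwise linear model target ~ source
      slope <- cov(values[v, ], values[target, ]) / var(values[v, ])
      recs[[length(recs) + 1L]] <- data.frame(
        source = v, target = target, slope = slope, p = pval)
    }
  }
  if (!length(recs))
    return(data.frame(source = character(), target = character(),
                      slope = numeric(), direction = character(),
                      p = numeric(), adj_p = numeric()))
  out <- do.call(rbind, recs)
  out$adj_p <- adjustFDRBY(out$p)
  out <- out[out$adj_p < alpha, , drop = FALSE]
  out$direction <- ifelse(out$slope > 0, "UP", "DOWN")
  out <- out[order(out$adj_p, out$source, out$target),
             c("source", "target", "slope", "direction", "p", "adj_p")]
  rownames(out) <- NULL
  out
}
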