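#' Maximal information coefficient
#'
#' Computes MIC(x, y): the maximum over grid resolutions (a, b) with
#' a * b <= B(n) of the grid mutual information normalised by
#' log2(min(a, b)), where B(n) = max(n^alpha, 4). Grid lines may only fall
#' between distinct data values on each axis. For each row count b the row
#' partition is enumerated exhaustively whenever the number of candidate
#' partitions is at most \code{maxPartitions} (always the case at the sample
#' sizes this package targets); for each row partition the optimal column
#' partition is found exactly by the standard dynamic-programming column
#' optimisation. When the row-partition count explodes (large n) the row axis
#' falls back to equipartition, which is the classic estimator's behaviour.
#' Both axis orientations are searched, so the result is symmetric in x and y.
#'
#' A constant vector carries no information: MIC = 0.
#'
#' @param x,y paired numeric vectors (n >= 4 complete pairs).
#' @param alpha grid-size exponent; B(n) = max(n^alpha, 4).
#' @param maxPartitions exhaustive-enumeration budget per (axis, b).
#' @return MIC in [0, 1].
#' @examples
#' x <- seq_len(16)
#' micScore(x, x^3)   # 1: monotone noiseless
#' @export
micScore <- function(x, y, alpha = 0.6, maxPartitions = 20000) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  B <- max(n^alpha, 4)
  best <- 0
  for (orient in 1:2) {
    rowv <- if (orient == 1) y else x
    colv <- if (orient == 1) x else y
    bmax <- floor(B / 2)
    for (b in 2:bmax) {
      amax <- floor(B / b)
      if (amax < 2) break
      parts <- rowPartitions(rowv, b, maxPartitions)
      for (rows in parts) {
        best <- max(best, bestNormalisedMI(colv, rows, b, amax))
      }
    }
  }
  min(1, max(0, best))
}

# All assignments of points to b contiguous row bins (by sorted distinct
# value), as integer label vectors; equipartition fallback when too many.
rowPartitions <- function(v, b, maxPartitions) {
  uv <- sort(unique(v))
  d <- length(uv)
  if (d < b) return(list())
  rank <- match(v, uv)
  nCuts <- choose(d - 1, b - 1)
  if (nCuts <= maxPartitions) {
    cuts <- combn(d - 1, b - 1)
    lapply(seq_len(ncol(cuts)), function(j) {
      breaks <- c(0, cuts[, j], d)
      findInterval(rank, breaks + 0.5)
    })
  } else {
    # equipartition: split sorted points into b near-equal groups, keeping
    # ties together
    targets <- ceiling(seq_len(b - 1) * length(v) / b)
    ord <- sort(v)
    cutVals <- unique(ord[targets])
    list(findInterval(v, cutVals, left.open = TRUE) + 1L)
  }
}

# For a fixed row labelling, DP over column cut positions; returns the best
# I(cols; rows) / log2(min(a, b)) over all column counts 2..amax.
bestNormalisedMI <- function(colv, rows, b, amax) {
  n <- length(colv)
  ord <- order(colv)
  cv <- colv[ord]
  rl <- rows[ord]
  # candidate cut positions: after index i where cv[i] < cv[i+1]
  cutPos <- which(diff(cv) > 0)
  bounds <- c(0L, cutPos, n)        # segment boundaries (prefix sizes)
  m <- length(bounds)
  if (m < 3) return(0)
  # prefix counts of row labels
  pref <- matrix(0L, m, b)
  cnt <- integer(b)
  bi <- 2L
  for (i in seq_len(n)) {
    cnt[rl[i]] <- cnt[rl[i]] + 1L
    if (bounds[bi] == i) { pref[bi, ] <- cnt; bi <- bi + 1L }
  }
  rowTot <- pref[m, ]
  Hrow <- entropyBits(rowTot / n)
  # term(i, j): contribution H(P) - H(P,Q) of a column spanning
  # boundary i..j (exclusive prefix i, inclusive prefix j)
  term <- function(i, j) {
    nc <- bounds[j] - bounds[i]
    cells <- pref[j, ] - pref[i, ]
    p <- nc / n
    -p * log2(p) + sum(ifelse(cells > 0, (cells / n) * log2(cells / n), 0))
  }
  maxA <- min(amax, m - 1)
  # f[j, l]: best sum of terms over first j-th boundary with exactly l columns
  f <- matrix(-Inf, m, maxA)
  for (j in 2:m) f[j, 1] <- term(1L, j)
  if (maxA >= 2) {
    for (l in 2:maxA) {
      for (j in (l + 1):m) {
        bestv <- -Inf
        for (i in l:(j - 1)) {
          v <- f[i, l - 1] + term(i, j)
          if (v > bestv) bestv <- v
        }
        f[j, l] <- bestv
      }
    }
  }
  bestScore <- 0
  for (l in 2:maxA) {
    I <- Hrow + f[m, l]
    score <- I / log2(min(l, b))
    if (is.finite(score) && score > bestScore) bestScore <- score
  }
  bestScore
}

entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
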