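# Brute-force MIC oracle for tiny n: exhaustively enumerates every grid
# (a, b) with a * b <= B(n) = max(n^0.6, 4) and every placement of cut points
# between distinct values on both axes, computing normalised mutual
# information directly from the contingency table.

micBruteForce <- function(x, y, alpha = 0.6) {
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  B <- max(n^alpha, 4)
  axisParts <- function(v, k) {
    uv <- sort(unique(v))
    d <- length(uv)
    if (d < k) return(list())
    rank <- match(v, uv)
    cuts <- combn(d - 1, k - 1)
    lapply(seq_len(ncol(cuts)), function(j) {
      findInterval(rank, c(0, cuts[, j], d) + 0.5)
    })
  }
  best <- 0
  for (a in 2:floor(B / 2)) {
    bmax <- floor(B / a)
    if (bmax < 2) break
    for (b in 2:bmax) {
      for (px in axisParts(x, a)) for (py in axisParts(y, b)) {
        tab <- table(px, py) / n
        pxm <- rowSums(tab); pym <- colSums(tab)
        I <- 0
        for (i in seq_along(pxm)) for (j in seq_along(pym)) {
          if (tab[i, j] > 0)
            I <- I + tab[i, j] * log2(tab[i, j] / (pxm[i] * pym[j]))
        }
        best <- max(best, I / log2(min(a, b)))
      }
    }
  }
  best
}
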