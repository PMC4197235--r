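# Independent closed-form re-implementation of the moderated linear model:
# per-gene OLS condition means, residual variances, method-of-moments fit of a
# scaled F distribution to the s_g^2 (log-variance moments, digamma/trigamma
# inversion), posterior variances and moderated t per contrast. Deliberately
# written straight from the formulas, sharing no code with the package path.

trigammaInverseOracle <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-14) break
  }
  x
}

moderatedOracle <- function(values, cond) {
  cond <- droplevels(as.factor(cond))
  lev <- levels(cond)
  n <- ncol(values)
  k <- length(lev)
  dg <- n - k
  groupIdx <- lapply(lev, function(l) which(cond == l))
  means <- t(apply(values, 1, function(v) vapply(groupIdx, function(i) mean(v[i]), 0)))
  s2 <- apply(values, 1, function(v) {
    fit <- vapply(groupIdx, function(i) sum((v[i] - mean(v[i]))^2), 0)
    sum(fit) / dg
  })
  # method-of-moments fit of the scaled F to s2
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigammaInverseOracle(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # complete pooling: prior variance is the plain average sample variance
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2post <- if (is.finite(d0)) (d0 * s02 + dg * s2) / (d0 + dg) else rep(s02, length(s2))
  nPer <- vapply(groupIdx, length, 0L)
  tstats <- sapply(2:k, function(j) {
    logFC <- means[, j] - means[, 1]
    se <- sqrt(s2post * (1 / nPer[j] + 1 / nPer[1]))
    logFC / se
  })
  colnames(tstats) <- paste0(lev[-1], "-", lev[1])
  logFC <- means[, -1, drop = FALSE] - means[, 1]
  colnames(logFC) <- colnames(tstats)
  list(d0 = d0, s02 = s02, s2 = s2, s2post = s2post, t = tstats,
       logFC = logFC, df = dg + d0)
}
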