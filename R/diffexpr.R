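#' Filter features that never rise above an expression floor
#'
#' Retains exactly the features whose maximum log2 expression over all samples
#' exceeds \code{floor} (default 6), in their original order. Low, never-
#' expressed features carry no information for the downstream tests and
#' removing them increases detection power at a fixed FDR.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param floor log2 expression floor; a feature is dropped when it never
#'   exceeds this value.
#' @return The filtered \linkS4class{ExpressionStudy}.
#' @export
filterLowExpression <- function(study, floor = 6) {
  stopifnot(is.finite(floor))
  keep <- apply(exprValues(study), 1, max, na.rm = TRUE) > floor
  if (!any(keep)) warning("no features exceed the expression floor")
  study[keep, ]
}

#' Empirical-Bayes moderated linear model across time points
#'
#' Fits per-feature condition means by least squares, shrinks residual
#' variances toward a common prior via the standard empirical-Bayes
#' method-of-moments fit (prior df d0 and prior variance s0^2), and reports
#' moderated t statistics for every time-point-vs-control contrast plus the
#' omnibus moderated F across the non-control coefficients. BH-adjusted
#' p-values are attached per contrast and for the omnibus test.
#'
#' The numerical work is delegated to \pkg{limma} (\code{lmFit},
#' \code{contrasts.fit}, \code{eBayes}); the package's test suite checks the
#' resulting statistics against a direct evaluation of the closed-form
#' formulas.
#'
#' @param study an \linkS4class{ExpressionStudy} with >= 2 conditions and
#'   >= 2 residual degrees of freedom overall.
#' @return A \linkS4class{DEResult}.
#' @examples
#' sim <- simulateTimecourseStudy(simulationConfig(nGenes = 60,
#'   lowExprFraction = 0, seed = 1))
#' res <- fitModeratedModel(sim$study)
#' head(deTable(res))
#' @export
fitModeratedModel <- function(study) {
  cond <- sampleConditions(study)
  lev <- levels(droplevels(cond))
  if (length(lev) < 2) stop("need at least 2 conditions")
  n <- ncol(study)
  if (n - length(lev) < 2) stop("need at least 2 residual degrees of freedom")

  values <- exprValues(study)
  ok <- rowSums(is.finite(values)) >= length(lev) + 1
  if (!all(ok)) {
    warning(sum(!ok), " feature(s) without residual degrees of freedom excluded")
    values <- values[ok, , drop = FALSE]
  }
  design <- model.matrix(~ 0 + cond)
  colnames(design) <- lev
  fit <- limma::lmFit(values, design)
  cm <- diag(length(lev))[, -1, drop = FALSE]
  cm[1, ] <- -1
  rownames(cm) <- lev
  colnames(cm) <- paste0(lev[-1], "-", lev[1])
  fit <- limma::contrasts.fit(fit, cm)
  fit <- limma::eBayes(fit)

  syms <- geneSymbols(study)[rownames(values)]
  tab <- data.frame(feature = rownames(values), gene = unname(syms),
                    F = fit$F, p = fit$F.p.value,
                    fdr = p.adjust(fit$F.p.value, "BH"),
                    row.names = NULL)
  contrasts <- do.call(rbind, lapply(colnames(cm), function(cn) {
    data.frame(feature = rownames(values), gene = unname(syms), contrast = cn,
               logFC = fit$coefficients[, cn], t = fit$t[, cn],
               p = fit$p.value[, cn],
               fdr = p.adjust(fit$p.value[, cn], "BH"), row.names = NULL)
  }))
  new("DEResult", table = tab, contrasts = contrasts,
      priorDf = unname(fit$df.prior[1]), priorVar = unname(fit$s2.prior[1]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p raw p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1).
#' @examples
#' adjustFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Count significant features and unique annotated genes
#'
#' Bookkeeping mirrors the feature-vs-gene distinction of probe-based arrays:
#' features lacking a gene symbol are excluded from gene-level counts and a
#' gene counts once however many of its probes are significant. Both the
#' omnibus definition of "variable across the time points" and the union over
#' per-contrast tests are reported; the omnibus is the default elsewhere.
#'
#' @param deres a \linkS4class{DEResult}.
#' @param fdr FDR threshold.
#' @return list(features, genes, genesUnion, perContrast).
#' @export
countSignificant <- function(deres, fdr = 0.05) {
  tab <- deTable(deres)
  sig <- tab$fdr < fdr
  ct <- contrastTable(deres)
  sigC <- ct[ct$fdr < fdr & !is.na(ct$gene), ]
  list(features = sum(sig, na.rm = TRUE),
       genes = length(unique(tab$gene[sig & !is.na(tab$gene)])),
       genesUnion = length(unique(sigC$gene)),
       perContrast = vapply(split(sigC$gene, sigC$contrast),
                            function(g) length(unique(g)), integer(1)))
}

#' Collapse probes to genes for the network stages
#'
#' Per gene symbol, keeps the probe with the smallest omnibus raw p-value and
#' renames the row to the symbol; unannotated features are dropped. This is
#' the deterministic collapse rule applied before any gene-level network is
#' built.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param deres the \linkS4class{DEResult} fitted on \code{study} (or a
#'   superset of its features).
#' @return An \linkS4class{ExpressionStudy} with one row per gene symbol.
#' @export
collapseToGenes <- function(study, deres) {
  tab <- deTable(deres)
  tab <- tab[tab$feature %in% rownames(study) & !is.na(tab$gene), ]
  best <- tab[order(tab$gene, tab$p, tab$feature), ]
  best <- best[!duplicated(best$gene), ]
  out <- study[best$feature, ]
  values <- exprValues(out)
  rownames(values) <- best$gene
  ExpressionStudy(values, geneSymbols = best$gene,
                  conditions = as.character(sampleConditions(out)),
                  replicates = sampleReplicates(out),
                  conditionLevels = conditionLevels(out))
}

#' Top differentially expressed genes
#'
#' Convenience selector: gene-collapsed study restricted to genes whose best
#' probe passes \code{fdr} on the omnibus test, optionally capped at the
#' \code{maxGenes} smallest omnibus p-values.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param deres matching \linkS4class{DEResult}.
#' @param fdr omnibus FDR cutoff.
#' @param maxGenes optional cap on the number of genes returned.
#' @return An \linkS4class{ExpressionStudy} of top genes (one row per gene).
#' @export
topDEGenes <- function(study, deres, fdr = 1e-4, maxGenes = Inf) {
  collapsed <- collapseToGenes(study, deres)
  tab <- deTable(deres)
  tab <- tab[tab$feature %in% rownames(study) & !is.na(tab$gene), ]
  gfdr <- tapply(tab$fdr, tab$gene, min)
  gp <- tapply(tab$p, tab$gene, min)
  keep <- names(gfdr)[gfdr < fdr]
  keep <- keep[order(gp[keep])]
  if (length(keep) > maxGenes) keep <- keep[seq_len(maxGenes)]
  collapsed[rownames(collapsed) %in% keep, ]
}
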