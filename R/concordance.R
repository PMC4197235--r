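#' Condition-mean matrix of a study
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param conditions condition labels to keep (default: all levels).
#' @return genes/features x conditions matrix of per-condition means.
#' @export
conditionMeans <- function(study, conditions = conditionLevels(study)) {
  cond <- as.character(sampleConditions(study))
  vapply(conditions, function(cc) {
    rowMeans(exprValues(study)[, cond == cc, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(study)))
}

#' Per-gene expression-profile concordance between two studies
#'
#' For every gene shared between the studies (matched by row name,
#' case-insensitively; collapse probes to genes beforehand), condition means
#' are computed in each study over the matched condition labels and the
#' Pearson correlation of the two condition-mean vectors is recorded. All
#' correlations are returned for reporting; the \code{pass} flag marks genes
#' with r strictly above \code{rMin}. Genes with a constant profile in either
#' study are excluded and listed in attribute \code{excluded}.
#'
#' @param a,b gene-level \linkS4class{ExpressionStudy} objects.
#' @param conditions matched condition labels present in both studies
#'   (>= 3 for a reportable r).
#' @param rMin concordance threshold (strict).
#' @return data.frame(gene, r, n, pass).
#' @export
profileConcordance <- function(a, b,
                               conditions = intersect(conditionLevels(a),
                                                      conditionLevels(b)),
                               rMin = 0.8) {
  if (length(conditions) < 3) stop("need at least 3 matched conditions")
  if (!all(conditions %in% conditionLevels(a)) ||
      !all(conditions %in% conditionLevels(b)))
    stop("both studies must contain the matched conditions")
  sharedKey <- intersect(tolower(rownames(a)), tolower(rownames(b)))
  if (!length(sharedKey)) stop("no shared genes")
  ga <- rownames(a)[match(sharedKey, tolower(rownames(a)))]
  gb <- rownames(b)[match(sharedKey, tolower(rownames(b)))]
  ma <- conditionMeans(a, conditions)[ga, , drop = FALSE]
  mb <- conditionMeans(b, conditions)[gb, , drop = FALSE]
  constant <- apply(ma, 1, sd) == 0 | apply(mb, 1, sd) == 0
  r <- rep(NA_real_, length(sharedKey))
  ok <- !constant
  r[ok] <- vapply(which(ok), function(i) cor(ma[i, ], mb[i, ]), numeric(1))
  out <- data.frame(gene = ga, r = r, n = length(conditions),
                    pass = !is.na(r) & r > rMin)[ok, ]
  rownames(out) <- NULL
  attr(out, "excluded") <- ga[constant]
  out
}

#' Fold-change table from an expression study
#'
#' Per gene and non-control condition: log2FC = mean(condition) -
#' mean(control) with the standard error of the difference of means from
#' replicate variability.
#'
#' @param study gene-level \linkS4class{ExpressionStudy}.
#' @param source label recorded in the \code{source} column.
#' @return data.frame(gene, condition, log2FC, se, n, source) — the
#'   fold-change currency shared by the concordance and qPCR stages.
#' @export
foldChangeTable <- function(study, source = "microarray") {
  cond <- as.character(sampleConditions(study))
  ctrl <- conditionLevels(study)[1]
  values <- exprValues(study)
  ctrlIdx <- cond == ctrl
  rows <- lapply(setdiff(conditionLevels(study), ctrl), function(cc) {
    idx <- cond == cc
    m1 <- rowMeans(values[, idx, drop = FALSE])
    m0 <- rowMeans(values[, ctrlIdx, drop = FALSE])
    v1 <- apply(values[, idx, drop = FALSE], 1, var) / sum(idx)
    v0 <- apply(values[, ctrlIdx, drop = FALSE], 1, var) / sum(ctrlIdx)
    data.frame(gene = rownames(values), condition = cc, log2FC = m1 - m0,
               se = sqrt(v1 + v0), n = sum(idx), source = source,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Global log2 fold-change concordance between two sources
#'
#' Pearson correlation over paired per-gene log2 fold changes at one
#' condition, with r^2 and the two-sided correlation-test p-value.
#'
#' @param x,y fold-change tables (see \code{\link{foldChangeTable}}); matched
#'   by gene symbol, case-insensitively.
#' @param condition condition/day label present in both tables.
#' @return list(r, r2, p, n, data) where \code{data} holds the paired values.
#' @examples
#' x <- data.frame(gene = letters[1:5], condition = "1d",
#'                 log2FC = c(1, 2, 0.5, -1, 0))
#' y <- transform(x, log2FC = log2FC + 0.1)
#' foldChangeConcordance(x, y, "1d")$r
#' @export
foldChangeConcordance <- function(x, y, condition) {
  xs <- x[x$condition == condition, ]
  ys <- y[y$condition == condition, ]
  key <- intersect(tolower(xs$gene), tolower(ys$gene))
  if (length(key) < 3) stop("need at least 3 shared genes at ", condition)
  xi <- xs[match(key, tolower(xs$gene)), ]
  yi <- ys[match(key, tolower(ys$gene)), ]
  ct <- cor.test(xi$log2FC, yi$log2FC)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(key),
       data = data.frame(gene = xi$gene, log2FC_x = xi$log2FC,
                         log2FC_y = yi$log2FC, row.names = NULL))
}
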