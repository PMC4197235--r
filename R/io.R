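#' Write / read an ExpressionStudy as tab-delimited text
#'
#' Three files under \code{prefix}: \code{<prefix>_matrix.tsv} (feature rows,
#' sample columns), \code{<prefix>_features.tsv} (feature, gene_symbol) and
#' \code{<prefix>_samples.tsv} (sample, condition, replicate).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param prefix path prefix.
#' @return \code{writeStudy}: the prefix, invisibly. \code{readStudy}: the
#'   \linkS4class{ExpressionStudy}.
#' @export
writeStudy <- function(study, prefix) {
  m <- exprValues(study)
  write.table(data.frame(feature = rownames(m), m, check.names = FALSE),
              paste0(prefix, "_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(feature = rownames(m),
                         gene_symbol = unname(geneSymbols(study))),
              paste0(prefix, "_features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = colnames(m),
                         condition = as.character(sampleConditions(study)),
                         replicate = unname(sampleReplicates(study))),
              paste0(prefix, "_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeStudy
#' @param conditionLevels ordered condition labels; defaults to order of
#'   appearance in the sample sheet.
#' @export
readStudy <- function(prefix, conditionLevels = NULL) {
  m <- read.delim(paste0(prefix, "_matrix.tsv"), check.names = FALSE)
  feats <- read.delim(paste0(prefix, "_features.tsv"))
  samples <- read.delim(paste0(prefix, "_samples.tsv"))
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m$feature
  ExpressionStudy(values,
                  geneSymbols = feats$gene_symbol[match(m$feature, feats$feature)],
                  conditions = samples$condition[match(colnames(values), samples$sample)],
                  replicates = samples$replicate[match(colnames(values), samples$sample)],
                  conditionLevels = conditionLevels)
}

#' Write a Cq table as TSV
#' @param table Cq table.
#' @param path output file.
#' @export
writeCqTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCqTable
#' @export
readCqTable <- function(path) read.delim(path)

#' Write planted ground truth as a plain key-value text file
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
  lines <- c(
    paste0("de_genes\t", paste(trueDEGenes(truth), collapse = ",")),
    paste0("module_membership\t",
           paste(names(trueModules(truth)), trueModules(truth),
                 sep = ":", collapse = ",")),
    paste0("hub_edges\t",
           paste(apply(trueHubEdges(truth), 1, function(r)
             paste(r[["source"]], r[["target"]], r[["sign"]], sep = ":")),
             collapse = ",")),
    paste0("concordant_genes\t",
           paste(trueConcordantGenes(truth), collapse = ",")),
    paste0("low_expr_features\t",
           paste(trueLowExprFeatures(truth), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

writeTSV <- function(df, path) {
  listCols <- vapply(df, is.list, logical(1))
  for (cn in names(df)[listCols])
    df[[cn]] <- vapply(df[[cn]], paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
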