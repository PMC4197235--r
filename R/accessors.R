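#' @describeIn ExpressionStudy log2 expression matrix (features x samples).
#' @param x an ExpressionStudy.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' @describeIn ExpressionStudy feature -> gene-symbol map (NA = unannotated).
#' @export
geneSymbols <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$gene_symbol, rownames(x))
}

#' @describeIn ExpressionStudy per-sample condition factor, control level first.
#' @export
sampleConditions <- function(x) {
  factor(SummarizedExperiment::colData(x)$condition, levels = x@conditionLevels)
}

#' @describeIn ExpressionStudy per-sample replicate ids.
#' @export
sampleReplicates <- function(x) {
  setNames(SummarizedExperiment::colData(x)$replicate, colnames(x))
}

#' @describeIn ExpressionStudy ordered condition labels (control first).
#' @export
conditionLevels <- function(x) x@conditionLevels

#' @describeIn GeneNetwork node ids of a network.
#' @param x a GeneNetwork.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn GeneNetwork edge table (from, to, r, mic).
#' @export
networkEdges <- function(x) x@edges

#' @describeIn DEResult per-feature omnibus table (feature, gene, F, p, fdr).
#' @param x a DEResult.
#' @export
deTable <- function(x) x@table

#' @describeIn DEResult long per-contrast table.
#' @export
contrastTable <- function(x) x@contrasts

#' @describeIn DEResult prior degrees of freedom d0.
#' @export
priorDf <- function(x) x@priorDf

#' @describeIn DEResult prior variance s0^2.
#' @export
priorVar <- function(x) x@priorVar

#' @describeIn ModuleAssignment named gene -> module label vector (0 = none).
#' @param x a ModuleAssignment.
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModuleAssignment samples x modules eigengene matrix.
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @describeIn ModuleAssignment module membership table (gene, module, MM, p).
#' @export
moduleMembershipTable <- function(x) x@membership

#' @describeIn GroundTruth planted differentially expressed genes.
#' @param x a GroundTruth.
#' @export
trueDEGenes <- function(x) x@deGenes

#' @describeIn GroundTruth planted gene -> module map.
#' @export
trueModules <- function(x) x@moduleMembership

#' @describeIn GroundTruth planted signed hub dependencies.
#' @export
trueHubEdges <- function(x) x@hubEdges

#' @describeIn GroundTruth genes planted as concordant across a study pair.
#' @export
trueConcordantGenes <- function(x) x@concordantGenes

#' @describeIn GroundTruth features planted below the expression floor.
#' @export
trueLowExprFeatures <- function(x) x@lowExprFeatures
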