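#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cor.test cov sd var quantile rnorm runif setNames
#'   p.adjust pt wilcox.test complete.cases hclust as.dist cutree lm coef
#'   model.matrix aggregate
#' @importFrom utils combn head read.delim write.table packageVersion
NULL

#' ExpressionStudy: a log2 expression time course
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a log2
#' expression matrix (features x samples) together with the metadata every
#' downstream stage consumes: a feature-to-gene-symbol map in \code{rowData}
#' and condition/replicate labels in \code{colData}. The first condition level
#' is the control/sham arm against which all contrasts are formed.
#'
#' @slot conditionLevels character, ordered condition labels (control first).
#' @export
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  representation(conditionLevels = "character")
)

setValidity("ExpressionStudy", function(object) {
  msg <- NULL
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if ("condition" %in% colnames(cd) && anyNA(cd$condition))
    msg <- c(msg, "every sample needs a condition")
  if ("condition" %in% colnames(cd) &&
      !all(as.character(cd$condition) %in% object@conditionLevels))
    msg <- c(msg, "sample conditions outside conditionLevels")
  if (!"gene_symbol" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'gene_symbol'")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionStudy
#'
#' @param values numeric matrix of log2 expression, features x samples.
#' @param geneSymbols character vector, one symbol per feature (NA allowed for
#'   unannotated features).
#' @param conditions character/factor of per-sample condition labels.
#' @param replicates per-sample replicate ids; defaults to a within-condition
#'   counter.
#' @param conditionLevels ordered condition labels, control first; defaults to
#'   the order of first appearance.
#' @return An \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(20, 8), 4, 5,
#'   dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' ExpressionStudy(m, paste0("g", 1:4), c("control", "1d", "1d", "3d", "3d"))
#' @export
ExpressionStudy <- function(values, geneSymbols, conditions, replicates = NULL,
                            conditionLevels = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  conditions <- as.character(conditions)
  if (is.null(conditionLevels)) conditionLevels <- unique(conditions)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    rowData = S4Vectors::DataFrame(gene_symbol = as.character(geneSymbols),
                                   row.names = rownames(values)),
    colData = S4Vectors::DataFrame(condition = conditions,
                                   replicate = as.integer(replicates),
                                   row.names = colnames(values))
  )
  new("ExpressionStudy", se, conditionLevels = conditionLevels)
}

#' GeneNetwork: an undirected co-expression network
#'
#' Nodes are gene symbols; each edge carries the Pearson correlation \code{r}
#' and the maximal information coefficient \code{mic} that justified it.
#' Edges are stored once in canonical (from < to) order.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns from, to, r, mic.
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  msg <- NULL
  if (!all(c("from", "to", "r", "mic") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, r, mic")
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be in canonical order")
    if (anyDuplicated(paste(e$from, e$to))) msg <- c(msg, "duplicated edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(abs(e$r) > 1 + 1e-12, na.rm = TRUE)) msg <- c(msg, "|r| must be <= 1")
    if (any(e$mic < -1e-12 | e$mic > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "mic must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneNetwork
#' @param nodes character node ids.
#' @param edges data.frame(from, to, r, mic); orientation is normalised.
#' @export
GeneNetwork <- function(nodes, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), mic = numeric())
  } else {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("GeneNetwork", nodes = sort(unique(nodes)), edges = edges)
}

#' DEResult: moderated differential-expression statistics
#'
#' @slot table per-feature omnibus results: feature, gene, F, p, fdr.
#' @slot contrasts long table of per-contrast statistics: feature, gene,
#'   contrast, logFC, t, p, fdr.
#' @slot priorDf prior degrees of freedom d0 of the variance shrinkage.
#' @slot priorVar prior variance s0^2.
#' @export
setClass("DEResult",
  representation(table = "data.frame", contrasts = "data.frame",
                 priorDf = "numeric", priorVar = "numeric"))

setValidity("DEResult", function(object) {
  msg <- NULL
  if (with(object@table, any(fdr + 1e-12 < p, na.rm = TRUE)))
    msg <- c(msg, "adjusted p must be >= raw p")
  if (with(object@table, any(fdr < 0 | fdr > 1, na.rm = TRUE)))
    msg <- c(msg, "adjusted p must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' ModuleAssignment: weighted-network module labels and eigengenes
#'
#' @slot labels named integer vector, gene -> module label (0 = unassigned).
#' @slot eigengenes samples x modules matrix of unit-norm module eigengenes,
#'   columns named ME<label>.
#' @slot membership data.frame(gene, module, MM, p) of signed module
#'   membership values.
#' @slot corMethod correlation type used throughout ("spearman" or "pearson").
#' @export
setClass("ModuleAssignment",
  representation(labels = "integer", eigengenes = "matrix",
                 membership = "data.frame", corMethod = "character"))

setValidity("ModuleAssignment", function(object) {
  msg <- NULL
  if (nrow(object@membership) &&
      any(abs(object@membership$MM) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "|MM| must be <= 1")
  if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: study-design parameters for the synthetic generator
#'
#' Defaults emulate a heart-injury microarray time course: five conditions
#' (control plus 1/3/5/7 days post-injury) with three replicates, probe
#' multiplicity, roughly half of all features never rising above the log2 = 6
#' expression floor, two planted co-expression modules, and a signed hub
#' centred on \emph{ptgis} with one positive (\emph{ca2}) and three negative
#' (\emph{usp2a}, \emph{sgce}, \emph{acta1a}) linear dependents.
#'
#' @slot nGenes number of simulated genes.
#' @slot probesPerGene integer vector recycled over genes: probes per gene.
#' @slot conditions ordered condition labels, control first.
#' @slot nReplicates per-condition replicate counts (recycled).
#' @slot baselineMean,baselineSd log2 units of per-gene baseline expression.
#' @slot deFraction proportion of eligible genes given condition effects.
#' @slot effectSizeSd log2 sd of planted per-condition effects.
#' @slot moduleSpec list of planted modules, each list(size, rho, profile,
#'   scale); \code{rho} is the target within-module correlation, profile the
#'   shared latent time course (one value per condition).
#' @slot hubSpec list(hub, profile, scale, deps) where deps is a
#'   data.frame(gene, sign, slope, sd) of signed linear dependents.
#' @slot noiseSd per-feature, per-sample measurement noise (log2 units).
#' @slot bioNoiseSd biological replicate variability added to genes outside
#'   the planted modules and hub block, which carry their own latent
#'   variability (log2 units).
#' @slot lowExprFraction proportion of genes whose features stay below the
#'   log2 = 6 floor in every sample.
#' @slot probeNoiseSd probe-specific noise (log2 units).
#' @slot seed integer seed fixing every draw.
#' @export
setClass("SimulationConfig",
  representation(nGenes = "numeric", probesPerGene = "numeric",
                 conditions = "character", nReplicates = "numeric",
                 baselineMean = "numeric", baselineSd = "numeric",
                 deFraction = "numeric", effectSizeSd = "numeric",
                 moduleSpec = "list", hubSpec = "list",
                 noiseSd = "numeric", bioNoiseSd = "numeric",
                 lowExprFraction = "numeric",
                 probeNoiseSd = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  chk <- function(cond, field) if (!cond) msg <<- c(msg, paste0("invalid '", field, "'"))
  chk(length(object@nGenes) == 1 && object@nGenes >= 1, "nGenes")
  chk(all(object@probesPerGene >= 1), "probesPerGene")
  chk(length(object@conditions) >= 2 && !anyDuplicated(object@conditions), "conditions")
  chk(all(object@nReplicates >= 1), "nReplicates")
  chk(object@baselineSd > 0, "baselineSd")
  chk(object@deFraction >= 0 && object@deFraction <= 1, "deFraction")
  chk(object@effectSizeSd >= 0, "effectSizeSd")
  chk(object@noiseSd >= 0, "noiseSd")
  chk(object@bioNoiseSd >= 0, "bioNoiseSd")
  chk(object@probeNoiseSd >= 0, "probeNoiseSd")
  chk(object@lowExprFraction >= 0 && object@lowExprFraction < 1, "lowExprFraction")
  chk(length(object@seed) == 1 && is.finite(object@seed), "seed")
  nStructural <- 0
  if (length(object@hubSpec) && is.data.frame(object@hubSpec$deps))
    nStructural <- nStructural + 1 + nrow(object@hubSpec$deps)
  if (length(object@moduleSpec)) {
    sizes <- vapply(object@moduleSpec, function(m) m$size, numeric(1))
    rhos <- vapply(object@moduleSpec, function(m) m$rho, numeric(1))
    nStructural <- nStructural + sum(sizes)
    chk(sum(sizes) <= object@nGenes, "moduleSpec (sizes exceed nGenes)")
    chk(all(rhos >= 0 & rhos < 1), "moduleSpec (rho must lie in [0,1))")
    for (m in object@moduleSpec)
      chk(length(m$profile) == length(object@conditions), "moduleSpec (profile length)")
  }
  if (length(object@hubSpec)) {
    chk(is.character(object@hubSpec$hub), "hubSpec (hub name)")
    chk(length(object@hubSpec$profile) == length(object@conditions), "hubSpec (profile length)")
    d <- object@hubSpec$deps
    chk(is.data.frame(d) && all(c("gene", "sign", "slope", "sd") %in% colnames(d)),
        "hubSpec (deps columns)")
    if (is.data.frame(d)) {
      chk(all(d$sign %in% c(-1, 1)), "hubSpec (dep signs)")
      chk(all(d$sd > 0), "hubSpec (dep sd)")
    }
  }
  chk(nStructural <= (1 - object@lowExprFraction) * object@nGenes,
      "nGenes (module/hub genes exceed the non-low-expressed pool)")
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: planted structure of a simulated study
#'
#' @slot deGenes genes with condition-dependent means.
#' @slot moduleMembership named integer, gene -> planted module.
#' @slot hubEdges data.frame(source, target, sign, slope).
#' @slot concordantGenes genes sharing their profile across a study pair.
#' @slot lowExprFeatures feature ids that never exceed the expression floor.
#' @export
setClass("GroundTruth",
  representation(deGenes = "character", moduleMembership = "integer",
                 hubEdges = "data.frame", concordantGenes = "character",
                 lowExprFeatures = "character"))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  conditions:", paste(object@conditionLevels, collapse = ", "), "\n")
  syms <- SummarizedExperiment::rowData(object)$gene_symbol
  cat("  genes:", length(unique(syms[!is.na(syms)])), "annotated symbols\n")
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", length(object@nodes), "nodes,", nrow(object@edges), "edges\n")
})

setMethod("show", "DEResult", function(object) {
  cat("DEResult:", nrow(object@table), "features,",
      length(unique(object@contrasts$contrast)), "contrasts\n")
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.4g\n",
              object@priorDf, object@priorVar))
  cat("  features at FDR < 0.05:", sum(object@table$fdr < 0.05, na.rm = TRUE), "\n")
})

setMethod("show", "ModuleAssignment", function(object) {
  k <- sum(unique(object@labels) != 0)
  cat("ModuleAssignment:", length(object@labels), "genes,", k, "modules",
      sprintf("(%d unassigned)\n", sum(object@labels == 0)))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@deGenes), "DE genes,",
      length(unique(object@moduleMembership)), "planted modules,",
      nrow(object@hubEdges), "hub edges\n")
})
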