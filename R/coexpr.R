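#' Between-gene correlation matrix
#'
#' Pearson (default) or Spearman correlations between gene rows, using
#' pairwise-complete observations. Constant genes yield undefined
#' coefficients, recorded as NA and excluded from any edge downstream.
#'
#' @param study an \linkS4class{ExpressionStudy} or a genes x samples matrix.
#' @param method "pearson" or "spearman".
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(study, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  r <- suppressWarnings(cor(t(values), method = method,
                            use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Build a co-expression network gated by |r| and MIC
#'
#' Candidate edges are all gene pairs with a finite Pearson correlation; an
#' edge is kept iff |r| >= rMin and, as an independent confirmation of the
#' relationship, MIC > micMin. Isolated nodes are dropped from the reported
#' network. The number of finite-correlation candidate pairs is attached as
#' attribute \code{nCandidateEdges}.
#'
#' @param study gene-level \linkS4class{ExpressionStudy} (one row per gene;
#'   see \code{\link{collapseToGenes}}) or genes x samples matrix.
#' @param genes optional subset of genes to use.
#' @param rMin minimum |Pearson r| for an edge (kept at equality).
#' @param micMin MIC threshold (strict: edge needs MIC > micMin).
#' @return A \linkS4class{GeneNetwork}.
#' @examples
#' m <- rbind(a = 1:10, b = 2 * (1:10) + 1, c = -(1:10))
#' buildCoexpressionNetwork(m + 0, rMin = 0.9, micMin = 0.9)
#' @export
buildCoexpressionNetwork <- function(study, genes = NULL, rMin = 0.95,
                                     micMin = 0.95) {
  values <- if (is(study, "ExpressionStudy")) exprValues(study) else as.matrix(study)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(values))
    if (length(missing))
      stop("genes absent from study: ", paste(head(missing, 5), collapse = ", "))
    values <- values[genes, , drop = FALSE]
  }
  r <- correlationMatrix(values, "pearson")
  g <- rownames(values)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  finite <- is.finite(r[ut])
  nCandidate <- sum(finite)
  pass <- finite & abs(r[ut]) >= rMin
  keepFrom <- character(); keepTo <- character()
  keepR <- numeric(); keepMic <- numeric()
  for (k in which(pass)) {
    i <- ut[k, 1]; j <- ut[k, 2]
    mic <- micScore(values[i, ], values[j, ])
    if (mic > micMin) {
      keepFrom <- c(keepFrom, g[i]); keepTo <- c(keepTo, g[j])
      keepR <- c(keepR, r[i, j]); keepMic <- c(keepMic, mic)
    }
  }
  nodes <- sort(unique(c(keepFrom, keepTo)))
  net <- GeneNetwork(nodes, data.frame(from = keepFrom, to = keepTo,
                                       r = keepR, mic = keepMic))
  attr(net, "nCandidateEdges") <- nCandidate
  net
}

#' Export a network as SIF
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param path output file.
#' @param relation interaction label.
#' @export
writeSIF <- function(network, path, relation = "co") {
  e <- networkEdges(network)
  lines <- if (nrow(e)) paste(e$from, relation, e$to, sep = "\t") else character()
  isolated <- setdiff(networkNodes(network), c(e$from, e$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network as GraphML with r/MIC edge attributes
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param path output file.
#' @param nodeAttrs optional data.frame keyed by column \code{gene} with extra
#'   node attributes (e.g. per-condition mean log2FC, module membership).
#' @export
writeGraphML <- function(network, path, nodeAttrs = NULL) {
  g <- asIgraph(network)
  if (!is.null(nodeAttrs)) {
    idx <- match(igraph::V(g)$name, nodeAttrs$gene)
    for (cn in setdiff(colnames(nodeAttrs), "gene"))
      g <- igraph::set_vertex_attr(g, cn, value = nodeAttrs[[cn]][idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

asIgraph <- function(network) {
  e <- networkEdges(network)
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = networkNodes(network)))
}
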