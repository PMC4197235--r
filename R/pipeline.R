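#' Default pipeline configuration
#'
#' Returns the full configuration list for \code{\link{runPipeline}} with the
#' study's canonical thresholds: expression floor 6, omnibus FDR 0.05 for the
#' weighted-network gene set and 1e-4 for the top-gene network, |r| >= 0.95
#' and MIC > 0.95 edge gates, cohesive-module minimum size 5 / penalty 2 /
#' overlap 0.8, model-tree theta 0.30 and BY alpha 0.05, soft power 10,
#' minimum weighted-module size 20, eigengene merge height 0.15 and
#' cross-dataset concordance threshold 0.8. Any element can be overridden via
#' \code{...}; \code{sim} holds the \linkS4class{SimulationConfig} used when
#' no study files are supplied.
#'
#' @param ... overrides, e.g. \code{runPipelineConfig(theta = 0.2)}.
#' @return Named list of parameters.
#' @export
runPipelineConfig <- function(...) {
  cfg <- list(
    sim = simulationConfig(),
    concordantFraction = 0.1,
    profileNoiseSd = 0.1,
    floor = 6,
    fdr = 0.05,
    topFdr = 1e-4,
    maxNetworkGenes = 100,
    rMin = 0.95, micMin = 0.95,
    cohesiveMinSize = 5, cohesiveDensity = "auto",
    cohesivePenalty = 2, cohesiveOverlap = 0.8,
    theta = 0.30, alpha = 0.05,
    beta = 10, weightedCor = "spearman",
    minModuleSize = 20, mergeHeight = 0.15,
    mmThreshold = 0.8,
    concordanceRMin = 0.8,
    qpcrEfficiency = 1.95, qpcrNoiseSd = 0.2,
    referenceGenes = c("ef1a", "rpl13a", "tuba1"),
    includeGenes = character(), excludeGenes = character(),
    stages = list(coexpr = TRUE, cohesive = TRUE, treenet = TRUE,
                  weighted = TRUE, concordance = TRUE, qpcr = TRUE)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(cfg), names(cfg$stages)))
    if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (nm %in% names(cfg$stages)) cfg$stages[[nm]] <- dots[[nm]]
      else cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Select candidate genes across analysis stages
#'
#' A gene is flagged per technique when it (a) belongs to a significant
#' cohesive module, (b) is a node of the directed model-tree network, (c) has
#' |module membership| above \code{mmThreshold} in a weighted module, or (d)
#' is cross-dataset concordant. Candidates are the union of flagged genes,
#' minus the configured exclusions, plus manual inclusions (flagged
#' \code{manual}); manual curation stands in for criteria that are human
#' judgments (prior functional characterisation, primer feasibility) and is
#' never inferred from the data. Ranking is by omnibus FDR, then by the
#' number of supporting techniques.
#'
#' @param deres \linkS4class{DEResult} for gene-level FDR lookup.
#' @param cohesiveModules output of \code{\link{detectCohesiveModules}} (or
#'   NULL).
#' @param directedNetwork output of \code{\link{inferDirectedNetwork}} (or
#'   NULL).
#' @param weightedAssignment \linkS4class{ModuleAssignment} (or NULL).
#' @param concordance output of \code{\link{profileConcordance}} (or NULL).
#' @param include,exclude manual gene lists.
#' @param mmThreshold |MM| cutoff for the weighted-module flag.
#' @param moduleP significance cutoff for cohesive modules.
#' @return data.frame(gene, cohesive, directed, weighted, concordant, manual,
#'   nFlags, fdr) sorted by rank.
#' @export
selectCandidates <- function(deres, cohesiveModules = NULL,
                             directedNetwork = NULL,
                             weightedAssignment = NULL, concordance = NULL,
                             include = character(), exclude = character(),
                             mmThreshold = 0.8, moduleP = 0.05) {
  flagged <- list(
    cohesive = if (!is.null(cohesiveModules) && nrow(cohesiveModules)) {
      sig <- cohesiveModules[!is.na(cohesiveModules$p) &
                             cohesiveModules$p < moduleP, ]
      unique(unlist(sig$members))
    } else character(),
    directed = if (!is.null(directedNetwork) && nrow(directedNetwork)) {
      unique(c(directedNetwork$source, directedNetwork$target))
    } else character(),
    weighted = if (!is.null(weightedAssignment)) {
      mt <- moduleMembershipTable(weightedAssignment)
      mt$gene[abs(mt$MM) >= mmThreshold]
    } else character(),
    concordant = if (!is.null(concordance) && nrow(concordance)) {
      concordance$gene[concordance$pass]
    } else character())

  genes <- sort(unique(c(unlist(flagged), include)))
  genes <- setdiff(genes, exclude)
  if (!length(genes)) {
    warning("no candidate genes flagged")
    return(data.frame(gene = character(), cohesive = logical(),
                      directed = logical(), weighted = logical(),
                      concordant = logical(), manual = logical(),
                      nFlags = integer(), fdr = numeric()))
  }
  tab <- deTable(deres)
  gfdr <- tapply(tab$fdr, tab$gene, min)
  out <- data.frame(
    gene = genes,
    cohesive = genes %in% flagged$cohesive,
    directed = genes %in% flagged$directed,
    weighted = genes %in% flagged$weighted,
    concordant = genes %in% flagged$concordant,
    manual = genes %in% include, row.names = NULL)
  out$nFlags <- rowSums(out[, c("cohesive", "directed", "weighted", "concordant")])
  out$fdr <- unname(gfdr[out$gene])
  out <- out[order(out$fdr, -out$nFlags, out$gene, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Run the full discovery pipeline
#'
#' Executes the workflow end to end on simulated data: simulate a derivation
#' study and a companion study -> expression-floor filtering -> moderated
#' differential expression -> top-gene co-expression network (|r| and MIC
#' gates) -> cohesive overlapping modules -> directed model-tree network ->
#' weighted TOM modules -> cross-dataset profile concordance -> candidate
#' selection -> qPCR simulation and fold-change validation of the candidate
#' genes. Every intermediate table is written under \code{outDir} together
#' with a parameter log; all outputs are pure functions of the configuration
#' (no timestamps), so repeated runs are byte-identical.
#'
#' @param config list from \code{\link{runPipelineConfig}}, or the path of a
#'   YAML file with overrides for its scalar options.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with every stage result (study, truth, deres,
#'   network, cohesive, directed, weighted, concordance, qpcr, candidates).
#' @export
runPipeline <- function(config = runPipelineConfig(), outDir) {
  if (is.character(config)) config <- do.call(runPipelineConfig,
                                              yaml::read_yaml(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c("cardioNet pipeline run",
                paste0("package_version\t", as.character(utils::packageVersion("cardioNet"))))
  logParam <- function(k, v) logLines <<- c(logLines, paste0(k, "\t", paste(v, collapse = ",")))
  for (k in setdiff(names(config), c("sim", "stages")))
    logParam(k, unlist(config[[k]]))
  logParam("sim_seed", config$sim@seed)
  logParam("sim_nGenes", config$sim@nGenes)

  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  res <- list()

  # --- data ---
  pair <- tryCatch(simulateConcordantPair(config$sim,
                                          concordantFraction = config$concordantFraction,
                                          profileNoiseSd = config$profileNoiseSd),
                   error = function(e) fail("simulate", e))
  res$study <- pair$studyA
  res$companion <- pair$studyB
  res$truth <- pair$truth
  writeStudy(res$study, file.path(outDir, "derivation"))
  writeStudy(res$companion, file.path(outDir, "companion"))
  writeGroundTruth(res$truth, file.path(outDir, "ground_truth.txt"))

  # --- differential expression ---
  res$filtered <- tryCatch(filterLowExpression(res$study, config$floor),
                           error = function(e) fail("filter", e))
  res$deres <- tryCatch(fitModeratedModel(res$filtered),
                        error = function(e) fail("diffexpr", e))
  writeTSV(deTable(res$deres), file.path(outDir, "de_omnibus.tsv"))
  writeTSV(contrastTable(res$deres), file.path(outDir, "de_contrasts.tsv"))
  counts <- countSignificant(res$deres, config$fdr)
  logParam("features_after_filter", nrow(res$filtered))
  logParam("de_genes_omnibus", counts$genes)
  logParam("de_genes_union", counts$genesUnion)

  collapsed <- collapseToGenes(res$filtered, res$deres)
  topStudy <- topDEGenes(res$filtered, res$deres, fdr = config$topFdr,
                         maxGenes = config$maxNetworkGenes)
  logParam("top_network_genes", nrow(topStudy))

  # --- networks ---
  if (isTRUE(config$stages$coexpr)) {
    res$network <- tryCatch(
      buildCoexpressionNetwork(topStudy, rMin = config$rMin,
                               micMin = config$micMin),
      error = function(e) fail("coexpr", e))
    writeSIF(res$network, file.path(outDir, "coexpression.sif"))
    fcAttrs <- conditionMeansAsAttrs(topStudy)
    writeGraphML(res$network, file.path(outDir, "coexpression.graphml"), fcAttrs)
    logParam("network_nodes", length(networkNodes(res$network)))
    logParam("network_edges", nrow(networkEdges(res$network)))
  }
  if (isTRUE(config$stages$cohesive) && !is.null(res$network) &&
      length(networkNodes(res$network))) {
    res$cohesive <- tryCatch(
      detectCohesiveModules(res$network, minSize = config$cohesiveMinSize,
                            density = config$cohesiveDensity,
                            penalty = config$cohesivePenalty,
                            overlap = config$cohesiveOverlap),
      error = function(e) fail("cohesive", e))
    writeTSV(res$cohesive, file.path(outDir, "cohesive_modules.tsv"))
  }
  if (isTRUE(config$stages$treenet)) {
    res$directed <- tryCatch(
      inferDirectedNetwork(topStudy, theta = config$theta,
                           alpha = config$alpha),
      error = function(e) fail("treenet", e))
    writeTSV(res$directed, file.path(outDir, "directed_network.tsv"))
  }
  if (isTRUE(config$stages$weighted)) {
    wideStudy <- topDEGenes(res$filtered, res$deres, fdr = config$fdr)
    res$weighted <- tryCatch(
      detectWeightedModules(wideStudy, beta = config$beta,
                            method = config$weightedCor,
                            minModuleSize = config$minModuleSize,
                            mergeHeight = config$mergeHeight),
      error = function(e) fail("weighted", e))
    writeTSV(moduleMembershipTable(res$weighted),
             file.path(outDir, "weighted_modules.tsv"))
  }

  # --- cross-dataset concordance ---
  if (isTRUE(config$stages$concordance)) {
    deresB <- tryCatch(fitModeratedModel(filterLowExpression(res$companion,
                                                             config$floor)),
                       error = function(e) fail("concordance", e))
    collapsedB <- collapseToGenes(res$companion, deresB)
    res$concordance <- tryCatch(
      profileConcordance(collapsed, collapsedB,
                         rMin = config$concordanceRMin),
      error = function(e) fail("concordance", e))
    writeTSV(res$concordance, file.path(outDir, "concordance.tsv"))
    logParam("concordant_genes", sum(res$concordance$pass))
  }

  # --- candidate selection ---
  res$candidates <- selectCandidates(res$deres, res$cohesive, res$directed,
                                     res$weighted, res$concordance,
                                     include = config$includeGenes,
                                     exclude = config$excludeGenes,
                                     mmThreshold = config$mmThreshold)
  writeTSV(res$candidates, file.path(outDir, "candidates.tsv"))
  logParam("candidate_genes", nrow(res$candidates))

  # --- qPCR validation ---
  if (isTRUE(config$stages$qpcr) && nrow(res$candidates)) {
    fcArray <- foldChangeTable(collapsed)
    day <- conditionLevels(res$study)[2]
    targets <- head(res$candidates$gene, 15)
    planted <- fcArray$log2FC[fcArray$condition == day]
    names(planted) <- fcArray$gene[fcArray$condition == day]
    planted <- planted[targets]
    eff <- setNames(rep(config$qpcrEfficiency,
                        length(targets) + length(config$referenceGenes)),
                    c(targets, config$referenceGenes))
    cq <- tryCatch(
      simulateCqTable(planted, eff, cqNoiseSd = config$qpcrNoiseSd,
                      referenceGenes = config$referenceGenes,
                      days = day, seed = config$sim@seed + 2),
      error = function(e) fail("qpcr", e))
    writeCqTable(cq, file.path(outDir, "qpcr_cq.tsv"))
    res$qpcr <- tryCatch(qpcrFoldChanges(cq, config$referenceGenes),
                         error = function(e) fail("qpcr", e))
    writeTSV(res$qpcr, file.path(outDir, "qpcr_foldchanges.tsv"))
    arrDay <- fcArray[fcArray$condition == day, ]
    qc <- foldChangeConcordance(arrDay,
                                transform(res$qpcr, condition = day), day)
    logParam("qpcr_concordance_r", signif(qc$r, 4))
    res$qpcrConcordance <- qc
    writeTSV(qc$data, file.path(outDir, "qpcr_scatter.tsv"))
  }

  writeLines(logLines, file.path(outDir, "run_log.txt"))
  invisible(res)
}

conditionMeansAsAttrs <- function(study) {
  cm <- conditionMeans(study)
  fc <- cm[, -1, drop = FALSE] - cm[, 1]
  colnames(fc) <- paste0("log2FC_", colnames(fc))
  data.frame(gene = rownames(cm), fc, check.names = FALSE)
}
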