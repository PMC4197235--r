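#' Efficiency-corrected relative quantities from a Cq table
#'
#' Technical replicates are averaged on the Cq scale per (sample, gene); the
#' relative quantity of gene g in sample s is RQ = E_g^(Cq_cal - Cq_s) where
#' Cq_cal is the gene's mean Cq over the calibrator condition and E_g the
#' per-primer amplification efficiency (fold per cycle; 2 = 100%).
#'
#' @param table Cq table: data.frame(sample, condition, gene, replicate, Cq,
#'   efficiency); efficiencies may also be given in percent (> 2 is read as
#'   percent, e.g. 95 -> 1.95).
#' @param calibrator calibrator condition label.
#' @return data.frame(sample, condition, gene, RQ).
#' @export
relativeQuantities <- function(table, calibrator) {
  req <- c("sample", "condition", "gene", "Cq", "efficiency")
  stopifnot(all(req %in% colnames(table)))
  if (any(table$Cq <= 0)) stop("Cq values must be positive")
  table$efficiency <- ifelse(table$efficiency > 2,
                             1 + table$efficiency / 100, table$efficiency)
  if (any(table$efficiency <= 1 | table$efficiency > 2))
    stop("efficiencies must lie in (1, 2]")
  agg <- aggregate(Cq ~ sample + condition + gene + efficiency, table, mean)
  for (g in unique(agg$gene)) {
    if (!any(agg$gene == g & agg$condition == calibrator))
      stop("gene missing in calibrator condition: ", g)
  }
  cal <- aggregate(Cq ~ gene, agg[agg$condition == calibrator, ], mean)
  calCq <- setNames(cal$Cq, cal$gene)
  agg$RQ <- agg$efficiency^(calCq[agg$gene] - agg$Cq)
  agg[order(agg$gene, agg$sample), c("sample", "condition", "gene", "RQ")]
}

#' Multi-reference-normalised qPCR fold changes
#'
#' For each day, relative quantities are computed against the day's sham
#' calibrator, every sample is normalised by the geometric mean of its three
#' reference-gene RQs (so sample-to-sample loading differences cancel), and
#' per gene the log2 fold change is the mean over biological replicates of
#' log2 normalised expression in the injured arm minus the sham arm. Standard
#' errors come from the replicate variability of the two arms.
#'
#' @param table Cq table with conditions named <arm>-<day> (e.g. sham-1d,
#'   injured-1d).
#' @param referenceGenes reference genes, measured in every sample.
#' @param days day labels to process; defaults to every day present.
#' @param arms character(2): calibrator/sham arm first, injured arm second.
#' @return Fold-change table: data.frame(gene, condition, log2FC, se, n,
#'   source) with condition = day, source = "qPCR"; reference genes excluded.
#' @examples
#' cq <- simulateCqTable(c(ptgis = 2), c(ptgis = 2, ef1a = 2, rpl13a = 2,
#'   tuba1 = 2), cqNoiseSd = 0, seed = 1)
#' qpcrFoldChanges(cq)
#' @export
qpcrFoldChanges <- function(table, referenceGenes = c("ef1a", "rpl13a", "tuba1"),
                            days = NULL, arms = c("sham", "injured")) {
  condParts <- strsplit(as.character(table$condition), "-", fixed = TRUE)
  table$arm <- vapply(condParts, `[`, character(1), 1)
  table$day <- vapply(condParts, function(p) paste(p[-1], collapse = "-"),
                      character(1))
  if (is.null(days)) days <- unique(table$day)
  rows <- list()
  for (day in days) {
    sub <- table[table$day == day, ]
    rq <- relativeQuantities(sub, calibrator = paste0(arms[1], "-", day))
    for (s in unique(rq$sample)) {
      if (!all(referenceGenes %in% rq$gene[rq$sample == s]))
        stop("missing reference gene in sample ", s)
    }
    refs <- rq[rq$gene %in% referenceGenes, ]
    nf <- tapply(refs$RQ, refs$sample, function(v) exp(mean(log(v))))
    rq$norm <- rq$RQ / nf[rq$sample]
    targets <- setdiff(unique(rq$gene), referenceGenes)
    for (g in targets) {
      gi <- rq[rq$gene == g, ]
      byArm <- split(log2(gi$norm), vapply(strsplit(gi$condition, "-"),
                                           `[`, character(1), 1))
      sham <- byArm[[arms[1]]]; inj <- byArm[[arms[2]]]
      if (is.null(sham) || is.null(inj)) next
      se <- sqrt(var(inj) / length(inj) + var(sham) / length(sham))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = day, log2FC = mean(inj) - mean(sham),
        se = if (is.finite(se)) se else 0, n = length(inj), source = "qPCR")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
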