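#' Build a simulation configuration
#'
#' Returns a validated \linkS4class{SimulationConfig}. The defaults describe
#' the study design every acceptance simulation uses: a 5-condition (control,
#' 1/3/5/7 days post-injury) x 3-replicate log2 expression matrix with probe
#' multiplicity, 25% of genes differentially expressed with effects of sd 2
#' log2 units, measurement noise of 0.3 log2 units, half of all genes pinned
#' below the log2 = 6 expression floor, two planted co-expression modules
#' (18 and 21 genes, rho = 0.95) with distinct injury-response time profiles,
#' and a signed hub centred on \emph{ptgis}.
#'
#' @param nGenes,probesPerGene,conditions,nReplicates,baselineMean,baselineSd
#'   see \linkS4class{SimulationConfig}.
#' @param deFraction,effectSizeSd,moduleSpec,hubSpec,noiseSd,bioNoiseSd
#'   see \linkS4class{SimulationConfig}.
#' @param lowExprFraction see \linkS4class{SimulationConfig}.
#' @param probeNoiseSd,seed see \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, lowExprFraction = 0, seed = 1)
#' @export
simulationConfig <- function(nGenes = 1200,
                             probesPerGene = c(1, 1, 1, 2),
                             conditions = c("control", "1d", "3d", "5d", "7d"),
                             nReplicates = 3,
                             baselineMean = 8, baselineSd = 1.2,
                             deFraction = 0.25, effectSizeSd = 2,
                             moduleSpec = defaultModuleSpec(conditions),
                             hubSpec = defaultHubSpec(conditions),
                             noiseSd = 0.3, bioNoiseSd = 0.35,
                             lowExprFraction = 0.5,
                             probeNoiseSd = 0.2, seed = 17993) {
  cfg <- new("SimulationConfig", nGenes = nGenes, probesPerGene = probesPerGene,
             conditions = conditions, nReplicates = nReplicates,
             baselineMean = baselineMean, baselineSd = baselineSd,
             deFraction = deFraction, effectSizeSd = effectSizeSd,
             moduleSpec = moduleSpec, hubSpec = hubSpec, noiseSd = noiseSd,
             bioNoiseSd = bioNoiseSd, lowExprFraction = lowExprFraction,
             probeNoiseSd = probeNoiseSd, seed = seed)
  msg <- validObject(cfg, test = TRUE)
  if (!isTRUE(msg)) stop("configuration error: ", paste(msg, collapse = "; "))
  cfg
}

#' @rdname simulationConfig
#' @export
defaultModuleSpec <- function(conditions = c("control", "1d", "3d", "5d", "7d")) {
  k <- length(conditions)
  early <- approxProfile(c(0, 2.2, 1.6, 0.9, 0.3), k)
  late <- approxProfile(c(0, -0.5, 1.2, 2.0, 1.4), k)
  list(list(size = 18, rho = 0.95, profile = early, scale = 1.5),
       list(size = 21, rho = 0.95, profile = late, scale = 1.5))
}

#' @rdname simulationConfig
#' @export
defaultHubSpec <- function(conditions = c("control", "1d", "3d", "5d", "7d")) {
  list(hub = "ptgis",
       profile = approxProfile(c(0, 2.5, 2.0, 1.0, 0.4), length(conditions)),
       scale = 1.5,
       deps = data.frame(gene = c("ca2", "usp2a", "sgce", "acta1a"),
                         sign = c(1, -1, -1, -1),
                         slope = c(1.0, 0.8, 0.7, 1.0),
                         sd = rep(0.25, 4)))
}

# stretch/shrink a 5-point template to k conditions
approxProfile <- function(template, k) {
  if (k == length(template)) return(template)
  stats::approx(seq_along(template), template, n = k)$y
}

#' Simulate a time-course expression study with planted structure
#'
#' Generates an \linkS4class{ExpressionStudy} and the matching
#' \linkS4class{GroundTruth}. Planted differentially expressed genes get
#' per-condition mean shifts drawn from N(0, effectSizeSd). Module genes
#' follow the latent-factor model gene = scale * (sqrt(rho) L + sqrt(1-rho) Z)
#' with L a standardised per-sample latent built from the module's shared time
#' profile, so the expected within-module correlation is rho (before
#' measurement noise). Hub dependents equal slope * hub signal plus residual
#' noise, with the planted sign. A \code{lowExprFraction} of genes is pinned
#' below the log2 = 6 floor. Probes of a gene share its signal plus a
#' probe-specific offset and independent measurement noise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list(study = ExpressionStudy, truth = GroundTruth).
#' @examples
#' sim <- simulateTimecourseStudy(simulationConfig(nGenes = 60, seed = 1))
#' sim$study
#' @export
simulateTimecourseStudy <- function(config) {
  msg <- validObject(config, test = TRUE)
  if (!isTRUE(msg)) stop("configuration error: ", paste(msg, collapse = "; "))
  set.seed(config@seed)
  layout <- designLayout(config)
  sig <- simulateGeneSignals(config, layout)
  study <- probesFromSignals(config, layout, sig)
  list(study = study$study,
       truth = new("GroundTruth", deGenes = sig$deGenes,
                   moduleMembership = sig$moduleMembership,
                   hubEdges = sig$hubEdges,
                   concordantGenes = character(),
                   lowExprFeatures = study$lowExprFeatures))
}

designLayout <- function(config, conditions = config@conditions,
                         nReplicates = config@nReplicates) {
  k <- length(conditions)
  reps <- rep(nReplicates, length.out = k)
  cond <- rep(conditions, reps)
  repid <- unlist(lapply(reps, seq_len))
  list(conditions = conditions, cond = cond, repid = repid,
       n = length(cond),
       sampleIds = paste0(cond, "_r", repid))
}

# Assign gene roles and draw per-gene, per-sample signal (no probe/measurement
# noise yet).  Returns signals (genes x samples), condition-mean profiles, and
# the ground-truth labels.
simulateGeneSignals <- function(config, layout, profiles = NULL) {
  nG <- config@nGenes
  cond <- layout$cond
  n <- layout$n
  condIdx <- match(cond, layout$conditions)

  geneIds <- sprintf("g%05d", seq_len(nG))
  roles <- assignRoles(config, geneIds)
  geneIds[roles$hubGenes$idx] <- roles$hubGenes$name

  # per-gene condition profile (centered effects, control = 0)
  if (is.null(profiles)) {
    profiles <- matrix(0, nG, length(layout$conditions))
    for (g in roles$deIdx)
      profiles[g, -1] <- rnorm(length(layout$conditions) - 1, 0, config@effectSizeSd)
  }
  baseline <- rnorm(nG, config@baselineMean, config@baselineSd)
  baseline[roles$lowIdx] <- rnorm(length(roles$lowIdx), 4, 0.3)
  profiles[roles$lowIdx, ] <- 0

  signals <- baseline + profiles[, condIdx, drop = FALSE]

  moduleMembership <- integer(0)
  if (length(config@moduleSpec)) {
    for (m in seq_along(config@moduleSpec)) {
      spec <- config@moduleSpec[[m]]
      idx <- roles$moduleIdx[[m]]
      latent <- standardisedLatent(spec$profile[condIdx], n)
      scl <- if (is.null(spec$scale)) 1.5 else spec$scale
      for (g in idx) {
        z <- rnorm(n)
        signals[g, ] <- baseline[g] +
          scl * (sqrt(spec$rho) * latent + sqrt(1 - spec$rho) * z)
      }
      moduleMembership <- c(moduleMembership,
                            setNames(rep.int(m, length(idx)), geneIds[idx]))
    }
  }

  hubEdges <- data.frame(source = character(), target = character(),
                         sign = numeric(), slope = numeric())
  if (length(config@hubSpec)) {
    hs <- config@hubSpec
    hubIdx <- roles$hubGenes$idx[1]
    scl <- if (is.null(hs$scale)) 1.5 else hs$scale
    hubSignal <- scl * standardisedLatent(hs$profile[condIdx], n)
    signals[hubIdx, ] <- baseline[hubIdx] + hubSignal
    for (j in seq_len(nrow(hs$deps))) {
      depIdx <- roles$hubGenes$idx[j + 1]
      slope <- hs$deps$sign[j] * hs$deps$slope[j]
      signals[depIdx, ] <- baseline[depIdx] + slope * hubSignal +
        rnorm(n, 0, hs$deps$sd[j])
    }
    hubEdges <- data.frame(source = hs$hub, target = hs$deps$gene,
                           sign = hs$deps$sign,
                           slope = hs$deps$sign * hs$deps$slope)
  }

  # biological replicate variability for genes outside the planted structures
  # (module and hub genes carry theirs through the latent terms)
  structGenes <- c(unlist(roles$moduleIdx), roles$hubGenes$idx)
  bg <- setdiff(seq_len(nG), structGenes)
  if (length(bg) && config@bioNoiseSd > 0) {
    signals[bg, ] <- signals[bg, ] +
      matrix(rnorm(length(bg) * n, 0, config@bioNoiseSd), length(bg), n)
  }
  deGenes <- geneIds[sort(unique(c(roles$deIdx, structGenes)))]

  list(signals = signals, geneIds = geneIds, profiles = profiles,
       baseline = baseline, roles = roles, deGenes = deGenes,
       moduleMembership = moduleMembership, hubEdges = hubEdges)
}

# deterministic partition of genes into low-expressed / module / hub / DE roles
assignRoles <- function(config, geneIds) {
  nG <- config@nGenes
  nLow <- floor(config@lowExprFraction * nG)
  lowIdx <- if (nLow > 0) (nG - nLow + 1):nG else integer()
  pool <- seq_len(nG - nLow)

  moduleIdx <- list()
  cursor <- 1
  for (m in seq_along(config@moduleSpec)) {
    sz <- config@moduleSpec[[m]]$size
    moduleIdx[[m]] <- pool[cursor:(cursor + sz - 1)]
    cursor <- cursor + sz
  }
  hubGenes <- list(idx = integer(), name = character())
  if (length(config@hubSpec)) {
    nHub <- 1 + nrow(config@hubSpec$deps)
    hubGenes <- list(idx = pool[cursor:(cursor + nHub - 1)],
                     name = c(config@hubSpec$hub, config@hubSpec$deps$gene))
    cursor <- cursor + nHub
  }
  rest <- pool[pool >= cursor]
  nDE <- round(config@deFraction * length(rest))
  deIdx <- if (nDE > 0) sort(sample(rest, nDE)) else integer()
  list(lowIdx = lowIdx, moduleIdx = moduleIdx, hubGenes = hubGenes,
       deIdx = deIdx)
}

# standardise profile-plus-noise latent to unit variance; the jitter is the
# shared biological variability of the latent pathway around its time profile
standardisedLatent <- function(profileBySample, n, etaSd = 0.25) {
  raw <- profileBySample + rnorm(n, 0, etaSd)
  vp <- mean((profileBySample - mean(profileBySample))^2)
  (raw - mean(profileBySample)) / sqrt(vp + etaSd^2)
}

# expand gene signals to probes, add measurement noise, pin low features
probesFromSignals <- function(config, layout, sig, floor = 6) {
  nG <- config@nGenes
  nProbes <- rep(pmax(1, round(config@probesPerGene)), length.out = nG)
  featGene <- rep(seq_len(nG), nProbes)
  probeNum <- unlist(lapply(nProbes, seq_len))
  featIds <- paste0(sprintf("f%05d", featGene), "_p", probeNum)
  nF <- length(featGene)

  offsets <- rnorm(nF, 0, config@probeNoiseSd)
  values <- sig$signals[featGene, , drop = FALSE] + offsets +
    matrix(rnorm(nF * layout$n, 0, config@noiseSd), nF, layout$n)

  lowFeat <- featGene %in% sig$roles$lowIdx
  values[lowFeat, ] <- pmin(values[lowFeat, , drop = FALSE], floor - 0.05)
  dimnames(values) <- list(featIds, layout$sampleIds)

  study <- ExpressionStudy(values, geneSymbols = sig$geneIds[featGene],
                           conditions = layout$cond,
                           replicates = layout$repid,
                           conditionLevels = layout$conditions)
  list(study = study, lowExprFeatures = featIds[lowFeat])
}

#' Simulate a pair of studies with partially concordant responses
#'
#' The first study is drawn exactly as \code{simulateTimecourseStudy} would.
#' The companion study shares gene identities and baselines; a designated
#' fraction of the first study's differentially expressed genes keep their
#' condition-mean profile (up to \code{profileNoiseSd} per condition), all
#' other genes receive independent profiles. The companion may use fewer
#' conditions and an unbalanced replicate design, emulating a second,
#' smaller deposited dataset.
#'
#' @param config a \linkS4class{SimulationConfig} for the first study.
#' @param concordantFraction proportion of the first study's DE genes whose
#'   profiles carry over.
#' @param profileNoiseSd per-condition noise added to carried-over profiles
#'   (log2 units).
#' @param conditionsB,nReplicatesB design of the companion study; defaults to
#'   control/1d/3d/5d with 4,1,2,2 replicates.
#' @param seed integer seed for the companion draw.
#' @return list(studyA, studyB, truth) with
#'   \code{trueConcordantGenes(truth)} naming the planted concordant genes.
#' @export
simulateConcordantPair <- function(config, concordantFraction = 0.1,
                                   profileNoiseSd = 0.1,
                                   conditionsB = c("control", "1d", "3d", "5d"),
                                   nReplicatesB = c(4, 1, 2, 2),
                                   seed = config@seed + 1) {
  if (concordantFraction < 0 || concordantFraction > 1)
    stop("configuration error: invalid 'concordantFraction'")
  if (!all(conditionsB %in% config@conditions))
    stop("configuration error: 'conditionsB' must be a subset of conditions")
  simA <- simulateTimecourseStudy(config)

  set.seed(seed)
  layout <- designLayout(config, conditions = conditionsB,
                         nReplicates = nReplicatesB)
  # regenerate study A's internals deterministically to access its profiles
  set.seed(config@seed)
  layoutA <- designLayout(config)
  sigA <- simulateGeneSignals(config, layoutA)

  set.seed(seed)
  nG <- config@nGenes
  condSel <- match(conditionsB, config@conditions)
  deIdx <- which(sigA$geneIds %in% sigA$deGenes)
  nConc <- round(concordantFraction * length(deIdx))
  concIdx <- if (nConc > 0) sort(sample(deIdx, nConc)) else integer()

  profilesB <- matrix(0, nG, length(config@conditions))
  for (g in seq_len(nG)) {
    if (g %in% concIdx) {
      profilesB[g, ] <- sigA$profiles[g, ] +
        rnorm(ncol(profilesB), 0, profileNoiseSd)
      profilesB[g, 1] <- 0
    } else if (g %in% deIdx) {
      profilesB[g, -1] <- rnorm(ncol(profilesB) - 1, 0, config@effectSizeSd)
    }
  }
  condIdxB <- match(layout$cond, config@conditions)
  signalsB <- sigA$baseline + profilesB[, condIdxB, drop = FALSE]
  if (config@bioNoiseSd > 0) {
    signalsB <- signalsB + matrix(rnorm(nG * layout$n, 0, config@bioNoiseSd),
                                  nG, layout$n)
  }
  sigB <- sigA
  sigB$signals <- signalsB
  studyB <- probesFromSignals(config, layout, sigB)

  truth <- new("GroundTruth", deGenes = sigA$deGenes,
               moduleMembership = sigA$moduleMembership,
               hubEdges = sigA$hubEdges,
               concordantGenes = sigA$geneIds[concIdx],
               lowExprFeatures = studyB$lowExprFeatures)
  list(studyA = simA$study, studyB = studyB$study, truth = truth)
}

#' Simulate a qPCR Cq table from planted fold changes
#'
#' Cq values follow Cq = Cq0 - log_E(Q * L) + noise where Q = 2^log2FC in the
#' injured arm (1 in sham and for reference genes), L is a per-sample loading
#' factor common to every gene of the sample, and E the per-primer
#' amplification efficiency (fold per cycle). Measures come in technical
#' duplicates. Under this model geometric-mean reference normalisation cancels
#' L exactly, so the noiseless round trip through \code{qpcrFoldChanges}
#' recovers the planted fold changes.
#'
#' @param foldChanges named numeric, gene -> log2 fold change (injured vs
#'   sham); the same value is planted at every day in \code{days}.
#' @param efficiencies named numeric, gene -> E in (1, 2]; must cover every
#'   target and reference gene.
#' @param nBiologicalReplicates biological samples per arm and day.
#' @param cqNoiseSd technical noise on the Cq scale (cycles).
#' @param referenceGenes stable reference genes (planted fold change 0).
#' @param days day labels; conditions are named sham-<day> / injured-<day>.
#' @param loadingSd log-scale sd of the per-sample loading factor.
#' @param seed integer seed.
#' @return data.frame(sample, condition, gene, replicate, Cq, efficiency).
#' @examples
#' cq <- simulateCqTable(c(ptgis = 2), c(ptgis = 2, ef1a = 2, rpl13a = 2,
#'   tuba1 = 2), cqNoiseSd = 0, seed = 1)
#' head(cq)
#' @export
simulateCqTable <- function(foldChanges, efficiencies,
                            nBiologicalReplicates = 3, cqNoiseSd = 0.2,
                            referenceGenes = c("ef1a", "rpl13a", "tuba1"),
                            days = "1d", loadingSd = 0.1, seed = 1) {
  genes <- unique(c(names(foldChanges), referenceGenes))
  missingE <- setdiff(genes, names(efficiencies))
  if (length(missingE))
    stop("missing efficiency for gene(s): ", paste(missingE, collapse = ", "))
  if (any(efficiencies[genes] <= 1 | efficiencies[genes] > 2))
    stop("efficiencies must lie in (1, 2]")
  if (any(names(foldChanges) %in% referenceGenes &
          abs(foldChanges[names(foldChanges) %in% referenceGenes]) > 0))
    stop("reference genes must have fold change 0")
  fc <- setNames(rep(0, length(genes)), genes)
  fc[names(foldChanges)] <- foldChanges

  set.seed(seed)
  cq0 <- setNames(runif(length(genes), 20, 28), genes)
  rows <- list()
  for (day in days) {
    for (arm in c("sham", "injured")) {
      condition <- paste0(arm, "-", day)
      for (b in seq_len(nBiologicalReplicates)) {
        sampleId <- paste0(condition, "-", b)
        logL <- rnorm(1, 0, loadingSd)
        for (g in genes) {
          E <- efficiencies[[g]]
          q <- if (arm == "injured") fc[[g]] * log(2) else 0
          base <- cq0[[g]] - (q + logL) / log(E)
          for (tech in 1:2) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sampleId, condition = condition, gene = g,
              replicate = tech, Cq = base + rnorm(1, 0, cqNoiseSd),
              efficiency = E)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
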