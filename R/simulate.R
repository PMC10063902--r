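#' Simulation parameters for a synthetic phosphoproteomics study
#'
#' Defaults emulate a four-arm hippocampal phosphoproteomics experiment:
#' 4 groups (C, H, S, E) x 3 biological replicates, 21,239 phosphosites on
#' 4,290 proteins, serine/threonine/tyrosine composition 82.76/16.12/1.12%,
#' and a peptide multiplicity distribution of 17,003 : 2,824 : 571 : 95 for
#' the singly/doubly/triply/more-than-triply phosphorylated classes (the
#' latter two collapse into the `"3+"` multiplicity state of the site
#' table).  Intensities are log-normal: on the log2 scale a protein baseline
#' plus a site offset plus a group effect plus replicate noise.  Missingness
#' is a mixture of a missing-completely-at-random floor and an
#' intensity-dependent (missing-not-at-random) component whose weight is
#' `mnarWeight`.
#'
#' Ground-truth structure: a fraction of sites receive a +/- `effectSizeLog2`
#' shift in group H relative to C ("disease" sites); designated reversal
#' proteins carry two disease sites each whose shift is undone in group S
#' and/or E (treatment groups return to the C level, i.e. the significant
#' direction in the treatment-vs-H contrast opposes the H-vs-C direction).
#' Reversal proteins are drawn from the upper half of the abundance
#' distribution with confidently localised sites, because recovery is only
#' defined for sites the class-I and valid-value filters are designed to
#' keep.  A designated "target" KEGG set per treatment is packed with
#' reversal proteins (`enrichmentSpike` fraction) so enrichment ranking has
#' a known answer, and PPI edges are oversampled at high confidence within
#' the target sets.
#'
#' @param nProteins,nSites problem size.
#' @param residueProbs probabilities for S/T/Y.
#' @param multiplicityProbs probabilities for the 1/2/3/3+ peptide classes.
#' @param groups group labels; `replicates` samples per group.
#' @param replicates biological replicates per group.
#' @param baseLog2Mean,baseLog2SD protein baseline distribution (log2).
#' @param siteSD site-to-site offset SD (log2).
#' @param noiseSD replicate noise SD (log2).
#' @param effectSizeLog2 group-shift magnitude for affected sites.
#' @param fracDifferentialHC fraction of sites differential in H vs C.
#' @param fracReversedByS,fracReversedByE fraction of the H/C-differential
#'   sites whose effect is reversed by each treatment.
#' @param nMixedProteins reversal proteins per treatment forced to carry
#'   discordant site pairs (the "Up/down" pattern).
#' @param missingRate overall expected missing fraction; `mnarWeight` in
#'   \[0,1\] sets how strongly missingness concentrates at low intensity.
#' @param mnarWeight MNAR mixture weight.
#' @param locProbShape1,locProbShape2 Beta parameters for localization
#'   probabilities (skewed toward 1; a minority falls below 0.75).
#' @param deltaShape,deltaScale Gamma parameters for delta scores (a
#'   minority falls below 8).
#' @param nGeneSets,setSizeRange random annotation sets.
#' @param enrichmentSpike fraction of each target set drawn from reversal
#'   proteins.
#' @param ppiDensity background edge density; `ppiConfShape1/2` Beta
#'   parameters for background confidences.
#' @param ppiConfShape1,ppiConfShape2 Beta parameters for edge confidence.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the parameter set.
#' @return classed list of validated parameters (`SimulationParams`).
#' @export
simulationParams <- function(nProteins = 4290L,
                             nSites = 21239L,
                             residueProbs = c(S = 0.8276, T = 0.1612,
                                              Y = 0.0112),
                             multiplicityProbs = c(`1` = 17003, `2` = 2824,
                                                   `3` = 571, `3+` = 95) /
                               20493,
                             groups = c("C", "H", "S", "E"),
                             replicates = 3L,
                             baseLog2Mean = 23, baseLog2SD = 2,
                             siteSD = 1, noiseSD = 0.3,
                             effectSizeLog2 = 1.5,
                             fracDifferentialHC = 0.06,
                             fracReversedByS = 0.2,
                             fracReversedByE = 0.25,
                             nMixedProteins = 4L,
                             missingRate = 0.2, mnarWeight = 0.8,
                             locProbShape1 = 6, locProbShape2 = 1,
                             deltaShape = 2, deltaScale = 15,
                             nGeneSets = 50L, setSizeRange = c(15L, 120L),
                             enrichmentSpike = 0.6,
                             ppiDensity = 5e-4,
                             ppiConfShape1 = 2, ppiConfShape2 = 2,
                             seed = 1L) {
  p <- list(nProteins = as.integer(nProteins), nSites = as.integer(nSites),
            residueProbs = residueProbs,
            multiplicityProbs = multiplicityProbs,
            groups = groups, replicates = as.integer(replicates),
            baseLog2Mean = baseLog2Mean, baseLog2SD = baseLog2SD,
            siteSD = siteSD, noiseSD = noiseSD,
            effectSizeLog2 = effectSizeLog2,
            fracDifferentialHC = fracDifferentialHC,
            fracReversedByS = fracReversedByS,
            fracReversedByE = fracReversedByE,
            nMixedProteins = as.integer(nMixedProteins),
            missingRate = missingRate, mnarWeight = mnarWeight,
            locProbShape1 = locProbShape1, locProbShape2 = locProbShape2,
            deltaShape = deltaShape, deltaScale = deltaScale,
            nGeneSets = as.integer(nGeneSets),
            setSizeRange = as.integer(setSizeRange),
            enrichmentSpike = enrichmentSpike,
            ppiDensity = ppiDensity,
            ppiConfShape1 = ppiConfShape1, ppiConfShape2 = ppiConfShape2,
            seed = as.integer(seed))
  .checkProbs(p$residueProbs, "residueProbs")
  .checkProbs(p$multiplicityProbs, "multiplicityProbs")
  if (p$nProteins <= 0 || p$nSites <= 0)
    .stopf("counts must be positive")
  if (p$nSites < p$nProteins)
    .stopf("need at least one site per protein (nSites >= nProteins)")
  if (p$missingRate < 0 || p$missingRate >= 1)
    .stopf("missingRate must lie in [0, 1)")
  if (p$mnarWeight < 0 || p$mnarWeight > 1)
    .stopf("mnarWeight must lie in [0, 1]")
  if (p$fracDifferentialHC < 0 || p$fracDifferentialHC > 1 ||
      p$fracReversedByS < 0 || p$fracReversedByS > 1 ||
      p$fracReversedByE < 0 || p$fracReversedByE > 1)
    .stopf("fractions must lie in [0, 1]")
  if (p$fracReversedByS + 0 > 1 || p$fracReversedByE > 1)
    .stopf("infeasible reversal fractions")
  if (p$replicates < 2) .stopf("need >= 2 replicates per group")
  if (!identical(p$groups, c("C", "H", "S", "E")))
    .stopf("the generator models the four-arm C/H/S/E design")
  class(p) <- "SimulationParams"
  p
}

# pick `n2` proteins with >=2 sites and above-median baseline to act as
# reversal proteins; returns protein indices
.pickReversalProteins <- function(sitesPerProt, base, n2, exclude = integer(0)) {
  cand <- which(sitesPerProt >= 2 & base >= median(base))
  cand <- setdiff(cand, exclude)
  if (length(cand) < n2)
    .stopf("infeasible params: only %d eligible reversal proteins, need %d",
           length(cand), n2)
  sample(cand, n2)
}

#' Generate a complete synthetic study
#'
#' Produces, deterministically for a fixed parameter set, every input the
#' pipeline consumes plus a ground-truth ledger: the site table, the study
#' design (with default contrasts H/C, S/H, E/H), gene-set annotations
#' (KEGG sets including the spiked targets, plus subcellular compartments),
#' a PPI edge list, and per-site / per-protein truth.
#'
#' @param params a [simulationParams()] object.
#' @return list with elements `experiment` ([PhosphoExperiment-class]),
#'   `design` ([StudyDesign-class]), `geneSets`
#'   ([GeneSetCollection-class]), `edges` (canonical edge data.frame) and
#'   `truth` (list `sites`, `proteins`, `targetSets`).
#' @examples
#' sim <- simulateStudy(simulationParams(nProteins = 60, nSites = 300,
#'                                       nGeneSets = 8, seed = 7))
#' sim$experiment
#' @export
simulateStudy <- function(params = simulationParams()) {
  stopifnot(inherits(params, "SimulationParams"))
  p <- params
  set.seed(p$seed)

  nP <- p$nProteins; nS <- p$nSites
  proteins <- sprintf("P%05d", seq_len(nP))
  genes <- sprintf("GENE%04d", seq_len(nP))

  ## site -> protein assignment: every protein gets >= 1 site, remainder
  ## multinomial with log-normal protein weights (few proteins carry many
  ## sites, the familiar long tail)
  w <- exp(rnorm(nP, 0, 1))
  protOf <- c(seq_len(nP),
              sample.int(nP, nS - nP, replace = TRUE, prob = w))
  protOf <- sort(protOf)
  sitesPerProt <- tabulate(protOf, nP)

  ## distinct positions within each protein
  position <- unlist(lapply(seq_len(nP), function(i) {
    k <- sitesPerProt[i]
    sort(sample.int(2500L, k))
  }), use.names = FALSE)

  residue <- sample(names(p$residueProbs), nS, replace = TRUE,
                    prob = p$residueProbs)
  pepClass <- sample(names(p$multiplicityProbs), nS, replace = TRUE,
                     prob = p$multiplicityProbs)
  multiplicity <- ifelse(pepClass %in% c("3", "3+"), "3+", pepClass)
  locProb <- rbeta(nS, p$locProbShape1, p$locProbShape2)
  deltaScore <- rgamma(nS, shape = p$deltaShape, scale = p$deltaScale)

  base <- rnorm(nP, p$baseLog2Mean, p$baseLog2SD)
  siteMean <- base[protOf] + rnorm(nS, 0, p$siteSD)

  ## --- ground-truth effect structure -------------------------------------
  nDiff <- round(p$fracDifferentialHC * nS)
  nRevS <- round(p$fracReversedByS * nDiff)
  nRevE <- round(p$fracReversedByE * nDiff)
  nRevProtS <- floor(nRevS / 2)   # two reversed sites per reversal protein
  nRevProtE <- floor(nRevE / 2)
  if (2 * (nRevProtS + nRevProtE) > nDiff)
    .stopf("infeasible params: more reversed sites than differential sites")
  # nMixedProteins is an upper bound; small studies get what fits
  nMixedS <- min(p$nMixedProteins, nRevProtS)
  nMixedE <- min(p$nMixedProteins, nRevProtE)

  revProtS <- .pickReversalProteins(sitesPerProt, base, nRevProtS)
  revProtE <- .pickReversalProteins(sitesPerProt, base, nRevProtE,
                                    exclude = revProtS)

  signH <- integer(nS)          # H-vs-C true direction (+1 / -1 / 0)
  revS <- logical(nS)
  revE <- logical(nS)
  spiked <- logical(nS)

  assignRev <- function(protIdx, flag, signH, revFlag, spiked, nMixed) {
    for (j in seq_along(protIdx)) {
      sites <- which(protOf == protIdx[j])
      pick <- sites[sample.int(length(sites), 2L)]
      if (j <= nMixed) sg <- c(1L, -1L) else
        sg <- rep(sample(c(-1L, 1L), 1L), 2L)
      signH[pick] <- sg
      revFlag[pick] <- TRUE
      spiked[pick] <- TRUE
    }
    list(signH = signH, revFlag = revFlag, spiked = spiked)
  }
  r <- assignRev(revProtS, "S", signH, revS, spiked, nMixedS)
  signH <- r$signH; revS <- r$revFlag; spiked <- r$spiked
  r <- assignRev(revProtE, "E", signH, revE, spiked, nMixedE)
  signH <- r$signH; revE <- r$revFlag; spiked <- r$spiked

  ## remaining disease-only differential sites
  nLeft <- nDiff - sum(spiked)
  if (nLeft > 0) {
    pool <- which(!spiked)
    pick <- sample(pool, nLeft)
    signH[pick] <- sample(c(-1L, 1L), nLeft, replace = TRUE)
    spiked[pick] <- TRUE
  }

  ## spiked sites must be recoverable: confident localisation and score
  if (any(spiked)) {
    ns <- sum(spiked)
    locProb[spiked] <- 0.75 + 0.25 * rbeta(ns, 4, 1)
    deltaScore[spiked] <- 8 + rgamma(ns, shape = p$deltaShape,
                                     scale = p$deltaScale)
  }

  e <- p$effectSizeLog2
  deltaH <- e * signH
  deltaS <- ifelse(revS, -deltaH, 0)
  deltaE <- ifelse(revE, -deltaH, 0)
  groupMeans <- cbind(C = siteMean,
                      H = siteMean + deltaH,
                      S = siteMean + deltaH + deltaS,
                      E = siteMean + deltaH + deltaE)

  ## --- intensities and missingness ---------------------------------------
  reps <- p$replicates
  samples <- unlist(lapply(p$groups, function(g) paste0(g, seq_len(reps))))
  groupOfSample <- rep(p$groups, each = reps)
  logI <- matrix(0, nS, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples))
    logI[, j] <- groupMeans[, groupOfSample[j]] + rnorm(nS, 0, p$noiseSD)

  if (p$missingRate > 0) {
    u <- (rank(logI, ties.method = "first") - 0.5) / length(logI)
    pm <- p$missingRate * ((1 - p$mnarWeight) +
                             2 * p$mnarWeight * (1 - u))
    pm <- pmin(pmax(pm, 0), 1)
    miss <- matrix(runif(length(logI)) < pm, nS, length(samples))
    logI[miss] <- NA
  }
  intensity <- 2^logI

  site <- data.frame(protein = proteins[protOf], gene = genes[protOf],
                     position = position, residue = residue,
                     localizationProb = locProb, deltaScore = deltaScore,
                     multiplicity = multiplicity, stringsAsFactors = FALSE)
  pe <- PhosphoExperiment(intensity, site)
  pe <- .appendStep(pe, "simulate", seed = p$seed, n_sites = nS,
                    n_proteins = nP)

  design <- StudyDesign(setNames(split(samples, rep(seq_along(p$groups),
                                                    each = reps)),
                                 p$groups))

  ## --- truth ledgers ------------------------------------------------------
  dirLab <- function(s) c("down", "none", "up")[s + 2L]
  truthSites <- data.frame(
    site_id = rownames(pe), protein = site$protein, gene = site$gene,
    meanC = groupMeans[, "C"], meanH = groupMeans[, "H"],
    meanS = groupMeans[, "S"], meanE = groupMeans[, "E"],
    diffHC = signH != 0L, dirHC = dirLab(signH),
    diffSH = revS, dirSH = dirLab(-signH * revS),
    diffEH = revE, dirEH = dirLab(-signH * revE),
    stringsAsFactors = FALSE
  )
  protClass <- function(revProt, revFlag) {
    cls <- setNames(rep("none", nP), genes)
    for (i in revProt) {
      sgn <- signH[protOf == i & revFlag]
      cls[genes[i]] <- if (length(unique(sgn)) > 1) "mixed"
        else if (sgn[1] > 0) "up_down" else "down_up"
    }
    cls
  }
  truthProteins <- data.frame(
    gene = genes, protein = proteins,
    classS = unname(protClass(revProtS, revS)),
    classE = unname(protClass(revProtE, revE)),
    stringsAsFactors = FALSE
  )

  ## --- annotations ---------------------------------------------------------
  sizes <- sample(seq(p$setSizeRange[1], p$setSizeRange[2]), p$nGeneSets,
                  replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, min(k, length(genes))))
  names(sets) <- sprintf("PATHWAY_%03d", seq_along(sets))
  spikeSet <- function(revProt, label) {
    k <- max(20L, min(60L, 2L * length(revProt)))
    nSpike <- min(length(revProt), round(p$enrichmentSpike * k))
    members <- unique(c(genes[sample(revProt, nSpike)],
                        sample(genes, k - nSpike)))
    setNames(list(members), label)
  }
  targetS <- if (nRevProtS > 0) spikeSet(revProtS, "TARGET_PATHWAY_S") else NULL
  targetE <- if (nRevProtE > 0) spikeSet(revProtE, "TARGET_PATHWAY_E") else NULL
  keggSets <- c(sets, targetS, targetE)
  compartments <- c("CYTOSKELETON", "MITOCHONDRION", "CYTOPLASM",
                    "PEROXISOME", "NUCLEUS", "PLASMA_MEMBRANE")
  subcell <- lapply(compartments, function(cc)
    sample(genes, round(0.15 * nP)))
  names(subcell) <- compartments
  gsc <- GeneSetCollection(
    c(keggSets, subcell),
    category = c(rep("KEGG", length(keggSets)),
                 rep("SUBCELL", length(subcell)))
  )

  ## --- PPI edges -----------------------------------------------------------
  nBg <- round(p$ppiDensity * nP * (nP - 1) / 2)
  ia <- sample.int(nP, nBg, replace = TRUE)
  ib <- sample.int(nP, nBg, replace = TRUE)
  bg <- data.frame(a = genes[ia], b = genes[ib],
                   confidence = rbeta(nBg, p$ppiConfShape1, p$ppiConfShape2),
                   stringsAsFactors = FALSE)
  spikeEdges <- function(members) {
    m <- intersect(members, genes)
    if (length(m) < 2) return(NULL)
    prs <- t(combn(m, 2))
    keep <- runif(nrow(prs)) < 0.25
    if (!any(keep)) return(NULL)
    data.frame(a = prs[keep, 1], b = prs[keep, 2],
               confidence = runif(sum(keep), 0.7, 0.999),
               stringsAsFactors = FALSE)
  }
  spkList <- Filter(Negate(is.null), list(
    if (!is.null(targetS)) spikeEdges(targetS[[1]]),
    if (!is.null(targetE)) spikeEdges(targetE[[1]])))
  spk <- if (length(spkList)) do.call(rbind, spkList) else NULL
  edges <- suppressWarnings(canonicalizeEdges(rbind(bg, spk)))

  list(experiment = pe, design = design, geneSets = gsc, edges = edges,
       truth = list(sites = truthSites, proteins = truthProteins,
                    targetSets = c(if (!is.null(targetS)) "TARGET_PATHWAY_S",
                                   if (!is.null(targetE)) "TARGET_PATHWAY_E"),
                    params = p))
}

#' Compare pipeline output against simulation ground truth
#'
#' @param truth the `truth` element of [simulateStudy()].
#' @param differential named list of differential tables (one per
#'   contrast, names `H/C`, `S/H`, `E/H`), as from [computeContrast()].
#' @param reversal optional named list (`S`, `E`) of protein-level reversal
#'   hit tables, as from [classifyReversalProteins()] or
#'   [restrictToPathways()].
#' @param enrichment optional enrichment result (from
#'   [fisherEnrichment()]); target-set ranks are looked up in it.
#' @return list of recovery metrics: per-contrast `sensitivity` and `fdr`
#'   for site calls, per-treatment reversal-protein sensitivity, and the
#'   rank of each spiked target set.
#' @export
truthReport <- function(truth, differential, reversal = NULL,
                        enrichment = NULL) {
  out <- list()
  ts <- truth$sites
  diffCols <- c(`H/C` = "diffHC", `S/H` = "diffSH", `E/H` = "diffEH")
  dirCols <- c(`H/C` = "dirHC", `S/H` = "dirSH", `E/H` = "dirEH")
  for (cn in names(differential)) {
    dt <- differential[[cn]]
    if (!all(dt$site_id %in% ts$site_id))
      .stopf("mismatched identifiers: differential table '%s' does not come from this simulation", cn)
    if (!cn %in% names(diffCols)) next
    m <- match(dt$site_id, ts$site_id)
    trueFlag <- ts[[diffCols[cn]]][m]
    trueDir <- ts[[dirCols[cn]]][m]
    called <- dt$call != "ns"
    correct <- called & trueFlag & dt$call == trueDir
    sens <- if (any(trueFlag)) sum(correct) / sum(trueFlag) else NA_real_
    fdr <- if (any(called)) sum(called & !trueFlag) / sum(called) else 0
    out$differential[[cn]] <- list(sensitivity = sens, fdr = fdr,
                                   n_called = sum(called),
                                   n_true = sum(trueFlag))
  }
  if (!is.null(reversal)) {
    tp <- truth$proteins
    for (tr in names(reversal)) {
      cls <- tp[[paste0("class", tr)]]
      trueGenes <- tp$gene[cls != "none"]
      hitGenes <- toupper(reversal[[tr]]$gene)
      if (length(hitGenes) && !all(hitGenes %in% toupper(tp$gene)))
        .stopf("mismatched identifiers in reversal hits for treatment %s", tr)
      sens <- if (length(trueGenes))
        mean(toupper(trueGenes) %in% hitGenes) else NA_real_
      out$reversal[[tr]] <- list(sensitivity = sens,
                                 n_true = length(trueGenes),
                                 n_hit = length(hitGenes))
    }
  }
  if (!is.null(enrichment)) {
    for (sid in truth$targetSets) {
      r <- enrichment$rank[enrichment$set_id == sid]
      out$targetRank[[sid]] <- if (length(r)) r else NA_integer_
    }
  }
  out
}
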