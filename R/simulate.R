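## Synthetic multi-omics generator with planted three-layer modules and a
## serialised ground truth, so every pipeline stage is testable offline.
##
## Generative model (per-sample, standardised units):
##  * background entries of every layer are i.i.d. standard normal;
##  * each planted module k owns a disjoint gene block and tumor-sample
##    block; over its samples a latent factor f ~ N(factorMean, factorSd^2)
##    drives the module with direction dir_k (alternating +/-);
##  * module regulators carry unique latent components besides f: each
##    planted protein j has v_j and each planted repressor miRNA j has u_j,
##    and the module mRNAs load on f, the v's and the u's. Without those
##    unique components a Bayesian-network step could never justify a second
##    parent that merely re-measures f, so identifiable regulators must
##    carry signal of their own -- which is also how miRNA repression works
##    (direct action on targets, not only shared co-expression);
##  * repressor miRNAs load negatively (config `mirnaDirection`);
##  * tumor/normal differential expression is a mean shift on the DE genes;
##  * proteins of measured genes are a concordance-weighted mixture of the
##    gene's (standardised) mRNA profile and independent noise, so the
##    per-gene mRNA-protein correlation has a controllable target;
##  * PPI-expansion genes carry the module signature with a boosted loading
##    but no tumor/normal shift (the DE filter misses them; the PPI step is
##    what rescues them);
##  * survival times are exponential with hazard scaled by the expression
##    of a configured miRNA; censoring is uniform.

#' Configuration for the synthetic generator
#'
#' Defaults are deliberately desk-scale (minutes for the full pipeline) and
#' keep the qualitative layer-size asymmetry of tumor multi-omics studies
#' (proteins << mRNAs; a handful of normals).
#'
#' @param nGenes,nMirnas,nProteins,nTumor,nNormal layer dimensions.
#' @param nModules number of planted three-layer modules.
#' @param genesPerModule,samplesPerModule,proteinsPerModule,mirnasPerModule
#'   planted module composition.
#' @param expansionGenesPerModule coherent non-DE genes reachable via PPI.
#' @param moduleProteinGenes module genes (per module) that also get a
#'   protein measurement.
#' @param nDeGenes genes with a tumor/normal mean shift (includes all
#'   module genes).
#' @param deShift tumor-minus-normal shift of DE genes, in SD units (3 keeps
#'   a 10-normal cohort separable under Bonferroni at desk scale).
#' @param factorMean,factorSd module latent factor distribution over module
#'   samples.
#' @param factorLoading loading of module mRNAs on the factor.
#' @param proteinFactorLoading,proteinUniqueLoading loadings of planted
#'   regulator proteins on the factor and on their unique component.
#' @param geneProteinLoading loading of module mRNAs on each protein-unique
#'   component.
#' @param mirnaFactorLoading,mirnaUniqueLoading loadings of planted miRNAs.
#' @param geneMirnaLoading loading of module mRNAs on each miRNA-unique
#'   component.
#' @param mirnaDirection `"repressor"` (negative loading, default) or
#'   `"activator"`.
#' @param expansionBoost loading multiplier of PPI-expansion genes.
#' @param concordanceMean,concordanceSd background per-gene mRNA-protein
#'   concordance distribution (normal, truncated to `[-0.3, 0.9]`).
#' @param concordanceModule concordance target of module protein-genes.
#' @param targetsPerMirna,decoyTargets direct-target table composition.
#' @param ppiNoiseEdges random background PPI edges.
#' @param catalogueExtra non-regulator miRNAs added to the catalogue.
#' @param hazardRatio per-SD hazard ratio of the survival miRNA.
#' @param survivalMirnaIndex planted miRNA whose expression drives survival.
#' @param baseMedianDays baseline median survival (days).
#' @param censorLo,censorHi uniform censoring window (days).
#' @return a named list of settings for [simulateTriOmics()].
#' @export
simConfig <- function(nGenes = 1000, nMirnas = 100, nProteins = 60,
                      nTumor = 120, nNormal = 10,
                      nModules = 3, genesPerModule = 20,
                      samplesPerModule = 38, proteinsPerModule = 1,
                      mirnasPerModule = 2, expansionGenesPerModule = 5,
                      moduleProteinGenes = 10,
                      nDeGenes = 240, deShift = 3,
                      factorMean = 4.5, factorSd = 0.5, factorLoading = 0.5,
                      proteinFactorLoading = 0.6,
                      proteinUniqueLoading = 0.75,
                      geneProteinLoading = 0.5,
                      mirnaFactorLoading = 0.5, mirnaUniqueLoading = 0.8,
                      geneMirnaLoading = 0.45,
                      mirnaDirection = c("repressor", "activator"),
                      expansionBoost = 1.15,
                      concordanceMean = 0.25, concordanceSd = 0.2,
                      concordanceModule = 0.65,
                      targetsPerMirna = 8, decoyTargets = 20,
                      ppiNoiseEdges = 300, catalogueExtra = 4,
                      hazardRatio = 2, survivalMirnaIndex = 1,
                      baseMedianDays = 400, censorLo = 100,
                      censorHi = 1500) {
  cfg <- as.list(environment())
  cfg$mirnaDirection <- match.arg(mirnaDirection)
  stopifnot(
    nGenes > 0, nMirnas > 0, nProteins > 0, nTumor > 0, nNormal >= 0,
    nModules >= 0, genesPerModule >= 1, samplesPerModule >= 2,
    concordanceMean >= -1, concordanceMean <= 1, hazardRatio > 0)
  if (nModules > 0) {
    if (nModules * genesPerModule > nDeGenes || nDeGenes > nGenes)
      stop("infeasible config: module/DE genes exceed the matrix")
    if (nModules * samplesPerModule > nTumor)
      stop("infeasible config: module samples exceed the tumor cohort")
    if (nModules * proteinsPerModule +
        nModules * moduleProteinGenes > nProteins)
      stop("infeasible config: planted proteins exceed the protein layer")
    if (nModules * mirnasPerModule > nMirnas)
      stop("infeasible config: planted miRNAs exceed the miRNA layer")
  }
  cfg
}

.trunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a coupled synthetic multi-omics dataset
#'
#' See the model sketch in the file header and the methods vignette. All
#' outputs are reproducible per seed (one RNG stream, restored on exit).
#'
#' @param config list from [simConfig()].
#' @param seed integer seed.
#' @return list with `mrna`, `mirna`, `protein` ([ExpressionLayer-class];
#'   protein ids are platform ids `P_<gene>`), `proteinMapping` (named
#'   vector), `ppi` ([PPINetwork-class]), `tables` (named list of the four
#'   interaction tables), `geneSets`, `clinical`, `catalogue`, and `truth`
#'   (class `SyntheticTruth`: planted memberships, regulatory edges,
#'   concordance targets, hazard settings, config and seed).
#' @export
simulateTriOmics <- function(config = simConfig(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cf <- config
  genes <- sprintf("g%04d", seq_len(cf$nGenes))
  mirnas <- sprintf("sim-miR-%03d", seq_len(cf$nMirnas))
  tumor <- sprintf("T%03d", seq_len(cf$nTumor))
  normal <- if (cf$nNormal) sprintf("N%02d", seq_len(cf$nNormal)) else character()
  samples <- c(tumor, normal)
  cls <- stats::setNames(rep(c("tumor", "normal"),
                             c(cf$nTumor, cf$nNormal)), samples)
  nM <- cf$nModules
  dirs <- if (nM) rep_len(c(1, -1), nM) else numeric()
  mirSign <- if (cf$mirnaDirection == "repressor") -1 else 1

  ## ---- planted memberships (deterministic index blocks) ----
  modGenes <- lapply(seq_len(nM), function(k)
    genes[((k - 1) * cf$genesPerModule + 1):(k * cf$genesPerModule)])
  expBase <- cf$nDeGenes
  expGenes <- lapply(seq_len(nM), function(k)
    genes[(expBase + (k - 1) * cf$expansionGenesPerModule + 1):
          (expBase + k * cf$expansionGenesPerModule)])
  regBase <- expBase + nM * cf$expansionGenesPerModule
  regGenes <- lapply(seq_len(nM), function(k)
    genes[(regBase + (k - 1) * cf$proteinsPerModule + 1):
          (regBase + k * cf$proteinsPerModule)])
  modSamples <- lapply(seq_len(nM), function(k)
    tumor[((k - 1) * cf$samplesPerModule + 1):(k * cf$samplesPerModule)])
  modMirnas <- lapply(seq_len(nM), function(k)
    mirnas[((k - 1) * cf$mirnasPerModule + 1):(k * cf$mirnasPerModule)])
  plantedMirnas <- unlist(modMirnas)

  ## ---- mRNA layer ----
  mrna <- matrix(stats::rnorm(cf$nGenes * length(samples)), cf$nGenes,
                 dimnames = list(genes, samples))
  deGenes <- genes[seq_len(min(cf$nDeGenes, cf$nGenes))]
  deSign <- stats::setNames(sample(c(-1, 1), length(deGenes), TRUE), deGenes)
  for (k in seq_len(nM)) deSign[modGenes[[k]]] <- dirs[k]
  mrna[deGenes, tumor] <- mrna[deGenes, tumor] + deSign * cf$deShift

  latents <- lapply(seq_len(nM), function(k) {
    ns <- cf$samplesPerModule
    list(f = stats::rnorm(ns, cf$factorMean, cf$factorSd),
         v = matrix(stats::rnorm(ns * cf$proteinsPerModule), ns),
         u = matrix(stats::rnorm(ns * cf$mirnasPerModule), ns))
  })
  geneLoadVar <- cf$factorLoading^2 +
    cf$proteinsPerModule * cf$geneProteinLoading^2 +
    cf$mirnasPerModule * cf$geneMirnaLoading^2
  geneNoiseSd <- sqrt(max(1 - geneLoadVar, 0.05))
  for (k in seq_len(nM)) {
    L <- latents[[k]]
    sig <- cf$factorLoading * L$f +
      L$v %*% rep(cf$geneProteinLoading, cf$proteinsPerModule) +
      L$u %*% rep(cf$geneMirnaLoading, cf$mirnasPerModule)
    sig <- as.numeric(sig)
    for (g in modGenes[[k]])
      mrna[g, modSamples[[k]]] <- deSign[g] * cf$deShift + dirs[k] * sig +
        geneNoiseSd * stats::rnorm(cf$samplesPerModule)
    ## expansion genes: boosted signature, no DE shift
    bsig <- cf$expansionBoost * sig
    bNoise <- sqrt(max(1 - cf$expansionBoost^2 * geneLoadVar, 0.03))
    for (g in expGenes[[k]])
      mrna[g, modSamples[[k]]] <- dirs[k] * bsig +
        bNoise * stats::rnorm(cf$samplesPerModule)
  }

  ## ---- miRNA layer ----
  mir <- matrix(stats::rnorm(cf$nMirnas * length(samples)), cf$nMirnas,
                dimnames = list(mirnas, samples))
  mirNoiseSd <- sqrt(max(1 - cf$mirnaFactorLoading^2 -
                           cf$mirnaUniqueLoading^2, 0.05))
  for (k in seq_len(nM)) {
    L <- latents[[k]]
    for (j in seq_len(cf$mirnasPerModule)) {
      mi <- modMirnas[[k]][j]
      mir[mi, modSamples[[k]]] <-
        mirSign * dirs[k] * (cf$mirnaFactorLoading * L$f +
                               cf$mirnaUniqueLoading * L$u[, j]) +
        mirNoiseSd * stats::rnorm(cf$samplesPerModule)
    }
  }

  ## ---- protein layer (tumor samples only) ----
  modProtGenes <- lapply(seq_len(nM), function(k)
    modGenes[[k]][seq_len(min(cf$moduleProteinGenes, length(modGenes[[k]])))])
  nRegProt <- nM * cf$proteinsPerModule
  nModProt <- length(unlist(modProtGenes))
  nBgProt <- cf$nProteins - nRegProt - nModProt
  bgPool <- setdiff(deGenes, unlist(modGenes))
  if (nM == 0) bgPool <- genes
  bgProtGenes <- sample(bgPool, min(nBgProt, length(bgPool)))
  protGenes <- c(unlist(regGenes), unlist(modProtGenes), bgProtGenes)

  ## truncation bounds widen to admit extreme configured targets (e.g. a
  ## deterministic concordance of exactly 1)
  conc <- stats::setNames(
    .trunc_norm(length(protGenes), cf$concordanceMean, cf$concordanceSd,
                min(-0.3, cf$concordanceMean), max(0.9, cf$concordanceMean)),
    protGenes)
  conc[unlist(modProtGenes)] <- cf$concordanceModule
  conc[unlist(regGenes)] <- NA_real_  # regulators are factor-driven

  zTumor <- function(g) {
    x <- mrna[g, tumor]
    (x - mean(x)) / stats::sd(x)
  }
  prot <- matrix(NA_real_, length(protGenes), cf$nTumor,
                 dimnames = list(protGenes, tumor))
  protNoiseSd <- sqrt(max(1 - cf$proteinFactorLoading^2 -
                            cf$proteinUniqueLoading^2, 0.05))
  for (k in seq_len(nM)) {
    L <- latents[[k]]
    for (j in seq_len(cf$proteinsPerModule)) {
      g <- regGenes[[k]][j]
      row <- stats::rnorm(cf$nTumor)
      row[match(modSamples[[k]], tumor)] <-
        dirs[k] * (cf$proteinFactorLoading * L$f +
                     cf$proteinUniqueLoading * L$v[, j]) +
        protNoiseSd * stats::rnorm(cf$samplesPerModule)
      prot[g, ] <- row
    }
  }
  for (g in c(unlist(modProtGenes), bgProtGenes))
    prot[g, ] <- conc[g] * zTumor(g) +
      sqrt(1 - conc[g]^2) * stats::rnorm(cf$nTumor)
  rownames(prot) <- paste0("P_", protGenes)
  proteinMapping <- stats::setNames(protGenes, rownames(prot))

  ## ---- PPI network ----
  ppiEdges <- NULL
  for (k in seq_len(nM)) {
    mg <- modGenes[[k]]
    ring <- cbind(mg, mg[c(2:length(mg), 1)])
    hooks <- do.call(rbind, lapply(expGenes[[k]], function(e)
      cbind(e, sample(mg, 2))))
    ppiEdges <- rbind(ppiEdges, ring, hooks)
  }
  noise <- cbind(sample(genes, cf$ppiNoiseEdges, TRUE),
                 sample(genes, cf$ppiNoiseEdges, TRUE))
  ppi <- PPINetwork(as.data.frame(rbind(ppiEdges, noise),
                                  stringsAsFactors = FALSE))

  ## ---- interaction tables ----
  edge <- function(source, target, effect)
    data.frame(source = source, target = target, effect = effect,
               stringsAsFactors = FALSE)
  mirnaGene <- NULL; mirnaTf <- NULL; tfGene <- NULL; tfMirna <- NULL
  tfs <- vapply(regGenes, `[[`, character(1), 1L)  # one TF per module
  for (k in seq_len(nM)) {
    for (mi in modMirnas[[k]]) {
      tg <- modGenes[[k]][seq_len(min(cf$targetsPerMirna,
                                      length(modGenes[[k]])))]
      decoys <- sample(setdiff(genes, unlist(modGenes)), cf$decoyTargets)
      mirnaGene <- rbind(mirnaGene,
                         edge(mi, c(tg, decoys), "negative"))
      mirnaTf <- rbind(mirnaTf, edge(mi, tfs[k], "negative"))
      tfMirna <- rbind(tfMirna, edge(tfs[k], mi, "positive"))
    }
    tfTargets <- c(modGenes[[k]][seq_len(min(12, length(modGenes[[k]])))],
                   sample(setdiff(genes, unlist(modGenes)), 10))
    tfGene <- rbind(tfGene, edge(tfs[k], tfTargets, "positive"))
  }
  bgMirnas <- setdiff(mirnas, plantedMirnas)
  for (mi in utils::head(bgMirnas, min(30, length(bgMirnas))))
    mirnaGene <- rbind(mirnaGene,
                       edge(mi, sample(genes, 10), "unknown"))
  fixRole <- function(df, role) {
    if (is.null(df))
      df <- data.frame(source = character(), target = character(),
                       effect = character(), stringsAsFactors = FALSE)
    df <- df[!duplicated(df[c("source", "target")]), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "role") <- role
    df
  }
  tables <- list(mirnaGene = fixRole(mirnaGene, "mirna_gene"),
                 mirnaTf = fixRole(mirnaTf, "mirna_tf"),
                 tfGene = fixRole(tfGene, "tf_gene"),
                 tfMirna = fixRole(tfMirna, "tf_mirna"))

  ## ---- gene sets ----
  geneSets <- list()
  for (k in seq_len(nM))
    geneSets[[sprintf("PW_module%02d", k)]] <-
      c(modGenes[[k]], expGenes[[k]])
  for (j in seq_len(10))
    geneSets[[sprintf("PW_random%02d", j)]] <- sample(genes, 15)
  attr(geneSets, "source") <- "synthetic"

  ## ---- catalogue ----
  catalogue <- c(plantedMirnas,
                 sample(bgMirnas, min(cf$catalogueExtra, length(bgMirnas))))

  ## ---- clinical (tumor cohort) ----
  survMirna <- if (length(plantedMirnas))
    plantedMirnas[min(cf$survivalMirnaIndex, length(plantedMirnas))]
  else mirnas[1]
  expr <- mir[survMirna, tumor]
  rate <- log(2) / cf$baseMedianDays * cf$hazardRatio^expr
  death <- stats::rexp(cf$nTumor, rate)
  cens <- stats::runif(cf$nTumor, cf$censorLo, cf$censorHi)
  clinical <- data.frame(sample = tumor,
                         time = round(pmin(death, cens), 1),
                         event = death <= cens, stringsAsFactors = FALSE)

  truth <- structure(list(
    modules = lapply(seq_len(nM), function(k) list(
      genes = modGenes[[k]], samples = modSamples[[k]],
      expansion_genes = expGenes[[k]],
      regulator_proteins = paste0("P_", regGenes[[k]]),
      regulator_protein_genes = regGenes[[k]],
      protein_measured_genes = modProtGenes[[k]],
      mirnas = modMirnas[[k]], direction = dirs[k], tf = tfs[k])),
    planted_mirnas = plantedMirnas,
    de_genes = deGenes,
    background_protein_genes = bgProtGenes,
    concordance_targets = as.list(conc[!is.na(conc)]),
    survival = list(mirna = survMirna, hazard_ratio = cf$hazardRatio),
    config = cf, seed = seed), class = "SyntheticTruth")

  list(mrna = ExpressionLayer(mrna, "mrna", sampleClass = cls),
       mirna = ExpressionLayer(mir, "mirna", sampleClass = cls),
       protein = ExpressionLayer(prot, "protein",
                                 sampleClass = cls[tumor]),
       proteinMapping = proteinMapping, ppi = ppi, tables = tables,
       geneSets = geneSets, clinical = clinical, catalogue = catalogue,
       truth = truth)
}

#' Serialise / restore a SyntheticTruth
#'
#' JSON round-trip is lossless for the planted memberships, edges, targets
#' and configuration.
#'
#' @param truth a `SyntheticTruth` (from [simulateTriOmics()]).
#' @param path file path.
#' @return `path` invisibly / the restored `SyntheticTruth`.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
            class = "SyntheticTruth")
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (!u) return(0)
  length(intersect(a, b)) / u
}

#' Recovery metrics against the planted ground truth
#'
#' Compares pipeline output with a `SyntheticTruth`: per planted module the
#' best row/column Jaccard over the recovered modules (core mRNAs and
#' samples), regulator-protein and repressor-miRNA recovery, and the AUC of
#' the influence ranking against the planted-regulator labels.
#'
#' @param truth a `SyntheticTruth`.
#' @param modules optional list of [TriFactorModule-class] (or
#'   [Bicluster-class]) objects.
#' @param ranking optional [InfluenceRanking-class].
#' @return list of metrics; entries not computable from the supplied pieces
#'   are omitted.
#' @export
truthMetrics <- function(truth, modules = NULL, ranking = NULL) {
  out <- list()
  if (!is.null(modules) && length(truth$modules)) {
    rowsOf <- function(m) if (is(m, "TriFactorModule")) m@mrnaCore
                          else biclusterRows(m)
    colsOf <- function(m) if (is(m, "TriFactorModule")) m@sampleIds
                          else biclusterCols(m)
    per <- lapply(truth$modules, function(tm) {
      if (!length(modules)) return(list(row = 0, col = 0, best = NA))
      jr <- vapply(modules, function(m) .jaccard(rowsOf(m), tm$genes),
                   numeric(1))
      best <- which.max(jr)
      list(row = jr[best],
           col = .jaccard(colsOf(modules[[best]]), tm$samples),
           best = best)
    })
    out$row_jaccard <- mean(vapply(per, `[[`, numeric(1), "row"))
    out$col_jaccard <- mean(vapply(per, `[[`, numeric(1), "col"))
    if (all(vapply(modules, is, logical(1), "TriFactorModule"))) {
      inclMirnas <- unique(unlist(lapply(modules, function(m) m@mirnaIds)))
      out$mirna_recall <-
        length(intersect(inclMirnas, truth$planted_mirnas)) /
        length(truth$planted_mirnas)
      inclProts <- unique(unlist(lapply(modules, function(m) m@proteinIds)))
      out$regulator_protein_hit <- mean(vapply(seq_along(truth$modules),
        function(k) {
          tm <- truth$modules[[k]]
          any(tm$regulator_protein_genes %in% inclProts |
                tm$regulator_proteins %in% inclProts)
        }, logical(1)))
      bgProt <- truth$background_protein_genes
      out$noise_protein_exclusion <- if (length(bgProt))
        1 - length(intersect(inclProts,
                             c(bgProt, paste0("P_", bgProt)))) /
          length(bgProt) else NA_real_
    }
  }
  if (!is.null(ranking) && length(truth$planted_mirnas)) {
    tb <- rankingTable(ranking)
    out$planted_rank_positions <-
      stats::setNames(match(truth$planted_mirnas, tb$mirna),
                      truth$planted_mirnas)
    out$ranking_auc <- rocAuc(ranking, truth$planted_mirnas)$auc
  }
  out
}
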