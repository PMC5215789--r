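## End-to-end orchestration: load (or simulate) the inputs, run the
## requested stages, and write TSV/JSON outputs plus a reproducibility
## manifest. All randomness flows from the single `seed` parameter, so a
## run is byte-identical given the same config and seed.

.config_error <- function(msg)
  stop(structure(class = c("configError", "error", "condition"),
                 list(message = msg, call = NULL)))
.data_error <- function(msg)
  stop(structure(class = c("dataError", "error", "condition"),
                 list(message = msg, call = NULL)))

#' Default pipeline configuration
#'
#' @param out output directory.
#' @param simulate use the built-in synthetic generator instead of input
#'   files (`inputs` ignored then).
#' @param inputs named list of input paths: `mrna`, `sampleClass`, `mirna`,
#'   `protein`, `proteinMapping`, `ppi`, `mirnaGene`, `mirnaTf`, `tfGene`,
#'   `tfMirna`, `geneSets`, `clinical`, `catalogue`.
#' @param alpha vector of top-alpha% thresholds to rank at (in percent).
#' @param beta,gamma protein/miRNA candidate percentiles.
#' @param minMrnas,overlapFactor,nPerm module-discovery settings.
#' @param deLevel,deCorrection DE-selection settings.
#' @param permLevel,permCorrection permutation-filter settings.
#' @param method correlation method for the ranking matrices.
#' @param topPct top percentage for the catalogue fraction.
#' @param xPct survival stratification percentage.
#' @param seed integer seed.
#' @param sim optional [simConfig()] overrides (named list) when simulating.
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(out = "triomics_run", simulate = TRUE,
                           inputs = list(), alpha = c(1, 5), beta = 3,
                           gamma = 3, minMrnas = 10, overlapFactor = 0.1,
                           nPerm = 1000, deLevel = 0.05,
                           deCorrection = "bonferroni", permLevel = 0.05,
                           permCorrection = "bonferroni",
                           method = "spearman", topPct = 10, xPct = 50,
                           seed = 1, sim = list()) {
  as.list(environment())
}

.load_config <- function(path) {
  if (!file.exists(path)) .config_error(paste("config file not found:", path))
  cfg <- yaml::read_yaml(path)
  base <- pipelineConfig()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

.check_config <- function(cfg) {
  ok <- all(cfg$alpha > 0 & cfg$alpha <= 100) && cfg$beta > 0 &&
    cfg$gamma > 0 && cfg$minMrnas >= 2 && cfg$overlapFactor >= 0 &&
    cfg$overlapFactor <= 1 && cfg$nPerm >= 1 && cfg$xPct <= 50 &&
    cfg$method %in% c("spearman", "pearson")
  if (!ok) .config_error("pipeline parameters out of range")
  if (!isTRUE(cfg$simulate)) {
    need <- c("mrna", "sampleClass", "mirna", "protein", "proteinMapping",
              "ppi")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      .config_error(paste("missing input paths:",
                          paste(miss, collapse = ", ")))
    gone <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(gone))
      .data_error(paste("input file(s) not found:",
                        paste(gone, collapse = ", ")))
  }
  invisible(cfg)
}

.load_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    sc <- do.call(simConfig, cfg$sim)
    sim <- simulateTriOmics(sc, seed = cfg$seed)
    return(sim)
  }
  ins <- cfg$inputs
  sim <- list(
    mrna = readExpressionMatrix(ins$mrna, "mrna", ins$sampleClass),
    mirna = readExpressionMatrix(ins$mirna, "mirna", ins$sampleClass),
    protein = readExpressionMatrix(ins$protein, "protein"),
    proteinMapping = readFeatureMapping(ins$proteinMapping),
    ppi = readPPINetwork(ins$ppi),
    tables = list(
      mirnaGene = if (!is.null(ins$mirnaGene))
        readInteractionTable(ins$mirnaGene, "mirna_gene"),
      mirnaTf = if (!is.null(ins$mirnaTf))
        readInteractionTable(ins$mirnaTf, "mirna_tf"),
      tfGene = if (!is.null(ins$tfGene))
        readInteractionTable(ins$tfGene, "tf_gene"),
      tfMirna = if (!is.null(ins$tfMirna))
        readInteractionTable(ins$tfMirna, "tf_mirna")),
    geneSets = if (!is.null(ins$geneSets)) readGeneSets(ins$geneSets),
    clinical = if (!is.null(ins$clinical)) readClinicalTable(ins$clinical),
    catalogue = if (!is.null(ins$catalogue)) readCatalogue(ins$catalogue),
    truth = NULL)
  sim
}

#' Write a simulated dataset to flat files
#'
#' Emits exactly the formats the readers consume (expression TSVs, sample
#' classes, mapping, PPI and interaction edge lists, GMT, clinical TSV,
#' catalogue list) plus the ground truth as JSON.
#'
#' @param sim result of [simulateTriOmics()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeExpressionMatrix(sim$mrna, p("mrna.tsv"))
  writeExpressionMatrix(sim$mirna, p("mirna.tsv"))
  writeExpressionMatrix(sim$protein, p("protein.tsv"))
  cls <- sampleClass(sim$mrna)
  utils::write.table(data.frame(sample = names(cls), class = unname(cls)),
                     p("sample_class.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = names(sim$proteinMapping),
               gene_symbol = unname(sim$proteinMapping)),
    p("protein_mapping.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ppi@edges, p("ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tabFiles <- c(mirnaGene = "mirna_gene.tsv", mirnaTf = "mirna_tf.tsv",
                tfGene = "tf_gene.tsv", tfMirna = "tf_mirna.tsv")
  for (nm in names(tabFiles))
    utils::write.table(sim$tables[[nm]], p(tabFiles[[nm]]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  gmt <- vapply(names(sim$geneSets), function(nm)
    paste(c(nm, "synthetic", sim$geneSets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, p("gene_sets.gmt"))
  utils::write.table(
    data.frame(sample = sim$clinical$sample,
               time_days = sim$clinical$time,
               event = as.integer(sim$clinical$event)),
    p("clinical.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$catalogue, p("catalogue.txt"))
  writeTruthJson(sim$truth, p("truth.json"))
  invisible(vapply(list.files(dir, full.names = TRUE), identity,
                   character(1)))
}

.shared_tumor_samples <- function(sim) {
  cls <- sampleClass(sim$mrna)
  tumor <- names(cls)[cls %in% "tumor"]
  sort(Reduce(intersect, list(tumor, colnames(sim$mirna),
                              colnames(sim$protein))))
}

#' Run the pipeline
#'
#' Executes the requested stages on either input files or the built-in
#' synthetic dataset and writes their outputs under `config$out`:
#' ranking TSVs (one per alpha), the concordance-group table, module JSON
#' and TSV, validation TSVs, evaluation/survival TSVs, recovery metrics
#' (when ground truth is available), and a manifest with input checksums,
#' parameters, seed and package version.
#'
#' @param config list from [pipelineConfig()] (or a YAML path).
#' @param stages subset of `c("rank", "modules", "validate", "evaluate",
#'   "survival")`.
#' @return (invisibly) list with the in-memory results: `rankings`,
#'   `modules`, `validation`, `evaluation`, `metrics`, `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("rank", "modules", "validate",
                                   "evaluate", "survival")) {
  if (is.character(config)) config <- .load_config(config)
  .check_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out, f)
  sim <- .load_inputs(config)

  ## ---- preprocessing shared by all stages ----
  de <- differentialFeatures(sim$mrna, level = config$deLevel,
                             correction = config$deCorrection)
  deIds <- de$feature_id[de$selected]
  if (!length(deIds)) .data_error("no differentially expressed mRNAs")
  protMapped <- mapProteinFeatures(sim$protein, sim$proteinMapping)
  shared <- .shared_tumor_samples(sim)
  if (length(shared) < 3L) .data_error("too few shared tumor samples")
  mrnaT <- sim$mrna[, shared]
  mirnaT <- sim$mirna[, shared]
  protT <- protMapped[, shared]
  common <- commonGenes(deIds, protT)

  res <- list(outDir = config$out)
  rankings <- list()

  if ("rank" %in% stages) {
    cm <- correlationMatrix(mrnaT[common, ], mirnaT, method = config$method)
    cp <- correlationMatrix(protT[common, ], mirnaT, method = config$method)
    for (a in config$alpha) {
      sc <- influenceScores(cm, cp, a)
      r <- rankMirnas(sc, a)
      rankings[[as.character(a)]] <- r
      writeRankingTsv(r, p(sprintf("ranking_alpha%g.tsv", a)),
                      catalogue = sim$catalogue)
    }
    conc <- concordanceGroups(mrnaT[common, ], protT[common, ])
    utils::write.table(conc, p("concordance_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$rankings <- rankings
    res$concordance <- conc
  }

  mods <- list()
  if (any(c("modules", "validate") %in% stages)) {
    z <- zscoreRows(exprsMatrix(mrnaT)[intersect(deIds, rownames(mrnaT)), ,
                                       drop = FALSE])
    mods <- buildModules(z, mrnaT, protT, mirnaT, sim$ppi,
                         minMrnas = config$minMrnas,
                         overlapFactor = config$overlapFactor,
                         nPerm = config$nPerm, level = config$permLevel,
                         correction = config$permCorrection,
                         betaPct = config$beta, gammaPct = config$gamma,
                         seed = config$seed)
    writeModulesJson(mods, p("modules.json"))
    writeModulesTsv(mods, p("modules.tsv"))
    res$modules <- mods
  }

  if ("validate" %in% stages && length(mods)) {
    tb <- sim$tables
    measured <- rownames(sim$mrna)
    val <- list()
    if (!is.null(sim$geneSets))
      val$pathway <- do.call(rbind, lapply(mods, function(m)
        pathwayEnrichment(moduleGenes(m), sim$geneSets, measured,
                          moduleId = m@id)))
    if (!is.null(tb$mirnaGene)) {
      uni <- intersect(unique(tb$mirnaGene$target), measured)
      val$direct <- do.call(rbind, lapply(mods, function(m)
        directRegulationTest(m, tb$mirnaGene, uni)))
    }
    if (!is.null(tb$mirnaTf) && !is.null(tb$tfGene)) {
      uni <- intersect(unique(tb$tfGene$target), measured)
      val$indirect <- do.call(rbind, lapply(mods, function(m)
        indirectRegulationTest(m, tb$mirnaTf, tb$tfGene, uni)))
    }
    if (!is.null(tb$tfMirna) && !is.null(tb$tfGene)) {
      uni <- intersect(unique(tb$tfGene$target), measured)
      val$coreg <- do.call(rbind, lapply(mods, function(m)
        coregulationTest(m, tb$tfMirna, tb$tfGene, uni)))
    }
    for (nm in names(val))
      if (!is.null(val[[nm]]))
        utils::write.table(val[[nm]], p(sprintf("validation_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    res$validation <- val
  }

  if ("evaluate" %in% stages && !is.null(sim$catalogue) &&
      length(rankings)) {
    ev <- do.call(rbind, lapply(names(rankings), function(a) {
      r <- rankings[[a]]
      roc <- rocAuc(r, sim$catalogue)
      data.frame(alpha = as.numeric(a),
                 topk_known_fraction = topkKnownFraction(
                   r, sim$catalogue, topPct = config$topPct),
                 auc = roc$auc)
    }))
    utils::write.table(ev, p("evaluation.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$evaluation <- ev
  }

  if ("survival" %in% stages && !is.null(sim$clinical) &&
      length(rankings)) {
    r1 <- rankings[[1]]
    topN <- max(1L, floor(nrow(rankingTable(r1)) * config$topPct / 100))
    topMirnas <- rankingTable(r1)$mirna[seq_len(topN)]
    mx <- exprsMatrix(sim$mirna)
    sv <- do.call(rbind, lapply(topMirnas, function(mi) {
      expr <- mx[mi, intersect(colnames(mx), sim$clinical$sample)]
      grp <- survivalStratify(expr, sim$clinical, xPct = config$xPct)
      k <- kmLogrank(grp, sim$clinical, mirnaId = mi)
      data.frame(mirna = mi, n_top = k$n_top, n_bottom = k$n_bottom,
                 statistic = k$statistic, p_value = k$p_value)
    }))
    utils::write.table(sv, p("survival.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$survival <- sv
  }

  if (!is.null(sim$truth)) {
    met <- truthMetrics(sim$truth,
                        modules = if (length(mods)) mods,
                        ranking = if (length(rankings)) rankings[[
                          length(rankings)]])
    met$planted_rank_positions <- as.list(met$planted_rank_positions)
    jsonlite::write_json(met, p("recovery_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$metrics <- met
  }

  manifest <- list(
    package = "miRTriOmics",
    version = as.character(utils::packageVersion("miRTriOmics")),
    seed = config$seed,
    stages = stages,
    parameters = config[c("alpha", "beta", "gamma", "minMrnas",
                          "overlapFactor", "nPerm", "deLevel",
                          "deCorrection", "permLevel", "permCorrection",
                          "method", "topPct", "xPct")],
    inputs = if (isTRUE(config$simulate)) "simulated"
             else as.list(tools::md5sum(unlist(config$inputs))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
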