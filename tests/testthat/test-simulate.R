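test_that("the generator is reproducible and validates its configuration", {
  cf <- simConfig(nGenes = 120, nMirnas = 20, nProteins = 20, nTumor = 40,
                  nNormal = 4, nModules = 1, genesPerModule = 8,
                  samplesPerModule = 12, moduleProteinGenes = 4,
                  nDeGenes = 30, expansionGenesPerModule = 2)
  s1 <- simulateTriOmics(cf, seed = 5)
  s2 <- simulateTriOmics(cf, seed = 5)
  expect_identical(exprsMatrix(s1$mrna), exprsMatrix(s2$mrna))
  expect_identical(exprsMatrix(s1$protein), exprsMatrix(s2$protein))
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateTriOmics(cf, seed = 6)
  expect_false(identical(exprsMatrix(s1$mrna), exprsMatrix(s3$mrna)))

  ## infeasible configurations are rejected up front
  expect_error(simConfig(nGenes = 50, nDeGenes = 60), "infeasible")
  expect_error(simConfig(nTumor = 20, nModules = 2, samplesPerModule = 15),
               "infeasible")
  expect_error(simConfig(nMirnas = 3, nModules = 2, mirnasPerModule = 2),
               "infeasible")
})

test_that("planted members exist in the emitted matrices and tables", {
  sim <- simulateTriOmics(simConfig(), seed = 2)
  tr <- sim$truth
  for (tm in tr$modules) {
    expect_true(all(tm$genes %in% rownames(sim$mrna)))
    expect_true(all(tm$samples %in% colnames(sim$mrna)))
    expect_true(all(tm$mirnas %in% rownames(sim$mirna)))
    expect_true(all(tm$regulator_proteins %in% rownames(sim$protein)))
    expect_true(all(tm$expansion_genes %in% rownames(sim$mrna)))
  }
  edges <- sim$tables$mirnaGene
  expect_true(all(edges$source %in% rownames(sim$mirna)))
  expect_true(all(edges$target %in% rownames(sim$mrna)))
  expect_true(all(sim$catalogue %in% rownames(sim$mirna)))
  ## truth serialisation round-trips losslessly
  path <- tempfile(fileext = ".json")
  writeTruthJson(tr, path)
  back <- readTruthJson(path)
  expect_equal(back$modules, tr$modules)
  expect_equal(back$planted_mirnas, tr$planted_mirnas)
  expect_equal(back$concordance_targets, tr$concordance_targets)
})

test_that("a deterministic concordance of one gives perfect rank correlation", {
  cf <- simConfig(nModules = 0, nGenes = 60, nMirnas = 5, nProteins = 20,
                  nTumor = 30, nNormal = 2, nDeGenes = 30,
                  concordanceMean = 1, concordanceSd = 0)
  sim <- simulateTriOmics(cf, seed = 3)
  pm <- suppressMessages(mapProteinFeatures(sim$protein, sim$proteinMapping))
  genes <- rownames(pm)
  sccs <- vapply(genes, function(g)
    cor(exprsMatrix(sim$mrna)[g, colnames(pm)], exprsMatrix(pm)[g, ],
        method = "spearman"), numeric(1))
  expect_true(all(sccs == 1))
})

test_that("the configured mean mRNA-protein concordance is recovered", {
  cf <- simConfig(nModules = 0, nGenes = 400, nMirnas = 5, nProteins = 200,
                  nTumor = 150, nNormal = 2, nDeGenes = 50,
                  concordanceMean = 0.25)
  sim <- simulateTriOmics(cf, seed = 4)
  pm <- suppressMessages(mapProteinFeatures(sim$protein, sim$proteinMapping))
  sccs <- vapply(rownames(pm), function(g)
    cor(exprsMatrix(sim$mrna)[g, colnames(pm)], exprsMatrix(pm)[g, ],
        method = "spearman"), numeric(1))
  expect_lt(abs(mean(sccs) - 0.25), 0.05)
})

test_that("planted repressors outscore background miRNAs and drive survival", {
  aucs <- numeric(3)
  for (s in 1:3) {
    sim <- simulateTriOmics(simConfig(), seed = 200 + s)
    de <- differentialFeatures(sim$mrna)
    pm <- suppressMessages(mapProteinFeatures(sim$protein,
                                              sim$proteinMapping))
    shared <- sort(intersect(
      names(sampleClass(sim$mrna))[sampleClass(sim$mrna) == "tumor"],
      colnames(pm)))
    common <- commonGenes(de$feature_id[de$selected], pm)
    cm <- correlationMatrix(sim$mrna[common, shared],
                            sim$mirna[, shared])
    cp <- correlationMatrix(pm[common, shared], sim$mirna[, shared])
    r <- rankMirnas(influenceScores(cm, cp, 5), 5)
    aucs[s] <- truthMetrics(sim$truth, ranking = r)$ranking_auc
    tb <- rankingTable(r)
    planted <- tb$score[tb$mirna %in% sim$truth$planted_mirnas]
    background <- tb$score[!tb$mirna %in% sim$truth$planted_mirnas]
    expect_gt(mean(planted), mean(background))
  }
  expect_gt(mean(aucs), 0.9)

  ## survival: the high-expression group of the hazard-driving miRNA dies
  ## sooner (hazard ratio 2 by construction)
  sim <- simulateTriOmics(simConfig(), seed = 204)
  expr <- exprsMatrix(sim$mirna)[sim$truth$survival$mirna,
                                 sim$clinical$sample]
  gr <- survivalStratify(expr, sim$clinical, xPct = 50)
  medianOf <- function(ids) median(sim$clinical$time[
    match(ids, sim$clinical$sample)])
  expect_lt(medianOf(gr$top), medianOf(gr$bottom))
})

test_that("recovery metrics agree with closed-form Jaccard cases", {
  sim <- simulateTriOmics(simConfig(nGenes = 120, nMirnas = 20,
                                    nProteins = 20, nTumor = 40,
                                    nNormal = 4, nModules = 1,
                                    genesPerModule = 8,
                                    samplesPerModule = 12,
                                    moduleProteinGenes = 4, nDeGenes = 30,
                                    expansionGenesPerModule = 2), seed = 9)
  tm <- sim$truth$modules[[1]]
  exact <- new("Bicluster", rows = tm$genes, cols = tm$samples, score = 1)
  met <- truthMetrics(sim$truth, modules = list(exact))
  expect_equal(met$row_jaccard, 1)
  expect_equal(met$col_jaccard, 1)
  ## empty recovery
  met0 <- truthMetrics(sim$truth, modules = list())
  expect_equal(met0$row_jaccard, 0)
  ## closed-form overlap {a,b,c} vs {b,c,d} -> 0.5
  half <- new("Bicluster", rows = c(tm$genes[-1], "gZZZZ"),
              cols = tm$samples, score = 1)
  metH <- truthMetrics(sim$truth, modules = list(half))
  expect_equal(metH$row_jaccard,
               length(intersect(half@rows, tm$genes)) /
                 length(union(half@rows, tm$genes)))
})
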