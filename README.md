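# miRTriOmics

Cancer-related miRNA prioritisation and regulatory-module discovery from
matched **mRNA, protein, and miRNA** expression profiles.

miRNAs repress their target genes, but the repression is only partly
visible in mRNA levels — translation is regulated too, and mRNA–protein
correlations in tumor cohorts are notoriously weak. `miRTriOmics`
therefore demands that a miRNA's footprint appear in *both* expression
layers:

* **Influence-score ranking.** Build gene × miRNA rank-correlation
  matrices for the mRNA and the protein layer over the shared tumor
  samples, threshold each at its own top-α% absolute correlation
  (α = 1 and 5 by default), and score each miRNA by

  `score(m) = #{ g : |r_mRNA(g,m)| ≥ t_mRNA  and  |r_prot(g,m)| ≥ t_prot }`

  miRNAs are ranked by descending score; the count of genes that pass the
  double threshold is the miRNA's *influence score*.

* **Three-factor modules.** SAMBA-style biclustering of the z-scored,
  differentially expressed tumor mRNA matrix; a permutation test (1000
  random modules of equal dimensions, Bonferroni-filtered) keeps only
  coherent biclusters; PPI neighbours are added while the average pairwise
  correlation keeps rising; proteins (top β% = 3% by mean |SCC|) and then
  miRNAs (top γ% = 3% against mRNAs *and* proteins) are added greedily as
  parents of the module mRNAs in a linear-Gaussian Bayesian network,
  each accepted only if the network BIC strictly increases.

* **Evaluation.** Catalogue recovery (top-k fraction, ROC/AUC),
  expression-stratified Kaplan–Meier survival comparison (log-rank), and
  hypergeometric validation of modules: pathway enrichment plus direct,
  TF-mediated indirect, and TF co-regulation tests with BH q-values.

A synthetic-data generator with planted three-layer modules and a
serialised ground truth (`simulateTriOmics()`, `truthMetrics()`) makes the
entire pipeline testable without any external download. The methods
vignette (`vignettes/miRTriOmics-methods.Rmd`) documents the model, every
tunable parameter, and the design decisions.

## Worked example

On a synthetic cohort (1000 genes, 100 miRNAs, 60 proteins, 120 tumor +
10 normal samples, three planted modules):

```r
library(miRTriOmics)

sim <- simulateTriOmics(simConfig(), seed = 42)
sim$mrna
#> ExpressionLayer [mrna]: 1000 features x 130 samples
#>   sample classes: 120 tumor, 10 normal

de  <- differentialFeatures(sim$mrna)          # Welch t, Bonferroni < 0.05
sum(de$selected)
#> [1] 237
pm  <- mapProteinFeatures(sim$protein, sim$proteinMapping)
cls <- sampleClass(sim$mrna)
shared <- sort(intersect(names(cls)[cls == "tumor"], colnames(pm)))
common <- commonGenes(de$feature_id[de$selected], pm)
length(common)
#> [1] 56

cm <- correlationMatrix(sim$mrna[common, shared], sim$mirna[, shared])
cp <- correlationMatrix(pm[common, shared],       sim$mirna[, shared])
r  <- rankMirnas(influenceScores(cm, cp, 5), 5)
r
#> InfluenceRanking: 100 miRNAs, alpha = 5%
#>   rank       mirna score
#> 1    1 sim-miR-005    18
#> 2    2 sim-miR-003    17
#> 3    3 sim-miR-004    17
#> 4    4 sim-miR-002    16
#> 5    5 sim-miR-001    15
```

The six planted repressor miRNAs occupy the top six ranks: 15–18 of the 56
common genes pass both correlation thresholds for each of them, while
background miRNAs score near zero. Against the bundled disease catalogue
(the planted regulators plus a few decoy entries, mimicking an imperfect
curation):

```r
rocAuc(r, sim$catalogue)$auc
#> [1] 0.8227778
topkKnownFraction(r, sim$catalogue, topPct = 10)
#> [1] 0.6

z    <- zscoreRows(exprsMatrix(sim$mrna[, shared])[
          intersect(de$feature_id[de$selected], rownames(sim$mrna)), ])
mods <- buildModules(z, sim$mrna[, shared], pm[, shared],
                     sim$mirna[, shared], sim$ppi, seed = 42)
mods[[1]]
#> TriFactorModule M01: 25 mRNAs (20 core + 5 PPI), 37 samples, 1 proteins, 2 miRNAs
#>   bicluster permutation p = 0
```

Module `M01` recovered one planted module exactly: its 20 core mRNAs, the
5 coherent non-DE genes reachable only through the PPI step, the planted
regulator protein, and both planted repressor miRNAs.
`truthMetrics(sim$truth, modules = mods, ranking = r)` confirms row/column
Jaccard 1.0/0.93 against the planted biclusters, miRNA recall 1.0, and
ranking AUC 1.0 versus the planted-regulator labels.

`runPipeline(pipelineConfig(out = "run", seed = 42))` performs all of the
above plus validation, evaluation and survival testing in one call,
writing ranking TSVs, module JSON/TSV, validation tables and a
reproducibility manifest; the shipped CLI
(`inst/cli/mirtriomics.R` — subcommands `simulate`, `rank`, `modules`,
`validate`, `evaluate`, `survival`, `run`) is a thin wrapper around the
same functions for shell use.

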