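## Shared fixtures, all built in code.

## small expression layer with named dims
toyLayer <- function(values, layer = "mrna", sampleClass = NULL) {
  ExpressionLayer(values, layer, sampleClass = sampleClass)
}

namedMatrix <- function(nr, nc, data = rnorm(nr * nc), rowPrefix = "g",
                        colPrefix = "s") {
  matrix(data, nr, nc,
         dimnames = list(sprintf("%s%03d", rowPrefix, seq_len(nr)),
                         sprintf("%s%03d", colPrefix, seq_len(nc))))
}

## tumor/normal layer: first nTumor columns tumor, rest normal
classedLayer <- function(values, nTumor) {
  cls <- stats::setNames(rep(c("tumor", "normal"),
                             c(nTumor, ncol(values) - nTumor)),
                         colnames(values))
  ExpressionLayer(values, "mrna", sampleClass = cls)
}

## a bare module over given genes/samples
toyModule <- function(genes, samples, proteins = character(),
                      mirnas = character(), id = "T01") {
  new("TriFactorModule", id = id, mrnaCore = genes,
      mrnaAdded = character(), sampleIds = samples,
      proteinIds = proteins, mirnaIds = mirnas,
      avgPccTrace = numeric(), bicTraceProteins = numeric(),
      bicTraceMirnas = numeric(), permutationP = NA_real_)
}

## exhaustive hypergeometric upper tail via combinatorial sums -- the
## independent oracle for stats::phyper-based code
hyperOracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## exhaustive best-subset search over parent candidates under the network
## BIC -- the independent oracle for the greedy inclusion
bestSubsetBic <- function(children, pool, candidates) {
  best <- character()
  bestScore <- gaussianBnBic(children, NULL)
  idx <- seq_along(candidates)
  for (sz in seq_along(candidates)) {
    for (comb in utils::combn(idx, sz, simplify = FALSE)) {
      sc <- suppressWarnings(
        gaussianBnBic(children, pool[candidates[comb], , drop = FALSE]))
      if (!is.na(sc) && sc > bestScore) {
        bestScore <- sc
        best <- candidates[comb]
      }
    }
  }
  sort(best)
}

## write a small TSV expression file and return its path
writeToyTsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
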