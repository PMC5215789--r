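## SAMBA-style bicluster discovery on the z-scored DE mRNA matrix, plus the
## permutation significance test for discovered modules.
##
## The original SAMBA hashed bipartite-graph search is not reproduced
## bit-exactly; the reference backend keeps its core idea -- heavy subgraphs
## of a binarised gene x sample bipartite graph, with overlap-controlled
## redundancy -- in a form that is deterministic and testable on planted
## data. The backend is pluggable: any function with the same signature
## (or biclusters imported via readBiclustersTsv()) can stand in.

.avg_pairwise_cor <- function(x) {
  ## x: samples x genes
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

## Greedy biclique growth on one signed binarised graph, followed by a
## consolidation phase on the signed z-values themselves: the binary graph
## is good at locating a coherent core, but at |z| >= zCut it keeps only
## the strongest cells, so the core is consolidated by requiring each
## member's mean signed z over the counterpart set to exceed a cut below
## the binarisation threshold. The row cut (0.7 zCut) is stricter than the
## column cut (0.25 zCut): z-scored rows see-saw, so a gene repressed inside
## its own sample block is mildly elevated (by roughly the block fraction)
## across every other sample subset and needs a large margin to exclude;
## background columns sit *below* zero, so a low cut suffices and keeps the
## weakly expressing tail of the member samples -- losing that tail
## range-restricts every downstream within-module correlation.
## B: logical genes x samples; Zs: signed z (same orientation as B);
## returns list of list(rows, cols, score).
.consolidate <- function(Zs, G, S, rowCut, colCut, maxIter) {
  for (iter in seq_len(maxIter)) {
    mg <- rowMeans(Zs[, S, drop = FALSE])
    Gnew <- which(mg >= rowCut)
    if (length(Gnew) < 2L) return(NULL)
    ms <- colMeans(Zs[Gnew, , drop = FALSE])
    Snew <- which(ms >= colCut)
    if (length(Snew) < 2L) return(NULL)
    stable <- identical(Gnew, G) && identical(Snew, S)
    G <- Gnew; S <- Snew
    if (stable) break
  }
  list(G = G, S = S)
}

.grow_bicliques <- function(B, Zs, minRows, maxSeeds, maxIter, inDensity,
                            rowCut, colCut) {
  p <- mean(B)
  p <- min(max(p, 0.01), 0.5)
  deg <- rowSums(B)
  ## deterministic, permutation-invariant seed order: degree desc, id asc
  seedIdx <- order(-deg, rownames(B))[seq_len(min(maxSeeds, nrow(B)))]
  out <- list()
  seen <- character()
  for (g0 in seedIdx) {
    S <- which(B[g0, ])
    if (length(S) < 2L) next
    pc <- inDensity
    G <- integer()
    for (iter in seq_len(maxIter)) {
      we <- log(pc / p); wn <- log((1 - pc) / (1 - p))
      cnt <- rowSums(B[, S, drop = FALSE])
      rowScore <- cnt * we + (length(S) - cnt) * wn
      Gnew <- which(rowScore > 0)
      if (length(Gnew) < 2L) { G <- integer(); break }
      cntS <- colSums(B[Gnew, , drop = FALSE])
      colScore <- cntS * we + (length(Gnew) - cntS) * wn
      Snew <- which(colScore > 0)
      if (length(Snew) < 2L) { G <- integer(); break }
      stable <- identical(Gnew, G) && identical(Snew, S)
      G <- Gnew; S <- Snew
      pc <- min(max(mean(B[G, S, drop = FALSE]), 0.5), 0.95)
      if (stable) break
    }
    if (length(G) < 2L || length(S) < 2L) next
    cons <- .consolidate(Zs, G, S, rowCut, colCut, maxIter)
    if (is.null(cons)) next
    G <- cons$G; S <- cons$S
    if (length(G) < minRows || length(S) < 2L) next
    key <- paste(paste(G, collapse = ","), paste(S, collapse = ","), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    we <- log(pc / p); wn <- log((1 - pc) / (1 - p))
    sub <- B[G, S, drop = FALSE]
    score <- sum(sub) * we + sum(!sub) * wn
    out[[length(out) + 1L]] <- list(rows = rownames(B)[G],
                                    cols = colnames(B)[S], score = score)
  }
  out
}

#' Discover mRNA x sample biclusters
#'
#' Reference SAMBA-style backend: z-scores are binarised at `|z| >= zCut`
#' into two signed gene-sample bipartite graphs (induced and repressed);
#' seed bicliques are grown greedily under a log-likelihood weight that
#' rewards edges and penalises non-edges (edge weight `log(pc/p)`, non-edge
#' `log((1-pc)/(1-p))`, with `p` the background edge density and `pc` the
#' in-bicluster density, re-estimated during refinement). Because the
#' binary graph only keeps cells beyond `zCut`, each converged core is then
#' consolidated on the signed z-values: members must have mean signed z
#' over the counterpart set of at least `0.75*zCut` (genes) or `0.25*zCut`
#' (samples). The row cut is stricter because z-scored rows see-saw (a gene
#' repressed in its own sample block is mildly elevated across every other
#' sample subset); background columns sit below zero, so the low column cut
#' safely keeps weakly expressing member samples. Candidates are
#' then sorted by score and filtered: a candidate is discarded when its row
#' overlap with an already accepted bicluster exceeds `1 - overlapFactor`
#' (`overlapFactor` 0 = full duplication allowed, 1 = no duplication), and
#' biclusters with fewer than `minMrnas` rows are dropped.
#'
#' @param m z-scored [ExpressionLayer-class] or numeric matrix.
#' @param minMrnas minimum number of mRNAs per reported bicluster.
#' @param overlapFactor redundancy control in `[0, 1]`, see above.
#' @param zCut binarisation threshold on the z-scores.
#' @param inDensity initial in-bicluster edge-density assumption.
#' @param maxSeeds maximum number of seed genes per signed graph.
#' @param maxIter refinement iterations per seed.
#' @param backend alternative backend `function(zmatrix, minMrnas, ...)`
#'   returning a list of [Bicluster-class]; the default is the reference
#'   implementation described above.
#' @return list of [Bicluster-class] objects, sorted by descending score.
#' @export
discoverBiclusters <- function(m, minMrnas = 10, overlapFactor = 0.1,
                               zCut = 1, inDensity = 0.7, maxSeeds = 300,
                               maxIter = 25, backend = NULL) {
  stopifnot(minMrnas >= 2, overlapFactor >= 0, overlapFactor <= 1)
  Z <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  if (!is.null(backend))
    return(backend(Z, minMrnas = minMrnas, overlapFactor = overlapFactor))
  if (nrow(Z) < 2L || ncol(Z) < 2L) return(list())
  Z[is.na(Z)] <- 0
  cand <- c(
    .grow_bicliques(Z >= zCut, Z, minMrnas, maxSeeds, maxIter, inDensity,
                    0.75 * zCut, 0.25 * zCut),
    .grow_bicliques(-Z >= zCut, -Z, minMrnas, maxSeeds, maxIter, inDensity,
                    0.75 * zCut, 0.25 * zCut)
  )
  if (!length(cand)) return(list())
  ord <- order(-vapply(cand, `[[`, numeric(1), "score"),
               vapply(cand, function(b) paste(sort(b$rows), collapse = ","),
                      character(1)))
  accepted <- list()
  for (b in cand[ord]) {
    dup <- any(vapply(accepted, function(a)
      length(intersect(b$rows, a@rows)) / length(b$rows) >
        (1 - overlapFactor), logical(1)))
    if (dup) next
    accepted[[length(accepted) + 1L]] <-
      new("Bicluster", rows = b$rows, cols = b$cols, score = b$score)
  }
  accepted
}

#' Permutation significance test of a bicluster
#'
#' The observed statistic is the mean Pearson correlation over all unordered
#' gene pairs of the module, restricted to the module samples. `nPerm`
#' random modules are built by drawing the same numbers of genes and samples
#' uniformly without replacement from the full normalised matrix, and
#' \deqn{p = \#\{i : \mathrm{random}_{avg}(i) > \mathrm{observed}_{avg}\}/N.}
#' The indicator is strictly `>`, as printed in the defining formula; set
#' `smooth = TRUE` for the (+1)/(N+1) variant.
#'
#' @param b a [Bicluster-class] (at least two genes).
#' @param m the normalised [ExpressionLayer-class] or matrix the module was
#'   discovered in.
#' @param nPerm number of random modules (default 1000).
#' @param seed optional integer seed; given a seed the result is exactly
#'   reproducible.
#' @param smooth add-one smoothing of the p-value (off by default).
#' @return list with `observed_avg`, `random_avgs`, `p_value`, `n_perm`.
#' @export
permutationTest <- function(b, m, nPerm = 1000, seed = NULL, smooth = FALSE) {
  stopifnot(nPerm >= 1)
  X <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  rows <- biclusterRows(b); cols <- biclusterCols(b)
  if (length(rows) < 2L) stop("module must contain at least two genes")
  stopifnot(all(rows %in% rownames(X)), all(cols %in% colnames(X)))
  observed <- .avg_pairwise_cor(t(X[rows, cols, drop = FALSE]))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ng <- length(rows); ns <- length(cols)
  rand <- vapply(seq_len(nPerm), function(i) {
    gi <- sample.int(nrow(X), ng)
    si <- sample.int(ncol(X), ns)
    .avg_pairwise_cor(t(X[gi, si, drop = FALSE]))
  }, numeric(1))
  p <- if (smooth) (sum(rand > observed) + 1) / (nPerm + 1)
       else sum(rand > observed) / nPerm
  list(observed_avg = observed, random_avgs = rand, p_value = p,
       n_perm = nPerm)
}

#' Filter modules by adjusted permutation p-value
#'
#' @param results list of [permutationTest()] results (or a numeric vector
#'   of raw p-values).
#' @param level significance level on the adjusted p (default 0.05; modules
#'   with adjusted p at or below the level are kept).
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`.
#' @return logical vector marking the kept modules, with the adjusted
#'   p-values in `attr(, "p_adjusted")`.
#' @export
selectSignificant <- function(results, level = 0.05,
                              correction = c("bonferroni", "BH", "none")) {
  correction <- match.arg(correction)
  p <- if (is.numeric(results)) results
       else vapply(results, `[[`, numeric(1), "p_value")
  padj <- stats::p.adjust(p, method = correction)
  keep <- padj <= level
  attr(keep, "p_adjusted") <- padj
  keep
}
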