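## From significant biclusters to three-factor modules: PPI-guided mRNA
## expansion, then greedy inclusion of proteins and miRNAs as parents of the
## module mRNAs in a fixed-structure linear-Gaussian Bayesian network scored
## by BIC.

#' Expand a module with PPI-correlated genes
#'
#' Candidates are PPI neighbours of the current module genes that are
#' present in the expression matrix and not yet members. Each candidate is
#' scored by its mean Pearson correlation with the current module mRNAs over
#' the module samples; candidates are tried in descending score order and a
#' candidate is accepted iff the module-wide average pairwise PCC after
#' inclusion strictly exceeds the value before. The loop stops at the first
#' rejection. The average-PCC trace is recorded on the module.
#'
#' @param mod a [TriFactorModule-class] (mRNA core and samples filled in).
#' @param ppi a [PPINetwork-class].
#' @param m full mRNA [ExpressionLayer-class] or matrix (candidate profiles
#'   are taken from here).
#' @return the expanded [TriFactorModule-class].
#' @export
expandWithPPI <- function(mod, ppi, m) {
  X <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  members <- c(mod@mrnaCore, mod@mrnaAdded)
  stopifnot(all(members %in% rownames(X)))
  cols <- mod@sampleIds
  cur <- t(X[members, cols, drop = FALSE])  # samples x genes
  avg <- .avg_pairwise_cor(cur)
  trace <- avg
  cand <- setdiff(intersect(ppiNeighbors(ppi, members), rownames(X)), members)
  if (length(cand)) {
    sc <- vapply(cand, function(g)
      mean(suppressWarnings(stats::cor(X[g, cols], cur,
                                       use = "pairwise.complete.obs")),
           na.rm = TRUE), numeric(1))
    cand <- cand[order(-sc, cand)]
    for (g in cand) {
      trial <- cbind(cur, X[g, cols])
      newAvg <- .avg_pairwise_cor(trial)
      if (is.na(newAvg) || newAvg <= avg) break
      cur <- trial
      colnames(cur)[ncol(cur)] <- g
      mod@mrnaAdded <- c(mod@mrnaAdded, g)
      avg <- newAvg
      trace <- c(trace, avg)
    }
  }
  mod@avgPccTrace <- trace
  mod
}

#' Linear-Gaussian Bayesian-network BIC score
#'
#' The network structure is a fixed bipartite graph: every parent (protein
#' or miRNA) points at every module mRNA, with no intra-layer edges. Under
#' that structure the score decomposes over children, and for each child the
#' local score is the BIC of a linear-Gaussian regression of the child on
#' all parents (maximum-likelihood variance; parameter count = number of
#' parents + intercept + variance). The score is oriented so that larger is
#' better: \eqn{\sum_i [\log \hat L_i - \frac{k}{2}\log n]}, i.e.
#' \eqn{-\mathrm{BIC}/2} in the `stats::BIC` convention.
#'
#' @param children numeric matrix, module mRNAs x samples.
#' @param parents numeric matrix, parents x samples (0-row matrix or `NULL`
#'   for the intercept-only baseline).
#' @return numeric(1) score, or `NA` with a warning when the parent design
#'   is singular (collinear parents).
#' @export
gaussianBnBic <- function(children, parents = NULL) {
  Y <- t(children)                      # samples x children
  n <- nrow(Y)
  np <- if (is.null(parents)) 0L else nrow(parents)
  if (n < np + 2L) stop("need at least (number of parents + 2) samples")
  X <- if (np) cbind(1, t(parents)) else matrix(1, n, 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("singular parent design (collinear parents)")
    return(NA_real_)
  }
  res <- qr.resid(qrX, Y)
  rss <- colSums(res^2)
  if (any(rss <= 0)) {
    warning("degenerate (zero-residual) child fit")
    return(NA_real_)
  }
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  k <- np + 2L
  sum(ll) - ncol(Y) * k / 2 * log(n)
}

## Greedy parent inclusion shared by addProteins()/addMirnas():
## candidates in the given order; accept iff the network BIC strictly
## increases; stop at the first non-increase; a singular candidate is
## skipped with a warning (it does not stop the loop).
.greedy_bic <- function(children, parentPool, baseParents, candidates) {
  parents <- baseParents
  score <- gaussianBnBic(children, if (nrow(parents)) parents else NULL)
  trace <- score
  accepted <- character()
  for (id in candidates) {
    trial <- rbind(parents, parentPool[id, , drop = FALSE])
    rownames(trial)[nrow(trial)] <- id
    newScore <- withCallingHandlers(
      gaussianBnBic(children, trial),
      warning = function(w) {
        if (grepl("singular", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.na(newScore)) {
      warning("candidate '", id, "' skipped: singular design")
      next
    }
    if (newScore <= score) break
    parents <- trial
    score <- newScore
    trace <- c(trace, score)
    accepted <- c(accepted, id)
  }
  list(accepted = accepted, trace = trace, parents = parents)
}

## mean |SCC| (or signed mean) of each row of `pool` against the rows of
## `ref`, over the given samples
.mean_scc <- function(pool, ref, cols, useAbs = TRUE) {
  cc <- suppressWarnings(stats::cor(t(pool[, cols, drop = FALSE]),
                                    t(ref[, cols, drop = FALSE]),
                                    method = "spearman",
                                    use = "pairwise.complete.obs"))
  if (useAbs) cc <- abs(cc)
  rowMeans(cc, na.rm = TRUE)
}

#' Add proteins to a module by greedy BIC
#'
#' Candidate proteins are those whose mean absolute Spearman correlation
#' with the module mRNAs (over the `scoreSamples` cohort) falls in the top
#' `betaPct` percent across all proteins. They are
#' tried in descending candidate score, each accepted iff the network BIC
#' ([gaussianBnBic()]) strictly increases; the loop stops at the first
#' non-increase. The BIC trace is recorded on the module.
#'
#' @param mod a [TriFactorModule-class].
#' @param prot protein [ExpressionLayer-class] (gene-symbol keyed).
#' @param m full mRNA [ExpressionLayer-class] or matrix with the module gene
#'   profiles.
#' @param betaPct candidate percentile in percent (default 3, i.e. top 3%).
#' @param useAbs score candidates by absolute correlation (default) or
#'   signed.
#' @param scoreSamples samples used for the candidate screen: `"shared"`
#'   (default, the whole cohort shared between the layers) or `"module"`.
#'   Screening cohort-wide exploits the module/non-module contrast that
#'   identifies a regulator; within a module-sized sample subset the
#'   mutually correlated module mRNAs make chance alignments of background
#'   features score as high as true regulators.
#' @param fitSamples samples used for the greedy BIC fit: `"module"`
#'   (default; the regulatory signal is concentrated there) or `"shared"`.
#' @return the updated [TriFactorModule-class].
#' @export
addProteins <- function(mod, prot, m, betaPct = 3, useAbs = TRUE,
                        scoreSamples = c("shared", "module"),
                        fitSamples = c("module", "shared")) {
  scoreSamples <- match.arg(scoreSamples)
  fitSamples <- match.arg(fitSamples)
  X <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  P <- if (is(prot, "ExpressionLayer")) exprsMatrix(prot) else prot
  shared <- intersect(colnames(X), colnames(P))
  modCols <- intersect(mod@sampleIds, shared)
  scCols <- if (scoreSamples == "shared") shared else modCols
  fitCols <- if (fitSamples == "shared") shared else modCols
  if (length(fitCols) < 3L || length(scCols) < 3L)
    stop("too few shared samples for the protein stage")
  genes <- c(mod@mrnaCore, mod@mrnaAdded)
  sc <- .mean_scc(P, X[genes, , drop = FALSE], scCols, useAbs = useAbs)
  if (all(is.na(sc))) {
    cand <- character()
  } else {
    thr <- stats::quantile(sc, 1 - betaPct / 100, type = 7, names = FALSE,
                           na.rm = TRUE)
    cand <- names(sc)[!is.na(sc) & sc >= thr]
    cand <- cand[order(-sc[cand], cand)]
  }
  children <- X[genes, fitCols, drop = FALSE]
  fit <- .greedy_bic(children, P[, fitCols, drop = FALSE],
                     matrix(0, 0, length(fitCols),
                            dimnames = list(NULL, fitCols)), cand)
  mod@proteinIds <- fit$accepted
  mod@bicTraceProteins <- fit$trace
  mod
}

#' Add miRNAs to a module by greedy BIC
#'
#' Candidate miRNAs are scored by their mean absolute Spearman correlation
#' with all module mRNAs \emph{and} proteins; the top `gammaPct` percent are
#' tried in descending score as additional parents (alongside the module's
#' proteins), with the same strict-increase BIC acceptance and stop-at-first
#' -rejection rule as [addProteins()].
#'
#' @param mod a [TriFactorModule-class] (proteins already added, possibly
#'   an empty set).
#' @param mirna miRNA [ExpressionLayer-class].
#' @param m full mRNA [ExpressionLayer-class] or matrix.
#' @param prot protein [ExpressionLayer-class] (for the candidate score and
#'   the parent profiles of the module proteins).
#' @param gammaPct candidate percentile in percent (default 3).
#' @param useAbs score candidates by absolute correlation (default). The
#'   absolute value matters here: repressive miRNAs correlate negatively and
#'   would otherwise never qualify.
#' @param scoreSamples,fitSamples see [addProteins()].
#' @return the updated [TriFactorModule-class].
#' @export
addMirnas <- function(mod, mirna, m, prot, gammaPct = 3, useAbs = TRUE,
                      scoreSamples = c("shared", "module"),
                      fitSamples = c("module", "shared")) {
  scoreSamples <- match.arg(scoreSamples)
  fitSamples <- match.arg(fitSamples)
  X <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  P <- if (is(prot, "ExpressionLayer")) exprsMatrix(prot) else prot
  M <- if (is(mirna, "ExpressionLayer")) exprsMatrix(mirna) else mirna
  shared <- Reduce(intersect, list(colnames(X), colnames(M), colnames(P)))
  modCols <- intersect(mod@sampleIds, shared)
  scCols <- if (scoreSamples == "shared") shared else modCols
  fitCols <- if (fitSamples == "shared") shared else modCols
  if (length(fitCols) < 3L || length(scCols) < 3L)
    stop("too few shared samples for the miRNA stage")
  genes <- c(mod@mrnaCore, mod@mrnaAdded)
  ref <- rbind(X[genes, , drop = FALSE][, scCols, drop = FALSE],
               P[mod@proteinIds, scCols, drop = FALSE])
  sc <- .mean_scc(M[, scCols, drop = FALSE], ref, scCols, useAbs = useAbs)
  if (all(is.na(sc))) {
    cand <- character()
  } else {
    thr <- stats::quantile(sc, 1 - gammaPct / 100, type = 7, names = FALSE,
                           na.rm = TRUE)
    cand <- names(sc)[!is.na(sc) & sc >= thr]
    cand <- cand[order(-sc[cand], cand)]
  }
  children <- X[genes, fitCols, drop = FALSE]
  base <- P[mod@proteinIds, fitCols, drop = FALSE]
  fit <- .greedy_bic(children, M[, fitCols, drop = FALSE], base, cand)
  mod@mirnaIds <- fit$accepted
  mod@bicTraceMirnas <- fit$trace
  mod
}

#' Build three-factor modules end to end
#'
#' Orchestrates the module stages: bicluster discovery on the z-scored DE
#' mRNA matrix, permutation-test filtering, PPI expansion, protein inclusion
#' and miRNA inclusion. Modules that end without at least one protein and
#' one miRNA are dropped when `requireThreeFactors = TRUE` (mirroring the
#' successive module counts of the staged construction).
#'
#' @param zMatrix z-scored DE mRNA matrix (genes x tumor samples) the
#'   biclusters are discovered in.
#' @param mrna,prot,mirna the raw expression layers (tumor samples aligned).
#' @param ppi a [PPINetwork-class].
#' @param minMrnas,overlapFactor passed to [discoverBiclusters()].
#' @param nPerm,level,correction permutation-test settings
#'   ([permutationTest()], [selectSignificant()]).
#' @param betaPct,gammaPct candidate percentiles for proteins and miRNAs.
#' @param seed integer seed for the permutation tests.
#' @param requireThreeFactors keep only modules with all three layers.
#' @return list of [TriFactorModule-class] objects.
#' @export
buildModules <- function(zMatrix, mrna, prot, mirna, ppi,
                         minMrnas = 10, overlapFactor = 0.1,
                         nPerm = 1000, level = 0.05,
                         correction = "bonferroni",
                         betaPct = 3, gammaPct = 3, seed = 1,
                         requireThreeFactors = TRUE) {
  bics <- discoverBiclusters(zMatrix, minMrnas = minMrnas,
                             overlapFactor = overlapFactor)
  if (!length(bics)) return(list())
  perms <- lapply(seq_along(bics), function(i)
    permutationTest(bics[[i]], zMatrix, nPerm = nPerm,
                    seed = seed + i - 1L))
  keep <- selectSignificant(perms, level = level, correction = correction)
  padj <- attr(keep, "p_adjusted")
  mods <- list()
  for (i in which(keep)) {
    mod <- new("TriFactorModule", id = sprintf("M%02d", length(mods) + 1L),
               mrnaCore = biclusterRows(bics[[i]]),
               mrnaAdded = character(), sampleIds = biclusterCols(bics[[i]]),
               proteinIds = character(), mirnaIds = character(),
               avgPccTrace = numeric(), bicTraceProteins = numeric(),
               bicTraceMirnas = numeric(), permutationP = padj[i])
    mod <- expandWithPPI(mod, ppi, mrna)
    mod <- addProteins(mod, prot, mrna, betaPct = betaPct)
    mod <- addMirnas(mod, mirna, mrna, prot, gammaPct = gammaPct)
    mods[[length(mods) + 1L]] <- mod
  }
  if (requireThreeFactors)
    mods <- Filter(function(m) length(m@proteinIds) > 0 &&
                     length(m@mirnaIds) > 0, mods)
  mods
}

#' Serialise modules to JSON
#'
#' One record per module: id, core and PPI-added mRNAs, samples, proteins,
#' miRNAs, the build traces and the permutation p-value.
#'
#' @param mods list of [TriFactorModule-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModulesJson <- function(mods, path) {
  rec <- lapply(mods, function(m) list(
    id = m@id, mrna_core = m@mrnaCore, mrna_added = m@mrnaAdded,
    samples = m@sampleIds, proteins = m@proteinIds, mirnas = m@mirnaIds,
    avg_pcc_trace = m@avgPccTrace, bic_trace_proteins = m@bicTraceProteins,
    bic_trace_mirnas = m@bicTraceMirnas, permutation_p = m@permutationP))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Flat TSV export of module membership
#'
#' Columns `module_id`, `member_type` (`mrna_core`/`mrna_added`/`protein`/
#' `mirna`/`sample`), `member_id`.
#'
#' @inheritParams writeModulesJson
#' @return `path`, invisibly.
#' @export
writeModulesTsv <- function(mods, path) {
  rows <- do.call(rbind, lapply(mods, function(m) {
    data.frame(
      module_id = m@id,
      member_type = rep(c("mrna_core", "mrna_added", "protein", "mirna",
                          "sample"),
                        c(length(m@mrnaCore), length(m@mrnaAdded),
                          length(m@proteinIds), length(m@mirnaIds),
                          length(m@sampleIds))),
      member_id = c(m@mrnaCore, m@mrnaAdded, m@proteinIds, m@mirnaIds,
                    m@sampleIds),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(module_id = character(), member_type = character(),
                       member_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
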