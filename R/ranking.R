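## Influence-score ranking: gene x miRNA correlation matrices for the mRNA
## and protein layers, per-matrix top-alpha% absolute-correlation thresholds,
## and the per-miRNA count of genes passing both thresholds.

#' Gene x miRNA correlation matrix
#'
#' Rank (Spearman, default) or Pearson correlation of every gene profile
#' with every miRNA profile across their shared, aligned samples. Missing
#' values are handled pairwise-complete; any gene/miRNA pair with fewer than
#' three complete sample pairs gets a missing entry (logged via a message).
#'
#' @param genes,mirnas [ExpressionLayer-class] objects with identical sample
#'   ids (see [alignLayers()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A [CorrelationMatrix-class] (genes in rows, miRNAs in columns).
#' @export
correlationMatrix <- function(genes, mirnas,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(identical(colnames(genes), colnames(mirnas)))
  if (ncol(genes) < 3L) stop("at least three shared samples required")
  gx <- t(exprsMatrix(genes)); mx <- t(exprsMatrix(mirnas))
  use <- if (anyNA(gx) || anyNA(mx)) "pairwise.complete.obs" else "everything"
  vals <- suppressWarnings(stats::cor(gx, mx, method = method, use = use))
  ## pairs with < 3 complete observations are not estimable
  npair <- crossprod(!is.na(gx), !is.na(mx))
  thin <- npair < 3L
  if (any(thin)) {
    vals[thin] <- NA_real_
    message(sum(thin), " gene-miRNA pair(s) with < 3 complete samples set to NA")
  }
  ## clamp float fuzz from the rank transform
  vals[!is.na(vals)] <- pmin(1, pmax(-1, vals[!is.na(vals)]))
  new("CorrelationMatrix", values = vals, method = method)
}

#' Top-alpha% absolute-correlation threshold
#'
#' Returns the threshold `t` such that an entry is "significant" iff
#' `|value| >= t`, where `t` is the `(100 - alpha)`-th percentile (linear
#' interpolation between order statistics, R type 7) of all non-missing
#' absolute values of this matrix. Each matrix gets its own threshold.
#'
#' @param c a [CorrelationMatrix-class].
#' @param alphaPct alpha in percent, `0 < alpha <= 100`.
#' @return numeric(1) threshold.
#' @export
topAlphaThreshold <- function(c, alphaPct) {
  stopifnot(alphaPct > 0, alphaPct <= 100)
  v <- abs(corValues(c))
  v <- v[!is.na(v)]
  if (!length(v)) stop("correlation matrix has no non-missing entries")
  stats::quantile(v, 1 - alphaPct / 100, type = 7, names = FALSE)
}

#' Influence scores from the dual-threshold count
#'
#' For each miRNA, counts the genes whose absolute correlation with the
#' miRNA reaches the top-alpha% threshold in \emph{both} the mRNA and the
#' protein correlation matrix. Missing entries never count.
#'
#' @param cMrna,cProt [CorrelationMatrix-class] objects over the same gene
#'   universe (identical row ids) and the same miRNAs (identical column ids).
#' @param alphaPct alpha in percent.
#' @return named integer vector of influence scores (one per miRNA), with
#'   the two thresholds in attributes `"thresholdMrna"`/`"thresholdProtein"`.
#' @export
influenceScores <- function(cMrna, cProt, alphaPct) {
  vm <- corValues(cMrna); vp <- corValues(cProt)
  if (!identical(colnames(vm), colnames(vp)))
    stop("miRNA sets of the two matrices differ")
  if (!identical(rownames(vm), rownames(vp)))
    stop("gene universes of the two matrices differ")
  tm <- topAlphaThreshold(cMrna, alphaPct)
  tp <- topAlphaThreshold(cProt, alphaPct)
  pass <- (!is.na(vm) & abs(vm) >= tm) & (!is.na(vp) & abs(vp) >= tp)
  scores <- colSums(pass)
  storage.mode(scores) <- "integer"
  attr(scores, "thresholdMrna") <- tm
  attr(scores, "thresholdProtein") <- tp
  scores
}

#' Rank miRNAs by influence score
#'
#' Descending by score; ties broken by miRNA id (stable lexicographic
#' order); ranks are consecutive 1..n.
#'
#' @param scores named numeric vector of influence scores.
#' @param alphaPct the alpha the scores were computed at (bookkeeping only).
#' @return An [InfluenceRanking-class].
#' @export
rankMirnas <- function(scores, alphaPct = NA_real_) {
  ord <- order(-scores, names(scores))
  tb <- data.frame(rank = seq_along(scores),
                   mirna = names(scores)[ord],
                   score = as.numeric(scores)[ord],
                   stringsAsFactors = FALSE)
  new("InfluenceRanking", table = tb, alpha = as.numeric(alphaPct))
}

#' Write a ranking as TSV (rank, mirna, score, in_catalogue)
#'
#' @param ranking an [InfluenceRanking-class].
#' @param path output path.
#' @param catalogue optional character vector of known disease miRNAs used
#'   to fill the `in_catalogue` column.
#' @return `path`, invisibly.
#' @export
writeRankingTsv <- function(ranking, path, catalogue = NULL) {
  tb <- rankingTable(ranking)
  tb$in_catalogue <- if (is.null(catalogue)) NA else tb$mirna %in% catalogue
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
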