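## Normalisation, differential-expression selection and the mRNA-protein
## concordance grouping that precede ranking and module discovery.

#' Z-score each feature across samples
#'
#' Centres and scales every row to mean 0 and sample standard deviation 1
#' over its non-missing entries. Rows with fewer than two non-missing values
#' or zero variance cannot be standardised; they are excluded with a warning
#' (ids recorded in the `"excluded"` attribute), never silently zeroed.
#'
#' @param m an [ExpressionLayer-class] or numeric matrix.
#' @return object of the same kind with standardised rows; excluded feature
#'   ids in `attr(, "excluded")`.
#' @export
zscoreRows <- function(m) {
  x <- if (is(m, "ExpressionLayer")) exprsMatrix(m) else m
  mu <- rowMeans(x, na.rm = TRUE)
  n <- rowSums(!is.na(x))
  sd <- sqrt(rowSums((x - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L))
  bad <- n < 2L | sd == 0 | !is.finite(sd)
  if (any(bad))
    warning(sum(bad), " constant/degenerate feature(s) excluded from z-scoring: ",
            paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
  z <- (x[!bad, , drop = FALSE] - mu[!bad]) / sd[!bad]
  out <- if (is(m, "ExpressionLayer"))
    ExpressionLayer(z, layerType(m), sampleClass = sampleClass(m))
  else z
  attr(out, "excluded") <- rownames(x)[bad]
  out
}

## Row-wise two-sample t statistics (Welch by default), closed form so the
## full matrix is tested in one pass; cross-checked against stats::t.test
## in the unit tests.
.row_ttest <- function(x1, x2, varEqual = FALSE) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / (n2 - 1L)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Select differentially expressed features between tumor and normal samples
#'
#' Two-sided two-sample t-test per feature (Welch by default; set
#' `varEqual = TRUE` for the pooled-variance variant), followed by multiple
#' testing correction. Under Bonferroni, `p_adjusted = min(1, p * n_features)`
#' and a feature is selected iff `p_adjusted < level`.
#'
#' @param m an [ExpressionLayer-class] whose `sampleClass` assigns at least
#'   two samples to each of tumor and normal.
#' @param level significance level on the adjusted p-value (default 0.05).
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`.
#' @param varEqual use the pooled-variance Student t-test instead of Welch.
#' @return data.frame with columns `feature_id`, `t_statistic`, `p_raw`,
#'   `p_adjusted`, `selected`.
#' @export
differentialFeatures <- function(m, level = 0.05,
                                 correction = c("bonferroni", "BH", "none"),
                                 varEqual = FALSE) {
  correction <- match.arg(correction)
  cls <- sampleClass(m)
  if (is.null(cls)) stop("sample classes are required for the DE test")
  tumor <- names(cls)[cls %in% "tumor"]
  normal <- names(cls)[cls %in% "normal"]
  if (length(tumor) < 2L || length(normal) < 2L)
    stop("each class needs at least two samples")
  x <- exprsMatrix(m)
  tt <- .row_ttest(x[, tumor, drop = FALSE], x[, normal, drop = FALSE],
                   varEqual = varEqual)
  padj <- stats::p.adjust(tt$p, method = correction)
  data.frame(feature_id = rownames(x), t_statistic = unname(tt$t),
             p_raw = unname(tt$p), p_adjusted = unname(padj),
             selected = unname(padj < level), stringsAsFactors = FALSE)
}

#' Genes measured in both the DE mRNA set and the protein layer
#'
#' @param deMrnaIds character vector of differentially expressed mRNA ids.
#' @param mappedProtein protein [ExpressionLayer-class] keyed by gene symbols
#'   (see [mapProteinFeatures()]).
#' @return sorted character vector of common genes.
#' @export
commonGenes <- function(deMrnaIds, mappedProtein) {
  shared <- sort(intersect(deMrnaIds, rownames(mappedProtein)))
  if (!length(shared))
    stop("no common genes between DE mRNAs and the protein layer")
  shared
}

#' mRNA-protein concordance grouping
#'
#' Computes the per-gene Spearman correlation between mRNA and protein
#' expression across shared samples and classifies genes into quartile
#' groups G1-G4 by the 25th/50th/75th percentiles of those correlations
#' (G1 at or below the 25th percentile, G4 above the 75th). Percentiles use
#' linear interpolation between order statistics; ties keep the stable
#' feature order.
#'
#' @param mrna,protein [ExpressionLayer-class] objects over the same genes
#'   and the same (aligned) samples.
#' @return data.frame `gene`, `scc`, `group` with the three percentile cut
#'   values in `attr(, "cuts")`.
#' @export
concordanceGroups <- function(mrna, protein) {
  stopifnot(identical(rownames(mrna), rownames(protein)),
            identical(colnames(mrna), colnames(protein)))
  if (ncol(mrna) < 3L) stop("at least three shared samples required")
  xm <- exprsMatrix(mrna); xp <- exprsMatrix(protein)
  scc <- vapply(seq_len(nrow(xm)), function(i)
    suppressWarnings(stats::cor(xm[i, ], xp[i, ], method = "spearman",
                                use = "pairwise.complete.obs")),
    numeric(1))
  cuts <- stats::quantile(scc, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          type = 7, names = FALSE)
  ## explicit comparisons instead of cut(): robust to tied (duplicate) cut
  ## values; G1 at or below the 25th percentile, G4 above the 75th
  idx <- 1L + (scc > cuts[1]) + (scc > cuts[2]) + (scc > cuts[3])
  out <- data.frame(gene = rownames(xm), scc = scc,
                    group = paste0("G", idx), stringsAsFactors = FALSE)
  attr(out, "cuts") <- cuts
  out
}
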