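## Evaluation of rankings against a disease-miRNA catalogue (top-k fraction,
## ROC/AUC) and expression-stratified survival comparison.

#' Fraction of catalogue miRNAs captured in the top of a ranking
#'
#' \eqn{|known \cap top_{\lfloor topPct\% \cdot n \rfloor}| / |known \cap
#' ranked|}: of the catalogue miRNAs present in the ranked universe, the
#' fraction found in the top `topPct` percent of ranks.
#'
#' @param r an [InfluenceRanking-class].
#' @param known character vector of catalogue miRNA ids.
#' @param topPct top percentage of the ranking (default 10).
#' @return numeric(1) fraction in `[0, 1]`.
#' @export
topkKnownFraction <- function(r, known, topPct = 10) {
  tb <- rankingTable(r)
  inUniverse <- intersect(known, tb$mirna)
  if (!length(inUniverse)) stop("catalogue has no miRNA in the ranking")
  k <- floor(nrow(tb) * topPct / 100)
  top <- tb$mirna[seq_len(k)]
  length(intersect(inUniverse, top)) / length(inUniverse)
}

#' ROC curve and AUC of a ranking against a catalogue
#'
#' Positives are ranked miRNAs present in the catalogue, negatives the rest.
#' Every score value is swept as a threshold (tied scores form a single
#' threshold step), giving cumulative TPR/FPR points from (0,0) to (1,1);
#' the AUC is the trapezoidal area, which on ties-free data equals the
#' Mann-Whitney probability that a positive outscores a negative.
#'
#' @param r an [InfluenceRanking-class].
#' @param known character vector of catalogue miRNA ids.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
rocAuc <- function(r, known) {
  tb <- rankingTable(r)
  labels <- tb$mirna %in% known
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present in the ranked universe")
  ## descending scores; collapse tied scores into one step
  ord <- order(-tb$score)
  lab <- labels[ord]
  sc <- tb$score[ord]
  stepEnd <- cumsum(table(factor(sc, levels = unique(sc))))
  tp <- cumsum(lab)[stepEnd]
  fp <- cumsum(!lab)[stepEnd]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
       auc = unname(auc))
}

#' Split a cohort into top-X% and bottom-X% expression groups
#'
#' Deterministic: ties in expression are broken by sample id, and
#' `xPct <= 50` guarantees disjoint groups. Samples missing from either
#' input are dropped first.
#'
#' @param expr named numeric vector, per-sample expression of one miRNA.
#' @param clin clinical data.frame ([readClinicalTable()]).
#' @param xPct percentage per group (default 50, a median split).
#' @return list with character vectors `top` and `bottom`.
#' @export
survivalStratify <- function(expr, clin, xPct = 50) {
  if (xPct > 50) stop("xPct > 50 would make the groups overlap")
  ids <- intersect(names(expr), clin$sample)
  if (!length(ids)) stop("no samples shared between expression and clinical data")
  e <- expr[ids]
  k <- floor(length(ids) * xPct / 100)
  if (k < 1L) stop("groups would be empty at this xPct")
  topOrd <- ids[order(-e, ids)]
  botOrd <- ids[order(e, ids)]
  list(top = topOrd[seq_len(k)], bottom = botOrd[seq_len(k)])
}

#' Kaplan-Meier comparison of two patient groups
#'
#' Fits per-group Kaplan-Meier curves and compares them with the two-sample
#' log-rank test (via [survival::survdiff()]). With no death event in
#' either group the statistic is undefined and is reported as `NA` with a
#' warning.
#'
#' @param groups list with `top` and `bottom` sample-id vectors
#'   ([survivalStratify()]).
#' @param clin clinical data.frame (`sample`, `time`, `event`).
#' @param mirnaId optional id recorded in the result.
#' @return list with `mirna_id`, `n_top`, `n_bottom`, `statistic` (log-rank
#'   chi-squared), `p_value`, and the [survival::survfit] object in `fit`.
#' @export
kmLogrank <- function(groups, clin, mirnaId = NA_character_) {
  ids <- c(groups$top, groups$bottom)
  stopifnot(!anyDuplicated(ids), length(groups$top) >= 2L,
            length(groups$bottom) >= 2L)
  df <- clin[match(ids, clin$sample), ]
  df$group <- rep(c("top", "bottom"), c(length(groups$top),
                                        length(groups$bottom)))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0L) {
    warning("no events in either group; log-rank statistic undefined")
    return(list(mirna_id = mirnaId, n_top = length(groups$top),
                n_bottom = length(groups$bottom), statistic = NA_real_,
                p_value = NA_real_, fit = fit))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(mirna_id = mirnaId, n_top = length(groups$top),
       n_bottom = length(groups$bottom), statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       fit = fit)
}
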