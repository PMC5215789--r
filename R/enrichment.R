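## Hypergeometric validation of modules: pathway enrichment plus the three
## regulatory-relationship tests (direct targeting, TF-mediated indirect
## regulation, TF co-regulation), each with Benjamini-Hochberg q-values
## within the module's family.

#' Upper-tail hypergeometric probability
#'
#' Exact \eqn{P(X \ge k)} for a hypergeometric draw: `N` objects of which
#' `K` are special, `n` drawn without replacement, `k` special observed.
#'
#' @param N universe size.
#' @param K category size.
#' @param n draw size.
#' @param k observed overlap.
#' @return numeric(1) p-value.
#' @export
hypergeomUpper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement, preserving input order.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order.
#' @export
bhAdjust <- function(pValues) {
  stopifnot(all(pValues >= 0 & pValues <= 1, na.rm = TRUE))
  stats::p.adjust(pValues, method = "BH")
}

.enrich_row <- function(moduleId, unitId, universe, category, drawn) {
  k <- length(intersect(category, drawn))
  data.frame(module_id = moduleId, unit_id = unitId,
             N = length(universe), K = length(category), n = length(drawn),
             k = k,
             p_value = hypergeomUpper(length(universe), length(category),
                                      length(drawn), k),
             overlap_members = paste(sort(intersect(category, drawn)),
                                     collapse = ","),
             stringsAsFactors = FALSE)
}

#' Pathway enrichment of a module's genes
#'
#' The module's mRNAs and proteins are pooled into one gene set and tested
#' against each pathway with a nonzero overlap; q-values are BH within the
#' module's family.
#'
#' @param moduleGenes character vector of the module's pooled gene symbols.
#' @param sets named list of gene sets ([readGeneSets()]).
#' @param universe gene universe (all genes measured on the mRNA platform
#'   is the usual choice).
#' @param moduleId id used in the output rows.
#' @return data.frame of enrichment rows (`module_id`, `unit_id`, `N`, `K`,
#'   `n`, `k`, `p_value`, `q_value`, `overlap_members`), or a zero-row frame
#'   when no set overlaps.
#' @export
pathwayEnrichment <- function(moduleGenes, sets, universe,
                              moduleId = "module") {
  if (!length(universe)) stop("empty universe")
  drawn <- intersect(moduleGenes, universe)
  rows <- lapply(names(sets), function(nm) {
    category <- intersect(sets[[nm]], universe)
    if (!length(intersect(category, drawn))) return(NULL)
    .enrich_row(moduleId, nm, universe, category, drawn)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_enrichment())
  out$q_value <- bhAdjust(out$p_value)
  out[c("module_id", "unit_id", "N", "K", "n", "k", "p_value", "q_value",
        "overlap_members")]
}

.empty_enrichment <- function() {
  data.frame(module_id = character(), unit_id = character(),
             N = integer(), K = integer(), n = integer(), k = integer(),
             p_value = numeric(), q_value = numeric(),
             overlap_members = character(), stringsAsFactors = FALSE)
}

## shared harness for the three regulatory tests: for each module miRNA,
## test the overlap of `targetSet(mirna)` with the module genes against the
## universe; BH within the module family.
.regulation_test <- function(mod, targetSets, universe, minOverlap = NULL) {
  genes <- intersect(moduleGenes(mod), universe)
  rows <- lapply(mod@mirnaIds, function(mi) {
    category <- intersect(targetSets(mi), universe)
    if (!length(category)) {
      message("miRNA ", mi, " has no catalogued targets; skipped")
      return(NULL)
    }
    .enrich_row(mod@id, mi, universe, category, genes)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_enrichment())
  out$q_value <- bhAdjust(out$p_value)
  out$enriched <- out$q_value < 0.05 &
    (if (is.null(minOverlap)) TRUE else out$k >= minOverlap)
  out[c("module_id", "unit_id", "N", "K", "n", "k", "p_value", "q_value",
        "enriched", "overlap_members")]
}

#' Direct miRNA-target enrichment within a module
#'
#' For each miRNA in the module, tests whether its experimentally validated
#' target genes overlap the module's genes more than chance. A result is
#' flagged `enriched` iff `q < 0.05` and at least `minOverlap` module genes
#' are targeted.
#'
#' @param mod a [TriFactorModule-class].
#' @param targets miRNA-to-gene interaction table ([readInteractionTable()]).
#' @param universe gene universe (typically genes in the table intersected
#'   with measured genes).
#' @param minOverlap minimum targeted module genes for the flag (default 3).
#' @return data.frame of enrichment rows with an `enriched` flag.
#' @export
directRegulationTest <- function(mod, targets, universe, minOverlap = 3) {
  .regulation_test(mod, function(mi) targets$target[targets$source == mi],
                   universe, minOverlap = minOverlap)
}

#' Indirect (miRNA -> TF -> gene) enrichment within a module
#'
#' For each module miRNA, the indirect target set is the union, over the
#' TFs the miRNA targets, of those TFs' target genes; no double counting.
#'
#' @param mod a [TriFactorModule-class].
#' @param mirnaTf miRNA-to-TF interaction table.
#' @param tfGene TF-to-gene interaction table.
#' @param universe gene universe.
#' @return data.frame of enrichment rows with an `enriched` flag
#'   (`q < 0.05`).
#' @export
indirectRegulationTest <- function(mod, mirnaTf, tfGene, universe) {
  .regulation_test(mod, function(mi) {
    tfs <- mirnaTf$target[mirnaTf$source == mi]
    unique(tfGene$target[tfGene$source %in% tfs])
  }, universe)
}

#' TF co-regulation enrichment within a module
#'
#' For each module miRNA, the co-regulated gene set is the union of the
#' target genes of the TFs that regulate this miRNA.
#'
#' @param mod a [TriFactorModule-class].
#' @param tfMirna TF-to-miRNA interaction table.
#' @param tfGene TF-to-gene interaction table.
#' @param universe gene universe.
#' @return data.frame of enrichment rows with an `enriched` flag
#'   (`q < 0.05`).
#' @export
coregulationTest <- function(mod, tfMirna, tfGene, universe) {
  .regulation_test(mod, function(mi) {
    tfs <- tfMirna$source[tfMirna$target == mi]
    unique(tfGene$target[tfGene$source %in% tfs])
  }, universe)
}
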