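#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.LAYERS <- c("mrna", "mirna", "protein")
.SAMPLE_CLASSES <- c("tumor", "normal")

#' ExpressionLayer: one omics layer of a multi-omics experiment
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single features x samples expression matrix (assay `"exprs"`), tagged with
#' the omics layer it represents (`"mrna"`, `"mirna"` or `"protein"`) and,
#' optionally, a tumor/normal class per sample in `colData(x)$sampleClass`.
#'
#' @slot layer character(1), one of `"mrna"`, `"mirna"`, `"protein"`.
#' @export
setClass("ExpressionLayer",
  contains = "SummarizedExperiment",
  representation(layer = "character")
)

setValidity("ExpressionLayer", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("layer must be one of: %s", paste(.LAYERS, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- colData(object)
  if ("sampleClass" %in% colnames(cd)) {
    cls <- as.character(cd$sampleClass)
    if (!all(is.na(cls) | cls %in% .SAMPLE_CLASSES))
      msg <- c(msg, "sampleClass values must be 'tumor' or 'normal'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionLayer
#'
#' @param values numeric matrix, features x samples, with row and column
#'   names. `NA` entries denote missing measurements.
#' @param layer one of `"mrna"`, `"mirna"`, `"protein"`.
#' @param sampleClass optional named character vector (names are sample ids)
#'   with values `"tumor"`/`"normal"`; samples absent from it get `NA`.
#' @return An [ExpressionLayer-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
#' ExpressionLayer(m, "mrna")
#' @export
ExpressionLayer <- function(values, layer, sampleClass = NULL) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(sampleClass)) {
    bad <- setdiff(names(sampleClass), colnames(values))
    if (length(bad))
      stop("sampleClass refers to unknown samples: ", paste(bad, collapse = ", "))
    cd$sampleClass <- unname(sampleClass[colnames(values)])
  }
  new("ExpressionLayer",
      SummarizedExperiment(assays = list(exprs = values), colData = cd),
      layer = layer)
}

#' CorrelationMatrix: gene x miRNA rank-correlation values
#'
#' @slot values numeric matrix (genes in rows, miRNAs in columns), entries in
#'   \eqn{[-1, 1]} or `NA` where fewer than three complete sample pairs were
#'   available.
#' @slot method `"spearman"` or `"pearson"`.
#' @export
setClass("CorrelationMatrix",
  representation(values = "matrix", method = "character")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have row and column names")
  fin <- v[!is.na(v)]
  if (length(fin) && (any(!is.finite(fin)) || any(fin < -1 - 1e-12) || any(fin > 1 + 1e-12)))
    msg <- c(msg, "correlation values must lie in [-1, 1]")
  if (!object@method %in% c("spearman", "pearson"))
    msg <- c(msg, "method must be 'spearman' or 'pearson'")
  if (length(msg)) msg else TRUE
})

#' InfluenceRanking: miRNAs ordered by influence score
#'
#' @slot table data.frame with columns `rank`, `mirna`, `score`, sorted by
#'   descending score with ties broken by miRNA id.
#' @slot alpha the top-alpha-percent correlation threshold (in percent) the
#'   scores were computed at.
#' @export
setClass("InfluenceRanking",
  representation(table = "data.frame", alpha = "numeric")
)

setValidity("InfluenceRanking", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("rank", "mirna", "score")
  if (!all(need %in% names(tb))) {
    msg <- c(msg, "table needs columns rank, mirna, score")
  } else {
    if (nrow(tb) && !identical(tb$rank, seq_len(nrow(tb))))
      msg <- c(msg, "ranks must be consecutive 1..n")
    if (is.unsorted(-tb$score))
      msg <- c(msg, "scores must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Bicluster: an mRNA x sample submatrix found by the bicluster search
#'
#' @slot rows character vector of mRNA ids.
#' @slot cols character vector of sample ids.
#' @slot score the bipartite log-likelihood weight of the bicluster.
#' @export
setClass("Bicluster",
  representation(rows = "character", cols = "character", score = "numeric")
)

setValidity("Bicluster", function(object) {
  msg <- character()
  if (length(object@rows) < 1L) msg <- c(msg, "at least one row required")
  if (length(object@cols) < 2L) msg <- c(msg, "at least two columns required")
  if (anyDuplicated(object@rows) || anyDuplicated(object@cols))
    msg <- c(msg, "duplicate members")
  if (length(msg)) msg else TRUE
})

#' PPINetwork: an undirected protein-protein interaction network
#'
#' Stored as a two-column edge table over gene symbols; self-loops and
#' duplicated (unordered) edges are invalid.
#'
#' @slot edges data.frame with character columns `a`, `b`.
#' @export
setClass("PPINetwork", representation(edges = "data.frame"))

setValidity("PPINetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("a", "b") %in% names(e))) {
    msg <- c(msg, "edges needs columns a, b")
  } else {
    if (any(e$a == e$b)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PPINetwork from an edge table
#'
#' @param edges data.frame whose first two columns are interacting gene
#'   symbols. Self-loops are dropped; duplicate undirected edges collapsed.
#' @return A [PPINetwork-class] object.
#' @export
PPINetwork <- function(edges) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi))
  new("PPINetwork", edges = data.frame(a = lo[!dup], b = hi[!dup],
                                       stringsAsFactors = FALSE))
}

#' TriFactorModule: an mRNA/protein/miRNA module with its build traces
#'
#' Records the evolving module through the build stages: the bicluster core
#' mRNAs, the PPI-added mRNAs (provenance kept separate), the sample subset,
#' and the proteins and miRNAs accepted by the greedy BIC search, together
#' with the average-PCC trace of the PPI expansion and the BIC traces of the
#' two inclusion stages.
#'
#' @slot id module identifier.
#' @slot mrnaCore mRNAs from the underlying bicluster.
#' @slot mrnaAdded mRNAs contributed by PPI expansion.
#' @slot sampleIds module samples.
#' @slot proteinIds accepted proteins.
#' @slot mirnaIds accepted miRNAs.
#' @slot avgPccTrace average pairwise PCC after each accepted PPI gene
#'   (first element is the pre-expansion value).
#' @slot bicTraceProteins,bicTraceMirnas network BIC score after each
#'   accepted parent (first element is the parent-free baseline).
#' @slot permutationP permutation-test p-value of the underlying bicluster.
#' @export
setClass("TriFactorModule",
  representation(id = "character", mrnaCore = "character",
                 mrnaAdded = "character", sampleIds = "character",
                 proteinIds = "character", mirnaIds = "character",
                 avgPccTrace = "numeric", bicTraceProteins = "numeric",
                 bicTraceMirnas = "numeric", permutationP = "numeric")
)

setValidity("TriFactorModule", function(object) {
  msg <- character()
  if (length(intersect(object@mrnaCore, object@mrnaAdded)))
    msg <- c(msg, "core and PPI-added mRNA sets must be disjoint")
  if (anyDuplicated(object@proteinIds) || anyDuplicated(object@mirnaIds))
    msg <- c(msg, "duplicate protein or miRNA members")
  for (tr in list(object@avgPccTrace, object@bicTraceProteins,
                  object@bicTraceMirnas))
    if (length(tr) > 1L && any(diff(tr) <= 0))
      msg <- c(msg, "traces must be strictly increasing")
  if (length(msg)) msg else TRUE
})
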