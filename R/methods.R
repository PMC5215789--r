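#' @rdname ExpressionLayer-class
#' @export
setMethod("layerType", "ExpressionLayer", function(x) x@layer)

#' @rdname ExpressionLayer-class
#' @export
setMethod("exprsMatrix", "ExpressionLayer", function(x) assay(x, "exprs"))

#' @rdname ExpressionLayer-class
#' @export
setMethod("sampleClass", "ExpressionLayer", function(x) {
  cd <- colData(x)
  if (!"sampleClass" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$sampleClass), rownames(cd))
})

setMethod("show", "ExpressionLayer", function(object) {
  cls <- sampleClass(object)
  cat(sprintf("ExpressionLayer [%s]: %d features x %d samples\n",
              object@layer, nrow(object), ncol(object)))
  if (!is.null(cls)) {
    tab <- table(factor(cls, levels = .SAMPLE_CLASSES))
    cat(sprintf("  sample classes: %d tumor, %d normal\n",
                tab[["tumor"]], tab[["normal"]]))
  }
  n <- sum(is.na(exprsMatrix(object)))
  if (n) cat(sprintf("  missing values: %d\n", n))
})

#' @rdname CorrelationMatrix-class
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

#' @rdname CorrelationMatrix-class
#' @export
setMethod("corMethod", "CorrelationMatrix", function(x) x@method)

setMethod("show", "CorrelationMatrix", function(object) {
  v <- object@values
  cat(sprintf("CorrelationMatrix (%s): %d genes x %d miRNAs, %d NA\n",
              object@method, nrow(v), ncol(v), sum(is.na(v))))
})

#' @rdname InfluenceRanking-class
#' @export
setMethod("rankingTable", "InfluenceRanking", function(x) x@table)

#' @rdname InfluenceRanking-class
#' @export
setMethod("rankingAlpha", "InfluenceRanking", function(x) x@alpha)

setMethod("show", "InfluenceRanking", function(object) {
  tb <- object@table
  cat(sprintf("InfluenceRanking: %d miRNAs, alpha = %g%%\n",
              nrow(tb), object@alpha))
  print(utils::head(tb, 5))
  if (nrow(tb) > 5) cat("  ...\n")
})

#' @rdname Bicluster-class
#' @export
setMethod("biclusterRows", "Bicluster", function(x) x@rows)

#' @rdname Bicluster-class
#' @export
setMethod("biclusterCols", "Bicluster", function(x) x@cols)

setMethod("show", "Bicluster", function(object) {
  cat(sprintf("Bicluster: %d mRNAs x %d samples, score %.2f\n",
              length(object@rows), length(object@cols), object@score))
})

#' @rdname PPINetwork-class
#' @export
setMethod("ppiNeighbors", "PPINetwork", function(x, node) {
  e <- x@edges
  sort(unique(c(e$b[e$a %in% node], e$a[e$b %in% node])))
})

setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork: %d edges over %d genes\n",
              nrow(object@edges),
              length(unique(c(object@edges$a, object@edges$b)))))
})

#' @rdname TriFactorModule-class
#' @export
setMethod("moduleGenes", "TriFactorModule",
          function(x) sort(unique(c(x@mrnaCore, x@mrnaAdded))))

setMethod("show", "TriFactorModule", function(object) {
  cat(sprintf(
    "TriFactorModule %s: %d mRNAs (%d core + %d PPI), %d samples, %d proteins, %d miRNAs\n",
    object@id, length(object@mrnaCore) + length(object@mrnaAdded),
    length(object@mrnaCore), length(object@mrnaAdded),
    length(object@sampleIds), length(object@proteinIds),
    length(object@mirnaIds)))
  if (length(object@permutationP) && !is.na(object@permutationP))
    cat(sprintf("  bicluster permutation p = %.4g\n", object@permutationP))
})
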