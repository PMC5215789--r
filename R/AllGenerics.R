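#' @rdname ExpressionLayer-class
#' @param x,object an object.
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname ExpressionLayer-class
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname ExpressionLayer-class
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))

#' @rdname TriFactorModule-class
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname PPINetwork-class
#' @param node a gene symbol.
#' @export
setGeneric("ppiNeighbors", function(x, node) standardGeneric("ppiNeighbors"))

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corMethod", function(x) standardGeneric("corMethod"))

#' @rdname InfluenceRanking-class
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname InfluenceRanking-class
#' @export
setGeneric("rankingAlpha", function(x) standardGeneric("rankingAlpha"))

#' @rdname Bicluster-class
#' @export
setGeneric("biclusterRows", function(x) standardGeneric("biclusterRows"))

#' @rdname Bicluster-class
#' @export
setGeneric("biclusterCols", function(x) standardGeneric("biclusterCols"))
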