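#' @rdname HeteroGraph-class
#' @param x a HeteroGraph or WeightedGraph
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname HeteroGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname HeteroGraph-class
#' @export
setGeneric("edgeTypes", function(x) standardGeneric("edgeTypes"))

#' @rdname HeteroGraph-class
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname HeteroGraph-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree",
  function(x, node, edgeType = NULL) standardGeneric("nodeDegree"))

#' @rdname neighborhoodSubgraph
#' @export
setGeneric("neighborhoodSubgraph",
  function(x, terminals, maxNodes = 1000L, maxDepth = 4L)
    standardGeneric("neighborhoodSubgraph"))

#' @rdname filterGraph
#' @export
setGeneric("filterGraph",
  function(x, dropNodeTypes = character(), dropEdgeTypes = character(),
           dropEdges = NULL)
    standardGeneric("filterGraph"))

#' @rdname saveEdgeList
#' @export
setGeneric("saveEdgeList",
  function(x, path, header = TRUE) standardGeneric("saveEdgeList"))

#' @rdname WeightedGraph-class
#' @param x a WeightedGraph
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
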