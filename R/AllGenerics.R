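#' Accessors for implinet containers
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a package object (\linkS4class{TrivalentMatrix},
#'   \linkS4class{BooleanNetwork} or \linkS4class{ClusteredBooleanNetwork}).
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("binNodes", function(x) standardGeneric("binNodes"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("geneClusters", function(x) standardGeneric("geneClusters"))

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
#' @export
setGeneric("clusterEdges", function(x) standardGeneric("clusterEdges"))

#' @rdname accessors
#' @export
setMethod("stateMatrix", "TrivalentMatrix", function(x) x@states)

#' @rdname accessors
#' @export
setMethod("geneIds", "TrivalentMatrix", function(x) rownames(x@states))

#' @rdname accessors
#' @export
setMethod("sampleIds", "TrivalentMatrix", function(x) colnames(x@states))

#' @rdname accessors
#' @export
setMethod("binNodes", "BooleanNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("binEdges", "BooleanNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("geneClusters", "ClusteredBooleanNetwork", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("representatives", "ClusteredBooleanNetwork",
          function(x) x@representatives)

#' @rdname accessors
#' @export
setMethod("clusterEdges", "ClusteredBooleanNetwork", function(x) x@edges)
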