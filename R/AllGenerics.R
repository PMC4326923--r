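#' @include AllClasses.R
NULL

#' @rdname rpkm
#' @export
setGeneric("rpkm", function(x, ...) standardGeneric("rpkm"))

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x, ...) standardGeneric("logTransform"))

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("ageWeeks", function(x) standardGeneric("ageWeeks"))

#' @rdname accessors
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))

#' @rdname accessors
#' @export
setGeneric("ageGroups", function(x) standardGeneric("ageGroups"))

#' @rdname FuzzyClustering-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname FuzzyClustering-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname FuzzyClustering-accessors
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))

#' @rdname FuzzyClustering-accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname FuzzyClustering-accessors
#' @export
setGeneric("validityTable", function(x) standardGeneric("validityTable"))

#' @rdname CorrelationNetwork-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname CorrelationNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CorrelationNetwork-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
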