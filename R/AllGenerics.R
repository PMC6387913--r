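#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes; see the class pages
#' for what each slot holds.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))

#' @rdname accessors
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname accessors
#' @export
setGeneric("splicingClass", function(x) standardGeneric("splicingClass"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))

#' @rdname accessors
#' @export
setGeneric("constantMarks", function(x) standardGeneric("constantMarks"))

#' @rdname accessors
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname accessors
#' @export
setGeneric("stabilityThreshold", function(x) standardGeneric("stabilityThreshold"))

#' @rdname accessors
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname accessors
#' @export
setGeneric("trueDag", function(x) standardGeneric("trueDag"))
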