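# Accessors and show methods.

#' @rdname accessors
#' @export
setMethod("marks", "ModificationMatrix", function(x) colnames(x@presence))

#' @rdname accessors
#' @export
setMethod("marks", "CorrelationMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("region", "ModificationMatrix", function(x) x@region)

#' @rdname accessors
#' @export
setMethod("splicingClass", "ModificationMatrix", function(x) x@splicingClass)

#' @export
setMethod("dim", "ModificationMatrix", function(x) dim(x@presence))

#' Extract the underlying matrix
#' @param x a [ModificationMatrix-class] or [CorrelationMatrix-class].
#' @param ... ignored.
#' @return the underlying numeric matrix.
#' @export
setMethod("as.matrix", "ModificationMatrix", function(x, ...) x@presence)

#' @rdname as.matrix-ModificationMatrix-method
#' @export
setMethod("as.matrix", "CorrelationMatrix", function(x, ...) x@values)

#' Subset a ModificationMatrix by samples and/or marks
#' @param x a [ModificationMatrix-class].
#' @param i sample (row) index. @param j mark (column) index.
#' @param ... ignored. @param drop ignored; subsetting keeps the class.
#' @export
setMethod("[", "ModificationMatrix", function(x, i, j, ..., drop = FALSE) {
  m <- x@presence
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  suppressWarnings(
    ModificationMatrix(m, region = x@region, splicingClass = x@splicingClass)
  )
})

#' @rdname accessors
#' @export
setMethod("nodes", "DAGStructure", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("nodes", "ConsensusNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edges", "DAGStructure", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edges", "ConsensusNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nEdges", "DAGStructure", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("nEdges", "ConsensusNetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("nEdges", "PatternReport", function(x) x@nEdges)

#' @rdname accessors
#' @export
setMethod("patterns", "PatternReport", function(x) x@patterns)

#' @rdname accessors
#' @export
setMethod("singletons", "PatternReport", function(x) x@singletons)

#' @rdname accessors
#' @export
setMethod("constantMarks", "CorrelationMatrix", function(x) x@constantMarks)

#' @rdname accessors
#' @export
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

#' @rdname accessors
#' @export
setMethod("stabilityThreshold", "ConsensusNetwork", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("pairCounts", "ConsensusNetwork", function(x) x@pairCounts)

#' @rdname accessors
#' @export
setMethod("trueDag", "PlantedScenario", function(x) x@dag)

setMethod("show", "ModificationMatrix", function(object) {
  cat(sprintf(
    "ModificationMatrix: %d samples x %d marks (region=%s, class=%s)\n",
    nrow(object@presence), ncol(object@presence),
    object@region, object@splicingClass))
  cat("  marks:", paste(utils::head(colnames(object@presence), 6),
                        collapse = ", "),
      if (ncol(object@presence) > 6) "..." else "", "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d marks, n = %d\n",
              nrow(object@values), object@nUsed))
  if (length(object@constantMarks)) {
    cat("  undefined (constant) marks:",
        paste(object@constantMarks, collapse = ", "), "\n")
  }
})

setMethod("show", "DAGStructure", function(object) {
  cat(sprintf("DAGStructure: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges)) {
    ex <- utils::head(object@edges, 5)
    cat(paste0("  ", ex$from, " -> ", ex$to, collapse = "\n"), "\n")
    if (nrow(object@edges) > 5) cat("  ...\n")
  }
})

setMethod("show", "LearnConfig", function(object) {
  cat(sprintf(
    "LearnConfig: score=%s (ess=%g), maxParents=%d, maxIterations=%d, restarts=%d\n",
    object@score, object@ess, object@maxParents, object@maxIterations,
    object@restarts))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d samples in %d folds (seed=%d); sizes %s\n",
              object@n, object@k, object@seed,
              paste(tabulate(object@assignments, object@k), collapse = "/")))
})

setMethod("show", "PlantedScenario", function(object) {
  cat(sprintf(
    "PlantedScenario: %d nodes, %d true edges, nSamples=%d, seed=%d\n",
    length(object@dag@nodes), nrow(object@dag@edges),
    object@nSamples, object@seed))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf(
    "ConsensusNetwork: %d nodes, %d edges (threshold %d of %d networks)\n",
    length(object@nodes), nrow(object@edges), object@threshold,
    object@nNetworks))
  if (nrow(object@edges)) {
    ex <- utils::head(object@edges, 5)
    cat(paste0("  ", ex$from, " -> ", ex$to, " [", ex$skeleton_count, "/",
               object@nNetworks, ", ", ex$correlation_sign, "]",
               collapse = "\n"), "\n")
    if (nrow(object@edges) > 5) cat("  ...\n")
  }
})

setMethod("show", "PatternReport", function(object) {
  cat(sprintf(
    "PatternReport: %d edges, %d combinatorial patterns, %d singleton marks\n",
    object@nEdges, length(object@patterns), length(object@singletons)))
  for (p in utils::head(object@patterns, 5)) {
    cat("  {", paste(p, collapse = ", "), "}\n")
  }
  if (length(object@patterns) > 5) cat("  ...\n")
})

setMethod("show", "NetworkDiff", function(object) {
  cat(sprintf(
    "NetworkDiff: %d only in A, %d only in B, %d shared\n",
    nrow(object@onlyA), nrow(object@onlyB), nrow(object@shared)))
})
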