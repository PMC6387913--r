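# Post-analysis of consensus networks: combinatorial patterns (connected
# components), marks adjacent to a splicing outcome node, and skeleton-level
# differencing between conditions.

#' Combinatorial patterns of a consensus network
#'
#' A combinatorial pattern is a connected component (>= 2 marks) of the
#' undirected skeleton; marks not involved in any edge are reported as
#' singletons. Direction-invariant by construction.
#'
#' @param network a [ConsensusNetwork-class] or [DAGStructure-class].
#' @return a [PatternReport-class].
#' @examples
#' dag <- DAGStructure(LETTERS[1:5],
#'                     data.frame(from = c("A", "B", "D"),
#'                                to = c("B", "C", "E")))
#' findPatterns(dag)
#' @export
findPatterns <- function(network) {
  e <- if (is(network, "ConsensusNetwork")) network@edges else edges(network)
  nodes <- nodes(network)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  pats <- Filter(function(x) length(x) >= 2L, groups)
  pats <- lapply(pats, sort)
  pats <- pats[order(vapply(pats, `[`, character(1), 1L))]
  names(pats) <- NULL
  single <- sort(unlist(groups[lengths(groups) == 1L], use.names = FALSE))
  if (is.null(single)) single <- character(0)
  new("PatternReport", nEdges = nrow(e), patterns = pats,
      singletons = single)
}

#' Marks directly adjacent to an outcome node
#'
#' Returns every mark that is a parent or child of the given outcome node in
#' the network -- the marks "directly correlated" with the outcome when the
#' network was learned over the mark matrix plus an appended binary splicing
#' column (see [appendOutcomeColumn()]).
#'
#' @param network a [ConsensusNetwork-class] or [DAGStructure-class].
#' @param outcome name of the outcome node (must be in the network).
#' @return lexicographically sorted character vector of adjacent marks.
#' @export
directMarks <- function(network, outcome) {
  nodes <- nodes(network)
  if (!outcome %in% nodes) {
    stop("parameter error: outcome node '", outcome, "' is not in the network")
  }
  e <- if (is(network, "ConsensusNetwork")) network@edges else edges(network)
  adj <- c(e$from[e$to == outcome], e$to[e$from == outcome])
  sort(unique(adj))
}

#' Combine included/excluded matrices with a binary outcome column
#'
#' Stacks two modification matrices of the same region and appends a binary
#' outcome column (1 = included, 0 = excluded), producing the 39-node input
#' for learning splicing-adjacent marks.
#'
#' @param included,excluded [ModificationMatrix-class] objects over the same
#'   marks.
#' @param outcome name for the outcome column.
#' @return a [ModificationMatrix-class] with `splicingClass = "mixed"`.
#' @export
appendOutcomeColumn <- function(included, excluded, outcome = "splicing") {
  stopifnot(is(included, "ModificationMatrix"),
            is(excluded, "ModificationMatrix"))
  if (!identical(marks(included), marks(excluded))) {
    stop("parameter error: the two matrices must share the same marks")
  }
  if (outcome %in% marks(included)) {
    stop("parameter error: outcome name collides with a mark name")
  }
  xi <- as.matrix(included)
  xe <- as.matrix(excluded)
  m <- rbind(xi, xe)
  rownames(m) <- c(paste0("inc_", rownames(xi)), paste0("exc_", rownames(xe)))
  m <- cbind(m, rep(c(1L, 0L), c(nrow(xi), nrow(xe))))
  colnames(m)[ncol(m)] <- outcome
  suppressWarnings(
    ModificationMatrix(m, region = region(included), splicingClass = "mixed")
  )
}

#' Skeleton-level difference of two networks
#'
#' Partitions the union of the two skeletons into pairs only in A, only in
#' B, and shared pairs; shared pairs additionally report whether the
#' correlation-sign annotations agree.
#'
#' @param a,b [ConsensusNetwork-class] objects over the same node set.
#' @return a [NetworkDiff-class].
#' @export
diffNetworks <- function(a, b) {
  stopifnot(is(a, "ConsensusNetwork"), is(b, "ConsensusNetwork"))
  if (!identical(sort(a@nodes), sort(b@nodes))) {
    stop("parameter error: networks must share the same node set")
  }
  skel <- function(net) {
    e <- net@edges
    if (!nrow(e)) {
      return(data.frame(a = character(0), b = character(0),
                        sign = character(0), stringsAsFactors = FALSE))
    }
    data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
               sign = e$correlation_sign, stringsAsFactors = FALSE)
  }
  sa <- skel(a)
  sb <- skel(b)
  ka <- paste(sa$a, sa$b, sep = "\r")
  kb <- paste(sb$a, sb$b, sep = "\r")
  onlyA <- sa[!ka %in% kb, c("a", "b"), drop = FALSE]
  onlyB <- sb[!kb %in% ka, c("a", "b"), drop = FALSE]
  shared_keys <- intersect(ka, kb)
  ia <- match(shared_keys, ka)
  ib <- match(shared_keys, kb)
  shared <- data.frame(
    a = sa$a[ia], b = sa$b[ia],
    sign_a = sa$sign[ia], sign_b = sb$sign[ib],
    sign_agrees = sa$sign[ia] == sb$sign[ib],
    stringsAsFactors = FALSE
  )
  ord <- function(d) {
    d <- d[order(d$a, d$b), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  new("NetworkDiff", onlyA = ord(onlyA), onlyB = ord(onlyB),
      shared = ord(shared))
}

#' Serialize a pattern report or network diff to JSON
#'
#' @param x a [PatternReport-class] or [NetworkDiff-class].
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
writeReportJson <- function(x, path) {
  payload <- if (is(x, "PatternReport")) {
    list(n_edges = x@nEdges, n_patterns = length(x@patterns),
         patterns = x@patterns, singleton_nodes = x@singletons)
  } else if (is(x, "NetworkDiff")) {
    list(edges_only_in_a = x@onlyA, edges_only_in_b = x@onlyB,
         shared_edges = x@shared)
  } else {
    stop("unsupported class: ", class(x)[1L])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
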