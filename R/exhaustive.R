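# Exhaustive DAG enumeration for small node counts: the oracle the greedy
# search is validated against.

# Cache of enumerated DAG collections, keyed by node count.
.dag_enum_cache <- new.env(parent = emptyenv())

#' Enumerate every labeled DAG on p nodes
#'
#' Iterates over all 2^(p(p-1)) directed graphs on the ordered node set and
#' keeps the acyclic ones. Intended as a test oracle; refuses p > 5 (the
#' enumeration grows super-exponentially).
#'
#' @param p number of nodes (1..5).
#' @return a list of logical p x p adjacency matrices (`A[i, j]` = edge
#'   i -> j), in canonical (edge-bitmask) order.
#' @examples
#' length(enumerateDags(2))  # 3
#' @export
enumerateDags <- function(p) {
  p <- as.integer(p)
  if (p < 1L || p > 5L) {
    stop("refusing to enumerate DAGs on ", p,
         " nodes (supported: 1..5; the count grows super-exponentially)")
  }
  key <- as.character(p)
  if (!is.null(.dag_enum_cache[[key]])) return(.dag_enum_cache[[key]])
  if (p == 1L) {
    out <- list(matrix(FALSE, 1L, 1L))
    .dag_enum_cache[[key]] <- out
    return(out)
  }
  pairs <- which(diag(p) == 0, arr.ind = TRUE)   # ordered node pairs
  m <- nrow(pairs)
  out <- vector("list", 0L)
  A <- matrix(FALSE, p, p)
  for (mask in 0:(2^m - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
    A[] <- FALSE
    A[pairs[bits, , drop = FALSE]] <- TRUE
    if (is_acyclic_adj(A)) out[[length(out) + 1L]] <- A
  }
  .dag_enum_cache[[key]] <- out
  out
}

# Acyclicity of an adjacency matrix by iterative leaf removal.
is_acyclic_adj <- function(A) {
  active <- rep(TRUE, nrow(A))
  repeat {
    if (!any(active)) return(TRUE)
    sub <- A[active, active, drop = FALSE]
    sinks <- colSums(sub) == 0 | rowSums(sub) == 0
    if (!any(sinks)) return(FALSE)
    active[which(active)[sinks]] <- FALSE
  }
}

#' Exhaustive-search oracle for structure learning
#'
#' Scores every labeled DAG on the data's columns (subject to the
#' `maxParents` cap, so the search space matches [hillClimb()]'s) and
#' returns the score-maximal one; ties go to the first DAG in canonical
#' enumeration order.
#'
#' @param data a [ModificationMatrix-class] with at most `maxNodes` marks.
#' @param config a [LearnConfig-class].
#' @param maxNodes refusal bound on the node count (<= 5).
#' @return a [DAGStructure-class] with attribute `"score"`.
#' @seealso [hillClimb()], whose score this oracle bounds from above.
#' @export
exhaustiveSearch <- function(data, config = LearnConfig(), maxNodes = 4) {
  stopifnot(is(data, "ModificationMatrix"), is(config, "LearnConfig"))
  maxNodes <- min(as.integer(maxNodes), 5L)
  X <- as.matrix(data)
  p <- ncol(X)
  if (p > maxNodes) {
    stop("refusing exhaustive search on ", p, " nodes (maxNodes = ",
         maxNodes, "): combinatorial explosion")
  }
  dags <- enumerateDags(p)
  ls_fun <- make_score_fun(X, config)
  best <- NULL
  best_score <- -Inf
  for (A in dags) {
    if (any(colSums(A) > config@maxParents)) next
    sc <- sum(vapply(seq_len(p), function(b) ls_fun(b, which(A[, b])),
                     numeric(1)))
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- A
    }
  }
  eidx <- which(best, arr.ind = TRUE)
  nm <- colnames(X)
  dag <- DAGStructure(nm, data.frame(from = nm[eidx[, 1L]],
                                     to = nm[eidx[, 2L]],
                                     stringsAsFactors = FALSE))
  attr(dag, "score") <- best_score
  dag
}
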