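# The robust-network protocol: 10 random folds, ten leave-one-fold-out
# structure learners ("fundamental networks"), and a consensus that keeps
# edges appearing in at least 7 of the 10, annotated with correlation signs.

#' Partition samples into k random folds
#'
#' Seeded uniform partition with fold sizes differing by at most one
#' (floor(n/k) or ceiling(n/k)).
#'
#' @param n number of samples (>= k).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a [FoldPlan-class].
#' @examples
#' table(foldAssignments(makeFolds(105, 10, seed = 1)))
#' @export
makeFolds <- function(n, k = 10, seed = 1) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < k) stop("parameter error: need at least k samples (n >= k)")
  assignments <- with_seed(derive_seed(seed, 3L), {
    sample(rep(seq_len(k), length.out = n))
  })
  new("FoldPlan", n = n, k = k, assignments = as.integer(assignments),
      seed = as.integer(seed))
}

#' Learn the fundamental networks
#'
#' Network i is [hillClimb()] run on the data with fold i held out, so k
#' folds yield k fundamental networks (in fold-index order), each learned
#' from (k-1)/k of the samples.
#'
#' @param data a [ModificationMatrix-class].
#' @param folds a [FoldPlan-class] consistent with `data` (same n).
#' @param config a [LearnConfig-class].
#' @return list of k [DAGStructure-class] objects.
#' @export
learnFundamentalNetworks <- function(data, folds, config = LearnConfig()) {
  stopifnot(is(data, "ModificationMatrix"), is(folds, "FoldPlan"))
  if (folds@n != nrow(data)) {
    stop("parameter error: fold plan covers ", folds@n,
         " samples but data has ", nrow(data))
  }
  lapply(seq_len(folds@k), function(i) {
    hillClimb(data[folds@assignments != i, ], config)
  })
}

#' Build the consensus network
#'
#' For every unordered node pair, the stability count is the number of
#' fundamental networks containing the pair in either direction (a DAG can
#' contain at most one). Pairs with count >= `threshold` are retained.
#' Direction is resolved by majority among the networks containing the pair;
#' ties take the lexicographically smaller node as parent and are flagged
#' `direction_tie`. If the retained directed edges form cycles, the
#' lowest-stability edge in each cycle is re-oriented (flagged
#' `cycle_reversed`) or, failing that, dropped (`cycle_dropped`), so the
#' result is always a DAG. Retained edges are annotated with the sign and
#' value of the full-dataset correlation; an undefined correlation yields
#' sign `"undefined"`.
#'
#' With `edgeIdentity = "directed"` the count is over exactly-directed edges
#' instead of skeleton pairs (the stricter reading of edge stability).
#'
#' @param networks list of [DAGStructure-class] objects sharing one node set.
#' @param threshold minimum stability count (default 7, out of 10).
#' @param cm optional [CorrelationMatrix-class] for sign annotation.
#' @param edgeIdentity `"skeleton"` (default) or `"directed"`.
#' @return a [ConsensusNetwork-class].
#' @export
buildConsensus <- function(networks, threshold = 7, cm = NULL,
                           edgeIdentity = c("skeleton", "directed")) {
  edgeIdentity <- match.arg(edgeIdentity)
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, is, logical(1), "DAGStructure")))
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > length(networks)) {
    stop("parameter error: threshold must lie in 1..", length(networks))
  }
  nodes <- networks[[1L]]@nodes
  for (nw in networks[-1L]) {
    if (!identical(sort(nw@nodes), sort(nodes))) {
      stop("parameter error: all networks must share the same node set")
    }
  }
  p <- length(nodes)
  D <- matrix(0L, p, p, dimnames = list(nodes, nodes))  # directed counts
  for (nw in networks) {
    e <- nw@edges
    if (nrow(e)) {
      ij <- cbind(match(e$from, nodes), match(e$to, nodes))
      D[ij] <- D[ij] + 1L
    }
  }
  S <- D + t(D)                                         # skeleton counts

  ut <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  pair_counts <- data.frame(
    a = nodes[ut[, 1L]], b = nodes[ut[, 2L]],
    skeleton_count = S[ut],
    count_ab = D[ut],
    count_ba = t(D)[ut],
    stringsAsFactors = FALSE
  )
  pair_counts <- pair_counts[order(pair_counts$a, pair_counts$b), ,
                             drop = FALSE]
  rownames(pair_counts) <- NULL

  if (edgeIdentity == "skeleton") {
    keep <- pair_counts[pair_counts$skeleton_count >= threshold, ,
                        drop = FALSE]
    if (nrow(keep)) {
      fwd <- keep$count_ab > keep$count_ba
      tie <- keep$count_ab == keep$count_ba
      edges <- data.frame(
        from = ifelse(fwd | tie, keep$a, keep$b),
        to = ifelse(fwd | tie, keep$b, keep$a),
        skeleton_count = keep$skeleton_count,
        directed_count = pmax(keep$count_ab, keep$count_ba),
        reverse_count = pmin(keep$count_ab, keep$count_ba),
        flag = ifelse(tie, "direction_tie", ""),
        stringsAsFactors = FALSE
      )
    } else {
      edges <- empty_consensus_edges()[, c("from", "to", "skeleton_count",
                                           "directed_count", "reverse_count",
                                           "flag")]
    }
  } else {
    sel <- pair_counts$count_ab >= threshold
    rev_sel <- pair_counts$count_ba >= threshold
    edges <- data.frame(
      from = c(pair_counts$a[sel], pair_counts$b[rev_sel]),
      to = c(pair_counts$b[sel], pair_counts$a[rev_sel]),
      skeleton_count = c(pair_counts$skeleton_count[sel],
                         pair_counts$skeleton_count[rev_sel]),
      directed_count = c(pair_counts$count_ab[sel],
                         pair_counts$count_ba[rev_sel]),
      reverse_count = c(pair_counts$count_ba[sel],
                        pair_counts$count_ab[rev_sel]),
      flag = rep("", sum(sel) + sum(rev_sel)),
      stringsAsFactors = FALSE
    )
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  edges <- resolve_cycles(edges, nodes)

  if (!is.null(cm)) {
    stopifnot(is(cm, "CorrelationMatrix"))
    v <- as.matrix(cm)
    r <- v[cbind(match(edges$from, rownames(v)),
                 match(edges$to, colnames(v)))]
    edges$correlation_value <- r
    edges$correlation_sign <- ifelse(is.na(r) | r == 0, "undefined",
                                     ifelse(r > 0, "+", "-"))
  } else {
    edges$correlation_value <- rep(NA_real_, nrow(edges))
    edges$correlation_sign <- rep("undefined", nrow(edges))
  }
  edges <- edges[, c("from", "to", "skeleton_count", "directed_count",
                     "reverse_count", "correlation_sign",
                     "correlation_value", "flag")]

  new("ConsensusNetwork", nodes = nodes, edges = edges,
      threshold = threshold, nNetworks = length(networks),
      pairCounts = pair_counts)
}

empty_consensus_edges <- function() {
  data.frame(from = character(0), to = character(0),
             skeleton_count = integer(0), directed_count = integer(0),
             reverse_count = integer(0), correlation_sign = character(0),
             correlation_value = numeric(0), flag = character(0),
             stringsAsFactors = FALSE)
}

# Re-orient (once) or drop the lowest-stability edge of each directed cycle
# until the edge set is acyclic. Deterministic: within a strongly connected
# component, candidate edges are ordered by (stability, from, to).
resolve_cycles <- function(edges, nodes) {
  if (!nrow(edges)) return(edges)
  reversed <- character(0)
  repeat {
    if (!is.null(topo_order(nodes, edges$from, edges$to))) break
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = TRUE, vertices = nodes)
    comp <- igraph::components(g, mode = "strong")
    sizes <- comp$csize
    cyc_comp <- which(sizes >= 2L)
    members <- names(comp$membership)[comp$membership == cyc_comp[1L]]
    in_cyc <- which(edges$from %in% members & edges$to %in% members)
    o <- in_cyc[order(edges$skeleton_count[in_cyc], edges$from[in_cyc],
                      edges$to[in_cyc])]
    i <- o[1L]
    key <- pair_key(edges$from[i], edges$to[i])
    opposite_exists <- any(edges$from == edges$to[i] & edges$to == edges$from[i])
    if (key %in% reversed || opposite_exists) {
      edges$flag[i] <- paste0(edges$flag[i],
                              if (nzchar(edges$flag[i])) "," else "",
                              "cycle_dropped")
      edges <- edges[-i, , drop = FALSE]
    } else {
      tmp <- edges$from[i]
      edges$from[i] <- edges$to[i]
      edges$to[i] <- tmp
      dc <- edges$directed_count[i]
      edges$directed_count[i] <- edges$reverse_count[i]
      edges$reverse_count[i] <- dc
      edges$flag[i] <- paste0(edges$flag[i],
                              if (nzchar(edges$flag[i])) "," else "",
                              "cycle_reversed")
      reversed <- c(reversed, key)
    }
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Run the full consensus protocol on one dataset
#'
#' Convenience wrapper: computes the full-data correlation matrix, draws the
#' fold plan, learns the k fundamental networks and builds the consensus.
#' With `rounds > 1`, the k-fold procedure is repeated with independent fold
#' plans and the threshold scales to `rounds * threshold` over the pooled
#' `rounds * k` networks (the alternative reading of repeating the
#' cross-validation).
#'
#' @param data a [ModificationMatrix-class].
#' @param config a [LearnConfig-class].
#' @param k folds per round (default 10).
#' @param threshold per-round stability threshold (default 7).
#' @param rounds number of independent fold rounds (default 1).
#' @param seed integer seed for the fold plans.
#' @param edgeIdentity passed to [buildConsensus()].
#' @return a [ConsensusNetwork-class]; attribute `"foldPlans"` holds the
#'   fold plans and attribute `"fundamental"` the learned networks.
#' @export
consensusProtocol <- function(data, config = LearnConfig(), k = 10,
                              threshold = 7, rounds = 1, seed = 1,
                              edgeIdentity = "skeleton") {
  cm <- correlationMatrix(data)
  plans <- lapply(seq_len(rounds), function(r) {
    makeFolds(nrow(data), k, seed = derive_seed(seed, 10L + r))
  })
  networks <- unlist(lapply(plans, function(fp) {
    learnFundamentalNetworks(data, fp, config)
  }), recursive = FALSE)
  net <- buildConsensus(networks, threshold = as.integer(threshold * rounds),
                        cm = cm, edgeIdentity = edgeIdentity)
  attr(net, "foldPlans") <- plans
  attr(net, "fundamental") <- networks
  net
}
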