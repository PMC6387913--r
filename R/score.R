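# Decomposable network scores for binary variables: BDeu marginal
# likelihood and BIC. Both operate on sufficient statistics (cell counts of
# the child x parent-configuration table), so they are invariant to row
# order and cheap to cache by (node, parent set).

# Local score from the raw integer matrix. `j` and `par` are column indices;
# `par` may be empty. Counts are laid out as (config 0: x=0, x=1,
# config 1: x=0, x=1, ...) with the first parent as least significant bit.
local_score_idx <- function(X, j, par, score, ess) {
  n <- nrow(X)
  x <- X[, j]
  k <- length(par)
  q <- 2L^k
  if (k == 0L) {
    pc <- integer(n)
  } else {
    w <- 2^(seq_len(k) - 1L)
    pc <- as.integer(X[, par, drop = FALSE] %*% w)
  }
  counts <- tabulate(2L * pc + x + 1L, nbins = 2L * q)
  nj <- counts[seq(1L, 2L * q, 2L)] + counts[seq(2L, 2L * q, 2L)]
  if (score == "bdeu") {
    a <- ess / (2 * q)    # Dirichlet hyperparameter per cell (r = 2 states)
    aj <- ess / q
    sum(lgamma(aj) - lgamma(aj + nj)) +
      sum(lgamma(a + counts)) - 2 * q * lgamma(a)
  } else {
    pos <- counts > 0L
    njcell <- rep(nj, each = 2L)
    ll <- sum(counts[pos] * (log(counts[pos]) - log(njcell[pos])))
    ll - log(n) / 2 * q   # penalty = log(n)/2 * q * (r - 1), r = 2
  }
}

# Memoizing wrapper: one cache environment per learning run.
make_score_fun <- function(X, config) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  score <- config@score
  ess <- config@ess
  function(j, par) {
    key <- paste0(j, "|", paste(sort.int(par), collapse = ","))
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    v <- local_score_idx(X, j, sort.int(par), score, ess)
    cache[[key]] <- v
    v
  }
}

#' Local score of a node given a parent set
#'
#' The decomposable per-node term of the network score: the BDeu log
#' marginal likelihood (Dirichlet hyperparameters `ess / (q * r)` per cell,
#' with r = 2 states and q = 2^|parents| parent configurations) or the BIC
#' (maximized log-likelihood minus `log(n)/2 * q * (r - 1)`).
#'
#' @param node a column name of `data`.
#' @param parents character vector of parent column names (may be empty);
#'   must not contain `node`.
#' @param data a [ModificationMatrix-class].
#' @param config a [LearnConfig-class] (score family, ess, maxParents).
#' @return the log-scale local score (scalar).
#' @export
localScore <- function(node, parents, data, config = LearnConfig()) {
  stopifnot(is(data, "ModificationMatrix"), is(config, "LearnConfig"))
  X <- as.matrix(data)
  cols <- colnames(X)
  if (!node %in% cols) stop("parameter error: unknown node: ", node)
  if (!all(parents %in% cols)) {
    stop("parameter error: unknown parent(s): ",
         paste(setdiff(parents, cols), collapse = ", "))
  }
  if (node %in% parents) {
    stop("parameter error: parent set must not contain the node itself")
  }
  if (length(parents) > config@maxParents) {
    stop("parameter error: more than maxParents parents")
  }
  local_score_idx(X, match(node, cols), match(parents, cols),
                  config@score, config@ess)
}

#' Score of a whole DAG
#'
#' Sum of [localScore()] over every node with its DAG parents
#' (decomposability). Changing one edge changes only the child's term.
#'
#' @param dag a [DAGStructure-class] whose nodes are columns of `data`.
#' @param data a [ModificationMatrix-class].
#' @param config a [LearnConfig-class].
#' @return the log-scale network score (scalar).
#' @export
networkScore <- function(dag, data, config = LearnConfig()) {
  stopifnot(is(dag, "DAGStructure"))
  missing <- setdiff(dag@nodes, marks(data))
  if (length(missing)) {
    stop("parameter error: node(s) missing from data: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(data)
  cols <- colnames(X)
  sum(vapply(dag@nodes, function(nm) {
    par <- dag@edges$from[dag@edges$to == nm]
    local_score_idx(X, match(nm, cols), match(par, cols),
                    config@score, config@ess)
  }, numeric(1)))
}
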