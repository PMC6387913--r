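# Greedy score-based structure search over {add, delete, reverse} moves.
# Deterministic: the best admissible move is taken each iteration, with ties
# broken by a fixed total order (add < delete < reverse, then lexicographic
# parent/child names). A cached transitive closure makes acyclicity checks
# for additions O(1); reversals use a per-edge path check.

#' Learn a DAG by greedy hill climbing
#'
#' Starts from the empty graph and repeatedly applies the single edge
#' addition, deletion or reversal that most improves the decomposable
#' network score (BDeu or BIC, see [localScore()]), subject to acyclicity
#' and the `maxParents` cap, until no move improves the score by more than
#' `config@tol` or `maxIterations` moves were accepted. With
#' `config@restarts > 0`, additional climbs start from seeded random DAGs
#' and the best-scoring result is returned.
#'
#' @param data a [ModificationMatrix-class] with p >= 2 marks.
#' @param config a [LearnConfig-class].
#' @return a [DAGStructure-class]; attribute `"score"` holds the final
#'   network score and attribute `"trace"` the score after each accepted
#'   move (monotonically non-decreasing).
#' @examples
#' mm <- forwardSample(buildPlantedDag(4, 3, 2, 0.9, seed = 1, nSamples = 300))
#' hillClimb(mm, LearnConfig())
#' @export
hillClimb <- function(data, config = LearnConfig()) {
  stopifnot(is(data, "ModificationMatrix"), is(config, "LearnConfig"))
  X <- as.matrix(data)
  if (ncol(X) < 2L) stop("parameter error: at least two marks are required")
  best <- hill_climb_once(X, config, init = NULL)
  if (config@restarts > 0L) {
    p <- ncol(X)
    for (r in seq_len(config@restarts)) {
      init <- with_seed(derive_seed(config@seed, 100L + r), {
        random_adjacency(p, min(p, config@maxParents))
      })
      cand <- hill_climb_once(X, config, init = init)
      if (attr(cand, "score") > attr(best, "score") + config@tol) best <- cand
    }
  }
  best
}

# Random DAG adjacency used for restarts: random topological order, each
# feasible edge kept with probability 0.15 subject to the in-degree cap.
random_adjacency <- function(p, maxParents) {
  ord <- sample.int(p)
  A <- matrix(FALSE, p, p)
  indeg <- integer(p)
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1L)) {
      child <- ord[i]
      if (indeg[child] < maxParents && stats::runif(1) < 0.15) {
        A[ord[j], child] <- TRUE
        indeg[child] <- indeg[child] + 1L
      }
    }
  }
  A
}

hill_climb_once <- function(X, config, init = NULL) {
  p <- ncol(X)
  node_names <- colnames(X)
  rk <- rank(node_names)              # lexicographic rank for tie-breaks
  ls_fun <- make_score_fun(X, config)
  maxP <- config@maxParents
  tol <- config@tol

  pars <- rep(list(integer(0)), p)
  A <- matrix(FALSE, p, p)
  if (!is.null(init)) {
    A <- init
    for (b in seq_len(p)) pars[[b]] <- which(A[, b])
  }
  s0 <- vapply(seq_len(p), function(j) ls_fun(j, pars[[j]]), numeric(1))
  Rm <- reach_closure(A)

  # addDelta[a, b] = gain of adding a -> b given b's current parents;
  # NA where a == b or the edge already exists. Recomputed per column when
  # that child's parent set changes.
  addDelta <- matrix(NA_real_, p, p)
  recompute_col <- function(b) {
    for (a in seq_len(p)) {
      if (a == b || A[a, b]) {
        addDelta[a, b] <<- NA_real_
      } else {
        addDelta[a, b] <<- ls_fun(b, c(pars[[b]], a)) - s0[b]
      }
    }
  }
  for (b in seq_len(p)) recompute_col(b)

  trace <- sum(s0)
  iter <- 0L
  repeat {
    if (iter >= config@maxIterations) break
    npar <- lengths(pars)

    # --- best addition ---
    mask <- !is.na(addDelta) & !t(A) & !t(Rm)
    mask[, npar >= maxP] <- FALSE
    vals <- ifelse(mask, addDelta, -Inf)
    best_add <- max(vals)
    add_cell <- NULL
    if (is.finite(best_add)) {
      cand <- which(vals == best_add, arr.ind = TRUE)
      o <- order(rk[cand[, 1L]], rk[cand[, 2L]])
      add_cell <- cand[o[1L], ]
    }

    # --- best deletion / reversal over current edges ---
    eidx <- which(A, arr.ind = TRUE)
    best_del <- -Inf; del_cell <- NULL
    best_rev <- -Inf; rev_cell <- NULL
    if (nrow(eidx)) {
      o <- order(rk[eidx[, 1L]], rk[eidx[, 2L]])
      eidx <- eidx[o, , drop = FALSE]
      for (r in seq_len(nrow(eidx))) {
        a <- eidx[r, 1L]; b <- eidx[r, 2L]
        dd <- ls_fun(b, setdiff(pars[[b]], a)) - s0[b]
        if (dd > best_del) { best_del <- dd; del_cell <- c(a, b) }
        if (npar[a] < maxP) {
          A[a, b] <- FALSE
          cyc <- has_path(A, a, b)
          A[a, b] <- TRUE
          if (!cyc) {
            rd <- dd + ls_fun(a, c(pars[[a]], b)) - s0[a]
            if (rd > best_rev) { best_rev <- rd; rev_cell <- c(a, b) }
          }
        }
      }
    }

    deltas <- c(add = best_add, delete = best_del, reverse = best_rev)
    move <- names(deltas)[which.max(deltas)]   # ties: add < delete < reverse
    if (deltas[[move]] <= tol) break

    if (move == "add") {
      a <- add_cell[[1L]]; b <- add_cell[[2L]]
      pars[[b]] <- c(pars[[b]], a)
      A[a, b] <- TRUE
      s0[b] <- ls_fun(b, pars[[b]])
      changed <- b
    } else if (move == "delete") {
      a <- del_cell[[1L]]; b <- del_cell[[2L]]
      pars[[b]] <- setdiff(pars[[b]], a)
      A[a, b] <- FALSE
      s0[b] <- ls_fun(b, pars[[b]])
      changed <- b
    } else {
      a <- rev_cell[[1L]]; b <- rev_cell[[2L]]
      pars[[b]] <- setdiff(pars[[b]], a)
      pars[[a]] <- c(pars[[a]], b)
      A[a, b] <- FALSE
      A[b, a] <- TRUE
      s0[b] <- ls_fun(b, pars[[b]])
      s0[a] <- ls_fun(a, pars[[a]])
      changed <- c(a, b)
    }
    Rm <- reach_closure(A)
    for (ch in changed) recompute_col(ch)
    iter <- iter + 1L
    trace <- c(trace, sum(s0))
  }

  eidx <- which(A, arr.ind = TRUE)
  dag <- DAGStructure(node_names,
                      data.frame(from = node_names[eidx[, 1L]],
                                 to = node_names[eidx[, 2L]],
                                 stringsAsFactors = FALSE))
  attr(dag, "score") <- sum(s0)
  attr(dag, "trace") <- trace
  dag
}
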