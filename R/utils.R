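# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the user's random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific seed from a master seed. Kept strictly below
# 2^31 - 1 so it is always representable as an R integer.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 + as.numeric(stream) * 104729
  as.integer(s %% 2147483646) + 1L
}

# Kahn topological sort on an edge list. Returns the node order, or NULL if
# the graph contains a directed cycle.
topo_order <- function(nodes, from, to) {
  p <- length(nodes)
  idx <- stats::setNames(seq_len(p), nodes)
  indeg <- integer(p)
  adj <- vector("list", p)
  for (i in seq_along(from)) {
    a <- idx[[from[i]]]
    b <- idx[[to[i]]]
    adj[[a]] <- c(adj[[a]], b)
    indeg[b] <- indeg[b] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < p) NULL else nodes[out]
}

# Transitive closure of a logical adjacency matrix: R[i, j] is TRUE when a
# directed path of length >= 1 leads from i to j.
reach_closure <- function(A) {
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# Is there a directed path from `from` to `to` in adjacency matrix A?
has_path <- function(A, from, to) {
  seen <- logical(nrow(A))
  frontier <- which(A[from, ])
  seen[frontier] <- TRUE
  while (length(frontier)) {
    if (seen[to]) return(TRUE)
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[to]
}

# Canonical unordered pair key used for skeleton-level edge identity.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}
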