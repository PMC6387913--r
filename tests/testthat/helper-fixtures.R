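# Shared fixtures: all built in code at test time.

# A small binary matrix with named marks.
tiny_matrix <- function(values, marks, region = "exon", class = "mixed") {
  m <- matrix(values, ncol = length(marks), byrow = TRUE,
              dimnames = list(NULL, marks))
  suppressWarnings(ModificationMatrix(m, region = region,
                                      splicingClass = class))
}

# Write a TSV modification matrix by hand (independent of the package's
# writer, so read/write tests do not share a code path).
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Unordered skeleton keys of an edge data.frame.
skeleton_keys <- function(e) {
  if (!nrow(e)) return(character(0))
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
}

# Edge data.frame comparison ignoring row order/names.
expect_same_edges <- function(a, b) {
  norm <- function(e) {
    e <- e[order(e$from, e$to), c("from", "to")]
    rownames(e) <- NULL
    e
  }
  expect_identical(norm(a), norm(b))
}

# A consensus network with a fixed edge set: k identical fundamental DAGs.
consensus_of <- function(nodes, edges_df, k = 10, threshold = 7, cm = NULL) {
  dag <- DAGStructure(nodes, edges_df)
  buildConsensus(rep(list(dag), k), threshold = threshold, cm = cm)
}

# Seeded RNG block that restores the session's random state.
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent two-pass Pearson correlation (textbook formula), the oracle
# pearsonBinary is checked against.
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
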