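#' @import methods
NULL

REGIONS <- c("exon", "preceding_intron", "succeeding_intron")
SPLICING_CLASSES <- c("included", "excluded", "mixed")

#' ModificationMatrix: binary histone-modification presence calls
#'
#' An n x p binary matrix of presence (1) / absence (0) calls for p histone
#' modifications over n exons (or their flanking intronic regions), together
#' with the genomic region the calls refer to and the splicing class of the
#' exons (included in or excluded from mature transcripts, or a mix).
#'
#' @slot presence integer matrix with entries in \{0, 1\}; rownames are exon
#'   identifiers, colnames are unique modification names.
#' @slot region one of `"exon"`, `"preceding_intron"`, `"succeeding_intron"`.
#' @slot splicingClass one of `"included"`, `"excluded"`, `"mixed"`.
#' @export
setClass("ModificationMatrix",
  representation(
    presence = "matrix",
    region = "character",
    splicingClass = "character"
  )
)

setValidity("ModificationMatrix", function(object) {
  v <- object@presence
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "presence must be a numeric matrix")
  else if (!all(v == 0L | v == 1L)) {
    msgs <- c(msgs, "presence entries must all be 0 or 1")
  }
  if (nrow(v) < 1L) msgs <- c(msgs, "at least one sample (row) is required")
  if (ncol(v) < 2L) msgs <- c(msgs, "at least two marks (columns) are required")
  cn <- colnames(v)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn))) {
    msgs <- c(msgs, "mark names (colnames) must be present, non-empty and unique")
  }
  if (length(object@region) != 1L || !object@region %in% REGIONS) {
    msgs <- c(msgs, sprintf("region must be one of: %s",
                            paste(REGIONS, collapse = ", ")))
  }
  if (length(object@splicingClass) != 1L ||
      !object@splicingClass %in% SPLICING_CLASSES) {
    msgs <- c(msgs, sprintf("splicingClass must be one of: %s",
                            paste(SPLICING_CLASSES, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModificationMatrix
#'
#' Validates a binary presence matrix and attaches region / splicing-class
#' metadata. Rows with no modification present are legal (the upstream data
#' were filtered to remove them, so their presence is suspicious) and trigger
#' a single warning naming the offending rows.
#'
#' @param presence numeric or integer matrix with entries in \{0, 1\}.
#'   Column names are required (mark names); row names default to
#'   `sample_1 ... sample_n`.
#' @param region genomic region of the calls: `"exon"`,
#'   `"preceding_intron"` or `"succeeding_intron"`.
#' @param splicingClass `"included"`, `"excluded"` or `"mixed"`.
#' @return a validated [ModificationMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 3,
#'             dimnames = list(NULL, c("H3K4me3", "H3K9me3")))
#' mm <- ModificationMatrix(m, region = "exon", splicingClass = "included")
#' dim(mm)
#' @export
ModificationMatrix <- function(presence, region = "exon",
                               splicingClass = "mixed") {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (is.null(rownames(presence))) {
    rownames(presence) <- paste0("sample_", seq_len(nrow(presence)))
  }
  obj <- new("ModificationMatrix", presence = presence,
             region = region, splicingClass = splicingClass)
  zero <- which(rowSums(presence) == 0L)
  if (length(zero)) {
    warning(sprintf(
      "%d all-zero row(s) (no modification present): %s%s",
      length(zero),
      paste(utils::head(rownames(presence)[zero], 5L), collapse = ", "),
      if (length(zero) > 5L) ", ..." else ""
    ), call. = FALSE)
  }
  obj
}

#' CorrelationMatrix: pairwise phi coefficients between marks
#'
#' Symmetric p x p matrix of Pearson correlation coefficients computed on
#' binary presence columns (the phi coefficient). Entries involving constant
#' columns are undefined and stored as `NA`; the constant marks are recorded
#' so downstream consumers can distinguish "undefined" from "zero".
#'
#' @slot values symmetric numeric matrix in \[-1, 1\] with `NA` for undefined
#'   entries; dimnames are mark names.
#' @slot nUsed number of samples the coefficients were computed from.
#' @slot constantMarks names of constant (all-0 or all-1) columns.
#' @export
setClass("CorrelationMatrix",
  representation(
    values = "matrix",
    nUsed = "integer",
    constantMarks = "character"
  )
)

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v))) {
    msgs <- c(msgs, "values must carry identical row/column mark names")
  }
  fin <- v[!is.na(v)]
  if (length(fin) && max(abs(fin)) > 1 + 1e-12) {
    msgs <- c(msgs, "defined coefficients must lie in [-1, 1]")
  }
  if (!isTRUE(all.equal(v, t(v)))) msgs <- c(msgs, "values must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' DAGStructure: a directed acyclic graph over modification names
#'
#' @slot nodes ordered character vector of node names.
#' @slot edges data.frame with character columns `from`, `to`; one row per
#'   directed edge. No self loops, no duplicates, and the graph is acyclic.
#' @export
setClass("DAGStructure",
  representation(nodes = "character", edges = "data.frame")
)

setValidity("DAGStructure", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (!all(c("from", "to") %in% names(e))) {
    return("edges must have 'from' and 'to' columns")
  }
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "node names must be unique")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes)) {
      msgs <- c(msgs, "edge endpoints must be declared nodes")
    }
    if (any(e$from == e$to)) msgs <- c(msgs, "self loops are not allowed")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) {
      msgs <- c(msgs, "duplicate edges are not allowed")
    }
    if (is.null(topo_order(object@nodes, e$from, e$to))) {
      msgs <- c(msgs, "graph must be acyclic")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DAGStructure
#'
#' @param nodes character vector of node names.
#' @param edges data.frame (or 2-column matrix) of directed edges with
#'   columns `from`, `to`; defaults to the empty edge set.
#' @return a validated [DAGStructure-class].
#' @examples
#' DAGStructure(c("A", "B", "C"),
#'              data.frame(from = "A", to = "B"))
#' @export
DAGStructure <- function(nodes, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) {
    edges <- data.frame(from = edges[, 1], to = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  rownames(edges) <- NULL
  new("DAGStructure", nodes = as.character(nodes),
      edges = edges[, c("from", "to")])
}

#' LearnConfig: settings for score-based structure learning
#'
#' @slot score `"bdeu"` (Bayesian Dirichlet equivalent uniform marginal
#'   likelihood) or `"bic"`.
#' @slot ess positive equivalent sample size for the BDeu prior.
#' @slot maxParents maximum in-degree allowed during search.
#' @slot maxIterations cap on greedy-search moves.
#' @slot tol minimum log-score improvement for accepting a move.
#' @slot seed integer seed (used only by optional random restarts).
#' @slot restarts number of seeded random restarts (0 = deterministic
#'   single climb from the empty graph).
#' @export
setClass("LearnConfig",
  representation(
    score = "character",
    ess = "numeric",
    maxParents = "integer",
    maxIterations = "integer",
    tol = "numeric",
    seed = "integer",
    restarts = "integer"
  )
)

setValidity("LearnConfig", function(object) {
  msgs <- character(0)
  if (!object@score %in% c("bdeu", "bic")) {
    msgs <- c(msgs, "score must be 'bdeu' or 'bic'")
  }
  if (object@ess <= 0) msgs <- c(msgs, "ess must be positive")
  if (object@maxParents < 1L) msgs <- c(msgs, "maxParents must be >= 1")
  if (object@restarts < 0L) msgs <- c(msgs, "restarts must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LearnConfig
#'
#' Defaults follow common practice for sparse discrete networks: BDeu with
#' equivalent sample size 1 (a weak, near-uniform prior), at most 4 parents
#' per node, and a 1e-9 improvement tolerance (well below the floating-point
#' noise of count-based log scores).
#'
#' @param score `"bdeu"` or `"bic"`.
#' @param ess BDeu equivalent sample size (> 0).
#' @param maxParents maximum number of parents per node.
#' @param maxIterations maximum number of accepted greedy moves.
#' @param tol minimum score improvement to keep climbing.
#' @param seed integer seed for optional restarts.
#' @param restarts number of random restarts (0 disables them).
#' @return a [LearnConfig-class].
#' @examples
#' LearnConfig(score = "bic", maxParents = 3)
#' @export
LearnConfig <- function(score = c("bdeu", "bic"), ess = 1, maxParents = 4,
                        maxIterations = 500, tol = 1e-9, seed = 1,
                        restarts = 0) {
  new("LearnConfig", score = match.arg(score), ess = as.numeric(ess),
      maxParents = as.integer(maxParents),
      maxIterations = as.integer(maxIterations), tol = as.numeric(tol),
      seed = as.integer(seed), restarts = as.integer(restarts))
}

#' CPTSet: conditional probability tables for binary nodes
#'
#' One entry per node: an ordered parent list and a vector giving
#' P(node = 1) for every parent-value combination. Combinations are indexed
#' in binary order with the FIRST parent as the least significant bit, i.e.
#' element `k + 1` corresponds to parent values `binary digits of k`.
#'
#' @slot tables named list; each element is `list(parents = character,
#'   p1 = numeric)` with `length(p1) == 2^length(parents)` and
#'   probabilities in \[0, 1\].
#' @export
setClass("CPTSet", representation(tables = "list"))

setValidity("CPTSet", function(object) {
  msgs <- character(0)
  tb <- object@tables
  if (is.null(names(tb)) || anyDuplicated(names(tb))) {
    return("tables must be a uniquely named list")
  }
  for (nm in names(tb)) {
    t <- tb[[nm]]
    if (!is.list(t) || !all(c("parents", "p1") %in% names(t))) {
      msgs <- c(msgs, sprintf("table for '%s' needs 'parents' and 'p1'", nm))
      next
    }
    if (length(t$p1) != 2^length(t$parents)) {
      msgs <- c(msgs, sprintf(
        "table for '%s' must have 2^|parents| = %d probabilities",
        nm, 2^length(t$parents)))
    }
    if (any(t$p1 < 0 | t$p1 > 1)) {
      msgs <- c(msgs, sprintf("probabilities for '%s' must lie in [0, 1]", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CPTSet
#' @param tables named list of `list(parents = character, p1 = numeric)`
#'   entries (see [CPTSet-class]).
#' @return a validated [CPTSet-class].
#' @export
CPTSet <- function(tables) new("CPTSet", tables = tables)

#' PlantedScenario: a known ground-truth generative model
#'
#' Couples a DAG, its conditional probability tables, a sample size and a
#' seed, so a synthetic dataset and its answer key travel together.
#'
#' @slot dag the true [DAGStructure-class].
#' @slot cpts a [CPTSet-class] with one table per DAG node.
#' @slot nSamples number of rows to draw.
#' @slot seed master seed; topology and sampling use derived sub-streams.
#' @export
setClass("PlantedScenario",
  representation(dag = "DAGStructure", cpts = "CPTSet",
                 nSamples = "integer", seed = "integer")
)

setValidity("PlantedScenario", function(object) {
  msgs <- character(0)
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be positive")
  missing <- setdiff(object@dag@nodes, names(object@cpts@tables))
  if (length(missing)) {
    msgs <- c(msgs, sprintf("nodes without CPTs: %s",
                            paste(missing, collapse = ", ")))
  }
  for (nm in object@dag@nodes) {
    declared <- sort(object@dag@edges$from[object@dag@edges$to == nm])
    got <- sort(object@cpts@tables[[nm]]$parents)
    if (!identical(declared, got)) {
      msgs <- c(msgs, sprintf("CPT parents for '%s' disagree with the DAG", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlantedScenario
#' @param dag true [DAGStructure-class].
#' @param cpts [CPTSet-class] matching the DAG's parent sets.
#' @param nSamples rows to draw in [forwardSample()].
#' @param seed integer master seed.
#' @return a validated [PlantedScenario-class].
#' @export
PlantedScenario <- function(dag, cpts, nSamples, seed) {
  new("PlantedScenario", dag = dag, cpts = cpts,
      nSamples = as.integer(nSamples), seed = as.integer(seed))
}

#' FoldPlan: a seeded partition of samples into k folds
#'
#' @slot n number of samples.
#' @slot k number of folds.
#' @slot assignments integer vector in `1..k`, one entry per sample; fold
#'   sizes differ by at most one.
#' @slot seed the seed the partition was drawn with.
#' @export
setClass("FoldPlan",
  representation(n = "integer", k = "integer", assignments = "integer",
                 seed = "integer")
)

setValidity("FoldPlan", function(object) {
  msgs <- character(0)
  if (length(object@assignments) != object@n) {
    msgs <- c(msgs, "one fold assignment per sample is required")
  }
  if (!all(object@assignments %in% seq_len(object@k))) {
    msgs <- c(msgs, "assignments must lie in 1..k")
  }
  sizes <- tabulate(object@assignments, nbins = object@k)
  if (diff(range(sizes)) > 1L) {
    msgs <- c(msgs, "fold sizes must differ by at most one")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConsensusNetwork: stability-filtered consensus of fundamental networks
#'
#' Edges retained by the consensus rule, each carrying how many of the
#' fundamental networks contained the (undirected) pair, the majority
#' direction, and a correlation-sign annotation.
#'
#' @slot nodes mark names shared by all fundamental networks.
#' @slot edges data.frame with columns `from`, `to`, `skeleton_count`,
#'   `directed_count`, `reverse_count`, `correlation_sign`
#'   (`"+"`, `"-"` or `"undefined"`), `correlation_value`, `flag`
#'   (`""`, `"direction_tie"`, `"cycle_reversed"` or `"cycle_dropped"`
#'   annotations, comma separated).
#' @slot threshold minimum stability count an edge needed to be retained.
#' @slot nNetworks how many fundamental networks the counts are out of.
#' @slot pairCounts data.frame of ALL pairs seen in any network (`a`, `b`,
#'   `skeleton_count`, `count_ab`, `count_ba`), the full evidence the
#'   threshold was applied to.
#' @export
setClass("ConsensusNetwork",
  representation(nodes = "character", edges = "data.frame",
                 threshold = "integer", nNetworks = "integer",
                 pairCounts = "data.frame")
)

setValidity("ConsensusNetwork", function(object) {
  msgs <- character(0)
  e <- object@edges
  need <- c("from", "to", "skeleton_count", "directed_count",
            "correlation_sign", "correlation_value", "flag")
  if (!all(need %in% names(e))) {
    return(sprintf("edges must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes)) {
      msgs <- c(msgs, "edge endpoints must be declared nodes")
    }
    if (any(e$skeleton_count < object@threshold)) {
      msgs <- c(msgs, "every retained edge needs skeleton_count >= threshold")
    }
    if (is.null(topo_order(object@nodes, e$from, e$to))) {
      msgs <- c(msgs, "consensus graph must be acyclic after cycle resolution")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PatternReport: combinatorial patterns of a consensus network
#'
#' A "combinatorial pattern" is operationalized as a connected component of
#' size >= 2 of the undirected consensus skeleton; isolated marks are listed
#' separately.
#'
#' @slot nEdges number of edges in the network.
#' @slot patterns list of character vectors, each a component of >= 2 marks.
#' @slot singletons marks not involved in any edge.
#' @export
setClass("PatternReport",
  representation(nEdges = "integer", patterns = "list",
                 singletons = "character")
)

setValidity("PatternReport", function(object) {
  msgs <- character(0)
  if (any(lengths(object@patterns) < 2L)) {
    msgs <- c(msgs, "every pattern must contain >= 2 marks")
  }
  all_marks <- unlist(object@patterns)
  if (anyDuplicated(c(all_marks, object@singletons))) {
    msgs <- c(msgs, "patterns and singletons must be disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' NetworkDiff: skeleton-level comparison of two consensus networks
#'
#' @slot onlyA data.frame (`a`, `b`) of pairs present only in the first
#'   network; @slot onlyB likewise for the second.
#' @slot shared data.frame (`a`, `b`, `sign_a`, `sign_b`, `sign_agrees`).
#' @export
setClass("NetworkDiff",
  representation(onlyA = "data.frame", onlyB = "data.frame",
                 shared = "data.frame")
)
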