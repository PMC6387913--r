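# Synthetic binary data with known dependency structure: planted DAGs with
# noisy-OR-like CPTs, forward sampling, and a histone-like preset emulating
# the qualitative correlation structure of the CD4+ T-cell marks.

#' Build a random planted DAG scenario
#'
#' Draws a random DAG with exactly `nEdges` edges over `nNodes` nodes,
#' respecting a maximum in-degree, and attaches noisy-OR-like conditional
#' probability tables: root nodes fire with probability 0.5; a child fires
#' with probability `effect` when at least one parent is on and `1 - effect`
#' otherwise. A single `effect` knob therefore controls the strength of every
#' planted dependence. Topology and sampling use separate streams derived
#' from the one master seed, so the same structure can be re-sampled.
#'
#' @param nNodes number of nodes (>= 2).
#' @param nEdges exact number of edges to plant.
#' @param maxParents maximum in-degree of any node.
#' @param effect P(child = 1 | any parent on), in (0.5, 1].
#' @param seed integer master seed.
#' @param nSamples rows [forwardSample()] will draw (default 10000).
#' @param nodeNames optional node names (default `V01 ... Vp`).
#' @return a [PlantedScenario-class] holding the true DAG, its CPTs, the
#'   sample size and the seed.
#' @examples
#' sc <- buildPlantedDag(6, 4, maxParents = 2, effect = 0.9, seed = 1,
#'                       nSamples = 100)
#' trueDag(sc)
#' @export
buildPlantedDag <- function(nNodes, nEdges, maxParents, effect, seed,
                            nSamples = 10000, nodeNames = NULL) {
  nNodes <- as.integer(nNodes)
  nEdges <- as.integer(nEdges)
  maxParents <- as.integer(maxParents)
  if (nNodes < 2L) stop("parameter error: nNodes must be >= 2")
  if (effect <= 0.5 || effect > 1) {
    stop("parameter error: effect must lie in (0.5, 1]")
  }
  # Under acyclicity + in-degree cap, node i of a topological order can take
  # at most min(i - 1, maxParents) parents.
  max_feasible <- sum(pmin(seq_len(nNodes) - 1L, maxParents))
  if (nEdges < 0L || nEdges > max_feasible) {
    stop(sprintf(
      "parameter error: %d edges infeasible for %d nodes with maxParents=%d (max %d)",
      nEdges, nNodes, maxParents, max_feasible))
  }
  if (is.null(nodeNames)) {
    nodeNames <- sprintf("V%0*d", nchar(nNodes), seq_len(nNodes))
  }
  stopifnot(length(nodeNames) == nNodes, !anyDuplicated(nodeNames))

  edges <- with_seed(derive_seed(seed, 1L), {
    ord <- sample.int(nNodes)            # topological order: position -> node
    cand_i <- rep(seq_len(nNodes), times = seq_len(nNodes) - 1L)
    cand_j <- unlist(lapply(seq_len(nNodes), function(j) seq_len(j - 1L)))
    # candidate edge: ord[cand_j] -> ord[cand_i] (earlier position as parent)
    perm <- sample.int(length(cand_i))
    indeg <- integer(nNodes)
    keep_from <- integer(0)
    keep_to <- integer(0)
    for (k in perm) {
      if (length(keep_from) >= nEdges) break
      child <- ord[cand_i[k]]
      if (indeg[child] >= maxParents) next
      indeg[child] <- indeg[child] + 1L
      keep_from <- c(keep_from, ord[cand_j[k]])
      keep_to <- c(keep_to, child)
    }
    if (length(keep_from) < nEdges) {
      # Random greedy saturated some children early; fill deterministically
      # from the remaining candidates in permutation order is already done,
      # so any shortfall means the cap bound is tight -- take unused
      # candidates in canonical order.
      for (k in seq_along(cand_i)) {
        if (length(keep_from) == nEdges) break
        child <- ord[cand_i[k]]
        parent <- ord[cand_j[k]]
        if (indeg[child] >= maxParents) next
        if (any(keep_from == parent & keep_to == child)) next
        indeg[child] <- indeg[child] + 1L
        keep_from <- c(keep_from, parent)
        keep_to <- c(keep_to, child)
      }
    }
    data.frame(from = nodeNames[keep_from], to = nodeNames[keep_to],
               stringsAsFactors = FALSE)
  })
  dag <- DAGStructure(nodeNames, edges)
  cpts <- noisyOrCpts(dag, effect = effect, baseRate = 0.5)
  PlantedScenario(dag, cpts, nSamples = nSamples, seed = seed)
}

#' Noisy-OR-like CPTs for a DAG
#'
#' Roots fire with probability `baseRate`; children fire with probability
#' `effect` when at least one parent is on, `1 - effect` otherwise.
#'
#' @param dag a [DAGStructure-class].
#' @param effect P(child = 1 | >= 1 parent on).
#' @param baseRate marginal firing probability of root nodes.
#' @return a [CPTSet-class].
#' @export
noisyOrCpts <- function(dag, effect, baseRate = 0.5) {
  tables <- lapply(dag@nodes, function(nm) {
    parents <- dag@edges$from[dag@edges$to == nm]
    k <- length(parents)
    if (k == 0L) {
      list(parents = character(0), p1 = baseRate)
    } else {
      p1 <- rep(effect, 2^k)
      p1[1L] <- 1 - effect           # combination with all parents off
      list(parents = parents, p1 = p1)
    }
  })
  names(tables) <- dag@nodes
  CPTSet(tables)
}

#' Forward-sample a planted scenario
#'
#' Draws `nSamples` rows by sampling nodes in a topological order from their
#' conditional probability tables. Reproducible: the sampling stream is
#' derived from the scenario's seed.
#'
#' @param scenario a [PlantedScenario-class].
#' @return a [ModificationMatrix-class] (region `"exon"`, class `"mixed"`)
#'   whose columns follow the scenario's node order.
#' @export
forwardSample <- function(scenario) {
  stopifnot(is(scenario, "PlantedScenario"))
  dag <- scenario@dag
  tb <- scenario@cpts@tables
  n <- scenario@nSamples
  ord <- topo_order(dag@nodes, dag@edges$from, dag@edges$to)
  X <- matrix(0L, nrow = n, ncol = length(dag@nodes),
              dimnames = list(paste0("s", seq_len(n)), dag@nodes))
  with_seed(derive_seed(scenario@seed, 2L), {
    for (nm in ord) {
      t <- tb[[nm]]
      if (length(t$parents) == 0L) {
        p <- rep(t$p1[1L], n)
      } else {
        w <- 2^(seq_along(t$parents) - 1L)
        idx <- as.integer(X[, t$parents, drop = FALSE] %*% w) + 1L
        p <- t$p1[idx]
      }
      X[, nm] <- as.integer(stats::runif(n) < p)
    }
  })
  suppressWarnings(
    ModificationMatrix(X, region = "exon", splicingClass = "mixed")
  )
}

#' Histone-like synthetic preset
#'
#' Generates a 38-column binary matrix named after the full mark catalog and
#' reproducing the qualitative correlation structure reported for CD4+
#' T-cell exons: H2BK5me1 drives H3K4me1, H3K4me2, H3K79me1, H3K9me1,
#' H4K20me1 and H4K91ac (effect strength 0.85), while H3K9me3 is
#' anticorrelated with most other marks through a shared latent activity
#' state. Concretely, a latent binary (P = 0.5) raises the firing rate of the
#' 30 generic marks (0.45 vs 0.15, marginal 0.3) and of H2BK5me1 (0.65 vs
#' 0.35, marginal 0.5) while lowering H3K9me3 (0.15 vs 0.45, marginal 0.3).
#' The latent column is dropped from the output.
#'
#' @param nSamples number of rows (>= 2).
#' @param seed integer seed.
#' @return a [ModificationMatrix-class] with 38 columns in catalog order.
#'   The true generative scenario (including the latent node) is attached as
#'   attribute `"scenario"`.
#' @examples
#' mm <- histonePreset(500, seed = 1)
#' dim(mm)
#' @export
histonePreset <- function(nSamples, seed) {
  stopifnot(nSamples >= 2)
  all_marks <- markCatalog()
  hub <- "H2BK5me1"
  hub_children <- c("H3K4me1", "H3K4me2", "H3K79me1", "H3K9me1",
                    "H4K20me1", "H4K91ac")
  anti <- "H3K9me3"
  latent <- ".latent_activity"
  generic <- setdiff(all_marks, c(hub, hub_children, anti))

  nodes <- c(latent, all_marks)
  edges <- rbind(
    data.frame(from = hub, to = hub_children, stringsAsFactors = FALSE),
    data.frame(from = latent, to = c(hub, anti, generic),
               stringsAsFactors = FALSE)
  )
  dag <- DAGStructure(nodes, edges)

  tables <- list()
  tables[[latent]] <- list(parents = character(0), p1 = 0.5)
  tables[[hub]] <- list(parents = latent, p1 = c(0.35, 0.65))
  tables[[anti]] <- list(parents = latent, p1 = c(0.45, 0.15))
  for (m in generic) {
    tables[[m]] <- list(parents = latent, p1 = c(0.15, 0.45))
  }
  for (m in hub_children) {
    tables[[m]] <- list(parents = hub, p1 = c(0.15, 0.85))
  }
  scenario <- PlantedScenario(dag, CPTSet(tables),
                              nSamples = nSamples, seed = seed)
  full <- forwardSample(scenario)
  out <- suppressWarnings(full[, all_marks])
  attr(out, "scenario") <- scenario
  out
}

#' Plant a binary outcome node on top of a mark matrix scenario
#'
#' Extends a planted scenario with one extra node (default `"splicing"`)
#' that is a noisy-OR child of the given parent marks. Used to test recovery
#' of marks directly adjacent to a splicing outcome.
#'
#' @param scenario a [PlantedScenario-class].
#' @param parents names of the outcome's parent nodes.
#' @param effect P(outcome = 1 | >= 1 parent on), in (0.5, 1].
#' @param outcome name of the outcome node.
#' @return a new [PlantedScenario-class] including the outcome node.
#' @export
plantOutcome <- function(scenario, parents, effect = 0.9,
                         outcome = "splicing") {
  stopifnot(is(scenario, "PlantedScenario"),
            all(parents %in% scenario@dag@nodes),
            !outcome %in% scenario@dag@nodes)
  dag <- DAGStructure(
    c(scenario@dag@nodes, outcome),
    rbind(scenario@dag@edges,
          data.frame(from = parents, to = outcome, stringsAsFactors = FALSE))
  )
  k <- length(parents)
  p1 <- rep(effect, 2^k)
  p1[1L] <- 1 - effect
  tables <- scenario@cpts@tables
  tables[[outcome]] <- list(parents = parents, p1 = p1)
  PlantedScenario(dag, CPTSet(tables), nSamples = scenario@nSamples,
                  seed = scenario@seed)
}

#' Export a scenario's answer key as JSON
#'
#' Writes the true DAG and CPTs of a planted scenario, so a simulated TSV
#' matrix ships with a machine-readable ground truth for recovery tests.
#'
#' @param scenario a [PlantedScenario-class].
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
writeScenarioKey <- function(scenario, path) {
  key <- list(
    nodes = scenario@dag@nodes,
    edges = scenario@dag@edges,
    nSamples = scenario@nSamples,
    seed = scenario@seed,
    cpts = lapply(scenario@cpts@tables, function(t) {
      list(parents = t$parents, p1 = t$p1)
    })
  )
  jsonlite::write_json(key, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
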