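test_that("planted DAG scenarios are seed-deterministic with exact edge counts", {
  a <- buildPlantedDag(38, 20, 3, 0.9, seed = 1, nSamples = 100)
  b <- buildPlantedDag(38, 20, 3, 0.9, seed = 1, nSamples = 100)
  expect_identical(edges(trueDag(a)), edges(trueDag(b)))
  expect_identical(nrow(edges(trueDag(a))), 20L)
  expect_identical(as.matrix(forwardSample(a)), as.matrix(forwardSample(b)))

  small <- buildPlantedDag(2, 1, 1, 0.9, seed = 3, nSamples = 10)
  expect_identical(nrow(edges(trueDag(small))), 1L)
  expect_true(validObject(trueDag(small)))   # acyclicity via validity

  # in-degree cap respected across seeds
  for (s in 1:5) {
    sc <- buildPlantedDag(10, 15, 2, 0.9, seed = s, nSamples = 10)
    expect_lte(max(table(edges(trueDag(sc))$to)), 2L)
    expect_identical(nrow(edges(trueDag(sc))), 15L)
  }
})

test_that("infeasible edge counts are rejected", {
  # with maxParents = 1 at most 2 edges fit on 3 nodes
  expect_error(buildPlantedDag(3, 4, 1, 0.9, seed = 1), "infeasible")
  expect_error(buildPlantedDag(2, 2, 1, 0.9, seed = 1), "infeasible")
  expect_error(buildPlantedDag(5, 3, 2, 0.4, seed = 1), "effect")
})

test_that("forward sampling honors the conditional probability tables", {
  # deterministic CPTs: constant-one column and an exact copy through an edge
  dag <- DAGStructure(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  cpts <- CPTSet(list(
    A = list(parents = character(0), p1 = 0.5),
    B = list(parents = "A", p1 = c(0, 1)),   # B copies A exactly
    C = list(parents = character(0), p1 = 1) # constant one
  ))
  mm <- forwardSample(PlantedScenario(dag, cpts, nSamples = 50, seed = 4))
  X <- as.matrix(mm)
  expect_identical(X[, "B"], X[, "A"])
  expect_identical(sum(X[, "C"]), 50L)
})

test_that("sampled marginals converge to CPT probabilities", {
  n <- 10000
  sc <- buildPlantedDag(6, 0, 2, 0.9, seed = 9, nSamples = n)
  X <- as.matrix(forwardSample(sc))
  se <- sqrt(0.25 / n)
  for (j in seq_len(ncol(X))) {
    expect_lt(abs(mean(X[, j]) - 0.5), 4 * se)
  }
})

test_that("planted edges show positive phi, disjoint components near-zero phi", {
  sc <- buildPlantedDag(38, 10, 3, 0.9, seed = 21, nSamples = 10000)
  X <- as.matrix(forwardSample(sc))
  e <- edges(trueDag(sc))
  for (i in seq_len(nrow(e))) {
    expect_gt(pearsonBinary(X[, e$from[i]], X[, e$to[i]]), 0)
  }
  # pairs in disjoint weakly-connected components are uncorrelated
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = nodes(trueDag(sc)))
  comp <- igraph::components(g)$membership
  nm <- names(comp)
  pairs <- utils::combn(nm, 2)
  cross <- pairs[, comp[pairs[1, ]] != comp[pairs[2, ]], drop = FALSE]
  phis <- vapply(seq_len(ncol(cross)), function(k) {
    abs(pearsonBinary(X[, cross[1, k]], X[, cross[2, k]]))
  }, numeric(1))
  expect_gte(mean(phis < 0.05), 0.95)
})

test_that("histone preset reproduces the reported correlation signs", {
  mm <- histonePreset(10000, seed = 5)
  expect_identical(marks(mm), markCatalog())
  cm <- as.matrix(correlationMatrix(mm))
  for (child in c("H3K4me1", "H3K4me2", "H3K79me1", "H3K9me1",
                  "H4K20me1", "H4K91ac")) {
    expect_gt(cm["H2BK5me1", child], 0)
  }
  others <- setdiff(markCatalog(), "H3K9me3")
  expect_lt(cm["H3K9me3", "H3K4me1"], 0)
  # negatively related to most of the remaining 37 marks
  expect_gte(mean(cm["H3K9me3", others] < 0), 0.9)

  expect_identical(as.matrix(histonePreset(500, seed = 7)),
                   as.matrix(histonePreset(500, seed = 7)))
})

test_that("plantOutcome appends a noisy-OR child of the chosen marks", {
  sc <- buildPlantedDag(6, 3, 2, 0.9, seed = 2, nSamples = 5000)
  pars <- nodes(trueDag(sc))[1:3]
  sc2 <- plantOutcome(sc, pars, effect = 0.9, outcome = "splicing")
  expect_true("splicing" %in% nodes(trueDag(sc2)))
  e <- edges(trueDag(sc2))
  expect_setequal(e$from[e$to == "splicing"], pars)
  X <- as.matrix(forwardSample(sc2))
  on_rate <- mean(X[rowSums(X[, pars, drop = FALSE]) > 0, "splicing"])
  off_rate <- mean(X[rowSums(X[, pars, drop = FALSE]) == 0, "splicing"])
  expect_gt(on_rate, 0.85)
  expect_lt(off_rate, 0.15)
})

test_that("scenario answer keys serialize to JSON", {
  sc <- buildPlantedDag(5, 3, 2, 0.9, seed = 8, nSamples = 10)
  f <- tempfile(fileext = ".json")
  writeScenarioKey(sc, f)
  key <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(key$nodes, nodes(trueDag(sc)))
  expect_identical(nrow(key$edges), 3L)
})
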