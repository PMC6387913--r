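test_that("fold plans partition samples evenly and reproducibly", {
  fp <- makeFolds(100, 10, seed = 1)
  expect_identical(unname(tabulate(foldAssignments(fp), 10)), rep(10L, 10))

  fp2 <- makeFolds(105, 10, seed = 1)
  sizes <- sort(tabulate(foldAssignments(fp2), 10))
  expect_identical(sizes, c(rep(10L, 5), rep(11L, 5)))

  expect_identical(foldAssignments(makeFolds(57, 10, seed = 9)),
                   foldAssignments(makeFolds(57, 10, seed = 9)))
  expect_error(makeFolds(5, 10, seed = 1), "n >= k")
})

test_that("ten fundamental networks are learned, acyclic and deterministic", {
  pair <- with_seed_local(3, rbinom(300, 1, 0.5))
  noise <- with_seed_local(4, rbinom(300, 1, 0.3))
  m <- tiny_matrix(as.vector(rbind(pair, pair, noise)), c("A", "B", "C"))
  fp <- makeFolds(300, 10, seed = 2)
  nets <- learnFundamentalNetworks(m, fp, LearnConfig())
  expect_length(nets, 10L)
  for (nw in nets) {
    expect_true(validObject(nw))
    # the copied pair must be linked (either direction) in every network
    expect_true(any((edges(nw)$from == "A" & edges(nw)$to == "B") |
                    (edges(nw)$from == "B" & edges(nw)$to == "A")))
  }
  nets2 <- learnFundamentalNetworks(m, fp, LearnConfig())
  expect_identical(lapply(nets, edges), lapply(nets2, edges))

  expect_error(learnFundamentalNetworks(m, makeFolds(200, 10, seed = 1),
                                        LearnConfig()),
               "fold plan")
})

test_that("the stability threshold keeps 7-of-10 pairs and drops 6-of-10", {
  nodes <- c("A", "B", "C")
  with_edge <- DAGStructure(nodes, data.frame(from = "A", to = "B"))
  without <- DAGStructure(nodes)
  nets7 <- c(rep(list(with_edge), 7), rep(list(without), 3))
  net <- buildConsensus(nets7, threshold = 7)
  expect_identical(nrow(edges(net)), 1L)
  expect_identical(edges(net)$skeleton_count, 7L)

  nets6 <- c(rep(list(with_edge), 6), rep(list(without), 4))
  expect_identical(nrow(edges(buildConsensus(nets6, threshold = 7))), 0L)
})

test_that("skeleton counting pools directions; majority resolves them", {
  nodes <- c("A", "B")
  ab <- DAGStructure(nodes, data.frame(from = "A", to = "B"))
  ba <- DAGStructure(nodes, data.frame(from = "B", to = "A"))
  net <- buildConsensus(c(rep(list(ab), 6), rep(list(ba), 4)), threshold = 7)
  e <- edges(net)
  expect_identical(nrow(e), 1L)
  expect_identical(e$skeleton_count, 10L)
  expect_identical(e$from, "A")
  expect_identical(e$directed_count, 6L)
  expect_identical(e$reverse_count, 4L)
  expect_identical(e$flag, "")

  # a direction tie goes to the lexicographically smaller parent, flagged
  tie <- buildConsensus(c(rep(list(ab), 5), rep(list(ba), 5)), threshold = 7)
  expect_identical(edges(tie)$from, "A")
  expect_match(edges(tie)$flag, "direction_tie")

  # the strict directed reading is available
  strict <- buildConsensus(c(rep(list(ab), 6), rep(list(ba), 4)),
                           threshold = 7, edgeIdentity = "directed")
  expect_identical(nrow(edges(strict)), 0L)
})

test_that("consensus of identical networks is that network at any threshold", {
  mm <- forwardSample(buildPlantedDag(6, 5, 2, 0.9, seed = 9, nSamples = 400))
  dag <- hillClimb(mm)
  for (thr in c(1, 5, 10)) {
    net <- buildConsensus(rep(list(dag), 10), threshold = thr)
    expect_same_edges(edges(net), edges(dag))
    expect_true(all(edges(net)$skeleton_count == 10L))
  }
})

test_that("raising the threshold never adds edges", {
  mm <- forwardSample(buildPlantedDag(8, 6, 2, 0.7, seed = 23, nSamples = 250))
  nets <- learnFundamentalNetworks(mm, makeFolds(250, 10, seed = 23),
                                   LearnConfig())
  prev <- NULL
  for (thr in 1:10) {
    keys <- skeleton_keys(edges(buildConsensus(nets, threshold = thr)))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("consensus cycles are resolved to a DAG with flags", {
  nodes <- c("A", "B", "C")
  n1 <- DAGStructure(nodes, data.frame(from = c("A", "C"), to = c("B", "A")))
  n2 <- DAGStructure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  n3 <- DAGStructure(nodes, data.frame(from = c("C", "B"), to = c("A", "C")))
  nets <- c(rep(list(n1), 4), rep(list(n2), 4), rep(list(n3), 2))
  # majority directions: A->B (8/8), B->C (6/6), C->A (6/6): a directed cycle
  net <- buildConsensus(nets, threshold = 5)
  expect_true(validObject(net))               # acyclic post-resolution
  expect_identical(nrow(edges(net)), 3L)
  expect_true(any(grepl("cycle_", edges(net)$flag)))
})

test_that("consensus annotates edges with full-data correlation signs", {
  x <- with_seed_local(11, rbinom(400, 1, 0.5))
  m <- tiny_matrix(as.vector(rbind(x, x, 1L - x)), c("A", "B", "C"))
  cm <- correlationMatrix(m)
  dag <- DAGStructure(c("A", "B", "C"),
                      data.frame(from = c("A", "A"), to = c("B", "C")))
  net <- buildConsensus(rep(list(dag), 10), threshold = 7, cm = cm)
  e <- edges(net)
  expect_identical(e$correlation_sign[e$to == "B"], "+")
  expect_identical(e$correlation_sign[e$to == "C"], "-")
  expect_equal(e$correlation_value[e$to == "B"], 1)

  # undefined correlation -> sign "undefined", not an error
  mc <- tiny_matrix(c(1, 1, 1, 0, 1, 1, 1, 0, 1), c("A", "B", "C"))
  netu <- buildConsensus(rep(list(dag), 10), threshold = 7,
                         cm = correlationMatrix(mc))
  expect_true("undefined" %in% edges(netu)$correlation_sign)

  bad <- DAGStructure(c("A", "B", "Z"))
  expect_error(buildConsensus(list(dag, bad), threshold = 1), "node set")
  expect_error(buildConsensus(rep(list(dag), 10), threshold = 11), "1..10")
})

test_that("the protocol wrapper supports repeated rounds with scaled threshold", {
  mm <- forwardSample(buildPlantedDag(5, 4, 2, 0.9, seed = 15, nSamples = 300))
  net <- consensusProtocol(mm, LearnConfig(), k = 5, threshold = 4,
                           rounds = 2, seed = 1)
  expect_identical(net@nNetworks, 10L)
  expect_identical(stabilityThreshold(net), 8L)
  expect_length(attr(net, "foldPlans"), 2L)
  expect_true(validObject(net))
})
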