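test_that("patterns are connected components of size >= 2", {
  nodes <- markCatalog()
  net <- consensus_of(nodes, data.frame(from = c("H3K4me1", "H3K4me2", "H4K5ac"),
                                        to = c("H3K4me2", "H3K4me3", "H4K8ac")))
  rep <- findPatterns(net)
  expect_identical(nEdges(rep), 3L)
  expect_length(patterns(rep), 2L)
  expect_setequal(patterns(rep)[[1]], c("H3K4me1", "H3K4me2", "H3K4me3"))
  expect_setequal(patterns(rep)[[2]], c("H4K5ac", "H4K8ac"))
  expect_length(singletons(rep), 33L)
  expect_lte(length(patterns(rep)), nEdges(rep))
})

test_that("an empty network yields zero patterns and 38 singletons", {
  rep <- findPatterns(consensus_of(markCatalog(),
                                   data.frame(from = character(0),
                                              to = character(0)),
                                   threshold = 1))
  expect_length(patterns(rep), 0L)
  expect_length(singletons(rep), 38L)
  expect_identical(nEdges(rep), 0L)
})

test_that("patterns are invariant to edge direction", {
  nodes <- LETTERS[1:6]
  fwd <- findPatterns(consensus_of(nodes, data.frame(from = c("A", "B"),
                                                     to = c("B", "C"))))
  rev <- findPatterns(consensus_of(nodes, data.frame(from = c("B", "C"),
                                                     to = c("A", "B"))))
  expect_identical(patterns(fwd), patterns(rev))
  expect_identical(singletons(fwd), singletons(rev))
})

test_that("directMarks returns the sorted adjacency of the outcome node", {
  nodes <- c("H3K36me3", "H3K79me1", "H4K5ac", "splicing")
  net <- consensus_of(nodes,
                      data.frame(from = c("H3K36me3", "splicing"),
                                 to = c("splicing", "H3K79me1")))
  expect_identical(directMarks(net, "splicing"), c("H3K36me3", "H3K79me1"))

  isolated <- consensus_of(nodes, data.frame(from = "H3K36me3",
                                             to = "H3K79me1"))
  expect_identical(directMarks(isolated, "splicing"), character(0))
  expect_error(directMarks(net, "H3K4me3"), "not in the network")
})

test_that("appendOutcomeColumn stacks classes with a labeled outcome", {
  xi <- tiny_matrix(c(1, 0, 0, 1, 1, 1), c("A", "B"), class = "included")
  xe <- tiny_matrix(c(0, 0, 1, 0), c("A", "B"), class = "excluded")
  comb <- appendOutcomeColumn(xi, xe)
  expect_identical(dim(comb), c(5L, 3L))
  expect_identical(marks(comb), c("A", "B", "splicing"))
  expect_identical(as.matrix(comb)[, "splicing"],
                   stats::setNames(c(1L, 1L, 1L, 0L, 0L),
                                   rownames(as.matrix(comb))))
  bad <- tiny_matrix(c(1, 0, 1, 0), c("A", "C"))
  expect_error(appendOutcomeColumn(xi, bad), "same marks")
})

test_that("network diffs partition the skeleton union and are symmetric", {
  nodes <- LETTERS[1:5]
  base <- data.frame(from = c("A", "B", "D"), to = c("B", "C", "E"))
  na_ <- consensus_of(nodes, base)
  nb <- consensus_of(nodes, rbind(base[1:2, ],
                                  data.frame(from = "C", to = "D")))
  d <- diffNetworks(na_, nb)
  expect_identical(nrow(d@onlyA), 1L)
  expect_identical(paste(d@onlyA$a, d@onlyA$b), "D E")
  expect_identical(nrow(d@onlyB), 1L)
  expect_identical(paste(d@onlyB$a, d@onlyB$b), "C D")
  expect_identical(nrow(d@shared), 2L)
  # partition: the three sets cover the skeleton union exactly once
  all_pairs <- c(paste(d@onlyA$a, d@onlyA$b), paste(d@onlyB$a, d@onlyB$b),
                 paste(d@shared$a, d@shared$b))
  expect_identical(sort(all_pairs),
                   sort(unique(c(skeleton_keys(edges(na_)),
                                 skeleton_keys(edges(nb))))))

  swapped <- diffNetworks(nb, na_)
  expect_identical(swapped@onlyA, d@onlyB)
  expect_identical(swapped@onlyB, d@onlyA)

  same <- diffNetworks(na_, na_)
  expect_identical(nrow(same@onlyA), 0L)
  expect_identical(nrow(same@onlyB), 0L)
  expect_identical(nrow(same@shared), 3L)
  expect_true(all(same@shared$sign_agrees))

  expect_error(diffNetworks(na_, consensus_of(LETTERS[2:6], base[2, ])),
               "node set")
})

test_that("planted outcome neighbors are recovered through the full protocol", {
  sc <- buildPlantedDag(12, 6, 2, 0.9, seed = 33, nSamples = 4000)
  pars <- nodes(trueDag(sc))[c(1, 4, 8)]
  mm <- forwardSample(plantOutcome(sc, pars, effect = 0.9))
  net <- consensusProtocol(mm, LearnConfig(), k = 10, threshold = 7, seed = 33)
  expect_identical(directMarks(net, "splicing"), sort(pars))
})

test_that("pattern and diff reports serialize to JSON", {
  nodes <- LETTERS[1:4]
  net <- consensus_of(nodes, data.frame(from = "A", to = "B"))
  f <- tempfile(fileext = ".json")
  writeReportJson(findPatterns(net), f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(j$n_edges, 1L)
  expect_identical(j$n_patterns, 1L)
  writeReportJson(diffNetworks(net, net), f)
  j2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(nrow(j2$shared_edges), 1L)
})
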