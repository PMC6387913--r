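test_that("BDeu local score matches the closed-form gamma expression", {
  m <- tiny_matrix(c(1, 0, 1, 0, 0, 0, 1, 0), c("A", "B"))  # A = 1,1,0,1
  got <- localScore("A", character(0), m, LearnConfig(score = "bdeu", ess = 1))
  # log[ G(1)/G(1+4) * G(0.5+3) G(0.5+1) / (G(0.5) G(0.5)) ]
  want <- lgamma(1) - lgamma(5) +
    lgamma(0.5 + 3) + lgamma(0.5 + 1) - 2 * lgamma(0.5)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("BIC rewards a perfect-copy parent and scores are row-permutation
           invariant", {
  n <- 16
  x <- rep(c(0L, 1L), n / 2)
  m <- tiny_matrix(as.vector(rbind(x, x)), c("A", "B"))
  cfg <- LearnConfig(score = "bic")
  expect_gte(localScore("B", "A", m, cfg),
             localScore("B", character(0), m, cfg))

  mm <- forwardSample(buildPlantedDag(4, 3, 2, 0.9, seed = 5, nSamples = 200))
  X <- as.matrix(mm)
  perm <- with_seed_local(2, sample(nrow(X)))
  mp <- suppressWarnings(ModificationMatrix(X[perm, ]))
  for (score in c("bdeu", "bic")) {
    cfg <- LearnConfig(score = score)
    expect_equal(localScore("V2", c("V1", "V3"), mm, cfg),
                 localScore("V2", c("V1", "V3"), mp, cfg), tolerance = 1e-12)
  }
  expect_error(localScore("V2", c("V2"), mm, LearnConfig()), "itself")
})

test_that("network score decomposes over families", {
  mm <- forwardSample(buildPlantedDag(5, 4, 2, 0.9, seed = 6, nSamples = 300))
  cfg <- LearnConfig()
  nm <- marks(mm)
  empty <- DAGStructure(nm)
  expect_equal(networkScore(empty, mm, cfg),
               sum(vapply(nm, function(v) {
                 localScore(v, character(0), mm, cfg)
               }, numeric(1))), tolerance = 1e-12)

  one <- DAGStructure(nm, data.frame(from = nm[1], to = nm[2]))
  delta <- networkScore(one, mm, cfg) - networkScore(empty, mm, cfg)
  expect_equal(delta,
               localScore(nm[2], nm[1], mm, cfg) -
                 localScore(nm[2], character(0), mm, cfg),
               tolerance = 1e-12)
  expect_error(networkScore(DAGStructure(c(nm, "Z")), mm, cfg), "missing")
})

test_that("2-node network score equals a brute-force joint-count oracle", {
  mm <- forwardSample(buildPlantedDag(2, 1, 1, 0.8, seed = 12, nSamples = 250))
  X <- as.matrix(mm)
  nm <- colnames(X)
  cfg <- LearnConfig(score = "bdeu", ess = 1)
  dag <- DAGStructure(nm, data.frame(from = nm[1], to = nm[2]))
  # oracle: family terms computed straight from the 2x2 joint counts
  n <- nrow(X)
  n1a <- sum(X[, 1])
  joint <- table(factor(X[, 1], 0:1), factor(X[, 2], 0:1))
  s_a <- lgamma(1) - lgamma(1 + n) +
    lgamma(0.5 + n1a) + lgamma(0.5 + n - n1a) - 2 * lgamma(0.5)
  s_b <- 0
  for (j in 1:2) {
    nj <- sum(joint[j, ])
    s_b <- s_b + lgamma(0.5) - lgamma(0.5 + nj) +
      sum(lgamma(0.25 + joint[j, ]) - lgamma(0.25))
  }
  expect_equal(networkScore(dag, mm, cfg), s_a + s_b, tolerance = 1e-10)
})

test_that("hill climbing links a perfect copy by exactly one edge and matches
           the exhaustive 3-graph comparison", {
  pair <- with_seed_local(7, rbinom(500, 1, 0.5))
  m <- tiny_matrix(as.vector(rbind(pair, pair)), c("A", "B"))
  dag <- hillClimb(m)
  expect_identical(nrow(edges(dag)), 1L)
  expect_equal(attr(dag, "score"), attr(exhaustiveSearch(m), "score"),
               tolerance = 1e-9)
})

test_that("hill climbing on independent columns returns a near-empty graph
           under BIC", {
  mm <- forwardSample(buildPlantedDag(38, 0, 3, 0.9, seed = 17,
                                      nSamples = 10000))
  dag <- hillClimb(mm, LearnConfig(score = "bic"))
  expect_lte(nrow(edges(dag)), 2L)
})

test_that("hill climbing is deterministic, acyclic, and monotone in score", {
  for (s in 1:5) {
    mm <- forwardSample(buildPlantedDag(6, 5, 2, 0.8, seed = 40 + s,
                                        nSamples = 250))
    d1 <- hillClimb(mm)
    d2 <- hillClimb(mm)
    expect_identical(edges(d1), edges(d2))
    expect_true(validObject(d1))              # acyclicity via validity
    trace <- attr(d1, "trace")
    expect_true(all(diff(trace) > 0))
    expect_equal(attr(d1, "score"), networkScore(d1, mm, LearnConfig()),
                 tolerance = 1e-9)
  }
})

test_that("restarted climbs never score below the deterministic climb", {
  mm <- forwardSample(buildPlantedDag(5, 4, 2, 0.7, seed = 77, nSamples = 400))
  base <- attr(hillClimb(mm), "score")
  rs <- attr(hillClimb(mm, LearnConfig(restarts = 3, seed = 1)), "score")
  expect_gte(rs, base - 1e-9)
})

test_that("DAG enumeration agrees with the inclusion-exclusion recurrence", {
  # Independent oracle: a(n) = sum_k (-1)^(k+1) C(n,k) 2^(k(n-k)) a(n-k)
  dag_count <- function(n) {
    a <- c(1)  # a(0)
    for (m in seq_len(n)) {
      a[m + 1] <- sum(vapply(seq_len(m), function(k) {
        (-1)^(k + 1) * choose(m, k) * 2^(k * (m - k)) * a[m - k + 1]
      }, numeric(1)))
    }
    a[n + 1]
  }
  expect_identical(length(enumerateDags(1)), 1L)
  expect_identical(length(enumerateDags(2)), as.integer(dag_count(2)))  # 3
  expect_identical(length(enumerateDags(3)), as.integer(dag_count(3)))  # 25
  expect_identical(length(enumerateDags(4)), as.integer(dag_count(4)))  # 543
  expect_true(all(vapply(enumerateDags(3), histoneBN:::is_acyclic_adj,
                         logical(1))))
})

test_that("exhaustive search refuses large node sets and handles p = 2", {
  mm <- forwardSample(buildPlantedDag(6, 3, 2, 0.9, seed = 3, nSamples = 50))
  expect_error(exhaustiveSearch(mm), "refusing")
  m2 <- suppressWarnings(mm[, 1:2])
  best <- exhaustiveSearch(m2)
  expect_s4_class(best, "DAGStructure")
  expect_gte(attr(best, "score"), attr(hillClimb(m2), "score") - 1e-9)
})

test_that("exhaustive search dominates hill climbing on random 4-node data", {
  for (s in 1:10) {
    sc <- buildPlantedDag(4, (s %% 5), 3, 0.8, seed = 50 + s, nSamples = 300)
    mm <- forwardSample(sc)
    h <- attr(hillClimb(mm), "score")
    e <- attr(exhaustiveSearch(mm), "score")
    expect_lte(h, e + 1e-9)
  }
})
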