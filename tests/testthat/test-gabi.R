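test_that("branch thresholds anchor on the pool's rank extremes", {
  gs <- sprintf("g%d", 1:10)
  ot <- new("NormalizedOmega",
            values = matrix(c(seq(0.1, 0.9, length.out = 9), 0.93), 10, 1,
                            dimnames = list(gs, "b1")))
  pools <- list(high = list(b1 = c("g10", "g9")),
                low = list(b1 = c("g1", "g2")))
  hi <- branchThresholds(ot, pools, "b1", "high")
  expect_equal(unname(hi$omegaLo["b1"]), 0.9)   # min omega-tilde over pool
  expect_equal(unname(hi$omegaHi["b1"]), Inf)
  lo <- branchThresholds(ot, pools, "b1", "low")
  expect_equal(unname(lo$omegaHi["b1"]), 0.2)

  # tied low pool: the shared tied value is the cutoff
  ot2 <- new("NormalizedOmega",
             values = matrix(c(0.25, 0.25, 0.6, 1), 4, 1,
                             dimnames = list(gs[1:4], "b1")))
  pools2 <- list(high = list(), low = list(b1 = c("g1", "g2")))
  expect_equal(unname(branchThresholds(ot2, pools2, "b1",
                                       "low")$omegaHi["b1"]), 0.25)

  # branch-specific: different pools give different thresholds
  v3 <- cbind(b1 = c(0.5, 0.9, 1), b2 = c(1, 0.4, 0.7))
  rownames(v3) <- gs[1:3]
  ot3 <- new("NormalizedOmega", values = v3)
  pools3 <- list(high = list(b1 = c("g2", "g3"), b2 = c("g1", "g3")),
                 low = list())
  t1 <- branchThresholds(ot3, pools3, "b1", "high")
  t2 <- branchThresholds(ot3, pools3, "b2", "high")
  expect_false(unname(t1$omegaLo["b1"]) == unname(t2$omegaLo["b2"]))
  expect_error(branchThresholds(ot, list(high = list(), low = list()),
                                "b1", "high"), "empty")
})

test_that("binarization applies inclusive windows and zeroes missing cells", {
  X <- cbind(b1 = c(0.95, 0.5, NA), n1 = c(0.75, 0.9, 0.8),
             n2 = c(0.2, 1, 0.74))
  rownames(X) <- sprintf("g%d", 1:3)
  an <- new("AnalysisMatrix", values = X,
            columnClass = c("omega", "network", "network"))
  spec <- list(omegaLo = c(b1 = 0.9), omegaHi = c(b1 = Inf),
               networkMin = 0.75)
  inc <- binarize(an, spec)
  expect_equal(unname(inc[1, ]), c(1, 1, 0))  # boundary 0.75 inclusive
  expect_equal(unname(inc[2, ]), c(0, 1, 1))
  expect_equal(unname(inc[3, ]), c(0, 1, 0))  # missing omega -> 0

  allIn <- binarize(an, list(omegaLo = c(b1 = -Inf),
                             omegaHi = c(b1 = Inf), networkMin = -Inf))
  expect_equal(sum(allIn[1:2, ]), 6)
})

test_that("bicluster scores count area, optionally weighted", {
  b <- Bicluster(genes = c("a", "b", "c"), branches = "b1",
                 networks = c("n1", "n2"))
  expect_equal(scoreBicluster(b, gabiParams()), 9)
  expect_equal(scoreBicluster(b, gabiParams(do_weighting = TRUE)),
               3 * (2 * 1 + 1 * 2))
})

test_that("the GA finds trivial optima and respects minimum support", {
  empty <- matrix(0L, 20, 5,
                  dimnames = list(sprintf("g%d", 1:20),
                                  c("om", sprintf("n%d", 1:4))))
  attr(empty, "columnClass") <- c("omega", rep("network", 4))
  expect_length(gabiSearch(empty, params = smallGabiParams(seed = 1)), 0)

  ones <- matrix(1L, 50, 10,
                 dimnames = list(sprintf("g%d", 1:50),
                                 c("om", sprintf("n%d", 1:9))))
  attr(ones, "columnClass") <- c("omega", rep("network", 9))
  res <- gabiSearch(ones, params = gabiParams(
    amountOfBiclusterSearches = 1, popsize = 120, generations = 60,
    seed = 2))
  expect_length(res, 1)
  expect_equal(score(res[[1]]), 500)           # the entire matrix
  expect_length(genes(res[[1]]), 50)
  expect_length(networks(res[[1]]), 9)
})

test_that("emitted biclusters satisfy the membership constraint", {
  for (seed in 1:3) {
    inc <- randomIncidence(120, 8, density = 0.4, seed = seed)
    res <- gabiSearch(inc, params = smallGabiParams(seed = seed))
    for (b in res) {
      block <- inc[genes(b), c(branches(b), networks(b)), drop = FALSE]
      expect_true(all(block == 1L))
    }
  }
})

test_that("the GA search is deterministic under a fixed seed", {
  inc <- randomIncidence(150, 10, density = 0.35, seed = 9)
  r1 <- gabiSearch(inc, params = smallGabiParams(seed = 42))
  r2 <- gabiSearch(inc, params = smallGabiParams(seed = 42))
  expect_equal(lapply(r1, genes), lapply(r2, genes))
  expect_equal(lapply(r1, networks), lapply(r2, networks))
  expect_equal(vapply(r1, score, numeric(1)),
               vapply(r2, score, numeric(1)))
})

test_that("tabu masking of networks forbids reusing qualifying cells", {
  inc <- randomIncidence(200, 10, density = 0.45, seed = 4)
  res <- gabiSearch(inc, params = smallGabiParams(
    seed = 5, variableClassNotOnTabuList = c(TRUE, FALSE)))
  if (length(res) >= 2) {
    for (i in seq_len(length(res) - 1)) {
      for (j in (i + 1):length(res)) {
        sharedGenes <- intersect(genes(res[[i]]), genes(res[[j]]))
        sharedNets <- intersect(networks(res[[i]]), networks(res[[j]]))
        expect_true(length(sharedGenes) == 0 || length(sharedNets) == 0)
      }
    }
  } else {
    succeed("fewer than two biclusters emitted; nothing to compare")
  }
})

test_that("the parameter-cycling loop covers all four combinations", {
  inc <- randomIncidence(150, 8, density = 0.45, seed = 6)
  p <- smallGabiParams(seed = 11, global_optim = 4L,
                       amountOfBiclusterSearches = 2L)
  res <- globalOptimLoop(inc, params = p)
  combos <- vapply(res, function(b) b@runMetadata$combo, numeric(1))
  expect_true(all(combos %in% 1:4))
  expect_gte(length(unique(combos)), 3)

  p8 <- smallGabiParams(seed = 11, global_optim = 8L,
                        amountOfBiclusterSearches = 1L)
  res8 <- globalOptimLoop(inc, params = p8)
  its <- vapply(res8, function(b) b@runMetadata$iteration, numeric(1))
  seeds <- vapply(res8, function(b) b@runMetadata$seed, numeric(1))
  # a combination rerun in a later cycle uses a distinct derived seed
  expect_equal(length(unique(seeds)), length(unique(its)))

  res8b <- globalOptimLoop(inc, params = p8)
  expect_equal(lapply(res8, genes), lapply(res8b, genes))
})

test_that("merging follows the overlap-or-same-networks rule", {
  mk <- function(g, n) Bicluster(genes = g, branches = "b1", networks = n,
                                 score = length(g) * (1 + length(n)))
  A <- mk(sprintf("g%d", 1:10), c("n1", "n2"))
  B <- mk(sprintf("g%d", 6:13), c("n3", "n4"))    # 5 shared / min 8 = 0.625
  merged <- mergeBiclusters(list(A, B))
  expect_length(merged, 1)
  expect_length(genes(merged[[1]]), 13)
  expect_equal(score(merged[[1]]), 13 * (1 + 4))

  # disjoint genes but identical networks merge too
  C <- mk(sprintf("h%d", 1:6), c("n1", "n2"))
  expect_length(mergeBiclusters(list(A, C)), 1)

  # disjoint genes and different networks stay separate
  D <- mk(sprintf("h%d", 1:6), c("n9",  "n8"))
  expect_length(mergeBiclusters(list(A, D)), 2)
})

test_that("merging is idempotent", {
  set.seed(12)
  bcs <- lapply(1:8, function(i) {
    Bicluster(genes = sample(sprintf("g%d", 1:40), sample(5:15, 1)),
              branches = "b1",
              networks = sample(sprintf("n%d", 1:6), sample(1:3, 1)),
              score = 1)
  })
  once <- mergeBiclusters(bcs)
  twice <- mergeBiclusters(once)
  expect_equal(length(once), length(twice))
  expect_equal(lapply(once, genes), lapply(twice, genes))
  expect_equal(lapply(once, networks), lapply(twice, networks))
})
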