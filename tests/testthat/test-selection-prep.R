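makeOmega <- function(values, status) {
  g <- sprintf("g%d", seq_len(nrow(values)))
  b <- sprintf("b%d", seq_len(ncol(values)))
  OmegaTable(matrix(values, nrow(values), ncol(values),
                    dimnames = list(g, b)),
             status = matrix(status, nrow(values), ncol(values)))
}

test_that("relaxed constraints resolve dN=0, dS=0 and identical sequences", {
  om <- makeOmega(cbind(c(0.4, 2.7, NA, NA, NA, NA)),
                  cbind(c("STABLE", "STABLE", "DS_ZERO", "DN_ZERO",
                          "IDENTICAL", "UNSTABLE")))
  relaxed <- values(applyOmegaConstraints(om, "relaxed"))
  expect_equal(relaxed[3, 1], 2.7)     # dS = 0 -> branch maximum kept omega
  expect_equal(relaxed[4, 1], 0)       # dN = 0 -> purifying, omega 0
  expect_equal(relaxed[5, 1], 0)       # identical sequences -> neutral, 0
  expect_true(is.na(relaxed[6, 1]))    # unstable always filtered

  conservative <- values(applyOmegaConstraints(om, "conservative"))
  expect_true(all(is.na(conservative[3:6, 1])))
  expect_equal(conservative[1:2, 1], relaxed[1:2, 1])
})

test_that("conservative non-missing cells are a subset of relaxed ones", {
  set.seed(21)
  n <- 40
  vals <- matrix(runif(n * 3, 0, 3), n, 3)
  st <- matrix(sample(OMEGA_STATUS_CODES, n * 3, replace = TRUE), n, 3)
  vals[st != "STABLE"] <- NA
  om <- makeOmega(vals, st)
  consOK <- !is.na(values(applyOmegaConstraints(om, "conservative")))
  relOK <- !is.na(values(applyOmegaConstraints(om, "relaxed")))
  expect_true(all(relOK[consOK]))
})

test_that("unknown status codes are rejected", {
  om <- makeOmega(cbind(c(1, 2)), cbind(c("STABLE", "STABLE")))
  om@status[2, 1] <- "BOGUS"
  expect_error(applyOmegaConstraints(om), "unknown status")
})

test_that("omega rank normalization follows the printed formula", {
  # all-positive distinct branch: largest omega maps to exactly 1
  om <- makeOmega(cbind(c(0.2, 1.4, 0.9, 3.0, 0.5)), "STABLE")
  ot <- values(rankNormalizeOmega(om))
  expect_equal(ot[4, 1], 1)
  expect_equal(sort(unname(ot[, 1])), (1:5) / 5)

  # two positive distinct values -> (0.5, 1)
  om2 <- makeOmega(cbind(c(0.3, 2)), "STABLE")
  expect_equal(unname(values(rankNormalizeOmega(om2))[, 1]), c(0.5, 1))

  # ties, zeros and missing: brute-force direct-count oracle
  for (seed in 1:30) {
    set.seed(seed)
    x <- sample(c(0, 0, 0.5, 0.5, runif(6, 0, 3), NA, NA))
    om3 <- OmegaTable(matrix(x, ncol = 1,
                             dimnames = list(sprintf("g%d", 1:12), "b")))
    got <- values(rankNormalizeOmega(om3))[, 1]
    expect_equal(unname(got), oracleOmegaTilde(x))
  }
})

test_that("rank-normalized omega preserves raw order within a branch", {
  set.seed(31)
  x <- c(rexp(30), rep(0, 5), NA)
  om <- OmegaTable(matrix(x, ncol = 1,
                          dimnames = list(sprintf("g%d", 1:36), "b")))
  ot <- values(rankNormalizeOmega(om))[, 1]
  ok <- which(!is.na(x))
  for (a in ok) for (b in ok) {
    if (x[a] < x[b]) expect_lte(ot[a], ot[b])
  }
})

test_that("a branch without positive omega comes back missing with a warning", {
  om <- makeOmega(cbind(c(0, 0, 0)), "STABLE")
  expect_warning(res <- rankNormalizeOmega(om), "no strictly positive")
  expect_true(all(is.na(values(res))))
})

test_that("gene pools split at the thresholds and harmonize by truncation", {
  om <- makeOmega(cbind(c(0, 0.2, 1.5, 3.0)), "STABLE")
  pools <- buildGenePools(om, harmonize = FALSE)
  expect_setequal(pools$high$b1, c("g3", "g4"))
  expect_identical(pools$low$b1, "g1")

  # two branches with high sizes 3 and 2 -> both truncated to 2,
  # keeping the largest-omega genes
  vals <- cbind(b1 = c(1.2, 1.8, 2.5, 0, 0),
                b2 = c(3.0, 1.1, 0.5, 0, 0))
  om2 <- OmegaTable(matrix(vals, 5, 2,
                           dimnames = list(sprintf("g%d", 1:5),
                                           c("b1", "b2"))))
  pools2 <- buildGenePools(om2)
  expect_identical(pools2$high$b1, c("g3", "g2"))
  expect_identical(pools2$high$b2, c("g1", "g2"))
  expect_true(all(pools2$highSize == 2))

  # equal sizes are a fixed point
  pools3 <- buildGenePools(om2, harmonize = FALSE)
  pools3h <- buildGenePools(om2)
  expect_equal(lengths(pools3$low), lengths(pools3h$low))

  # an empty pool names the offending branch
  vals[, 2] <- c(0.5, 0.4, 0.5, 0, 0)
  om3 <- OmegaTable(matrix(vals, 5, 2,
                           dimnames = list(sprintf("g%d", 1:5),
                                           c("b1", "b2"))))
  expect_error(buildGenePools(om3), "b2")
})

test_that("high and low pools never overlap within a branch", {
  set.seed(5)
  for (i in 1:5) {
    vals <- matrix(c(runif(40, 0, 3), rep(0, 8)), ncol = 2)[sample(24), ]
    dimnames(vals) <- list(sprintf("g%d", 1:24), c("b1", "b2"))
    pools <- buildGenePools(OmegaTable(vals), harmonize = FALSE)
    for (b in c("b1", "b2"))
      expect_length(intersect(pools$high[[b]], pools$low[[b]]), 0)
  }
})

test_that("spatial gene filter keeps genes with any |r| above threshold", {
  r <- matrix(c(0.05, -0.09, 0.02,
                0.5, 0.0, 0.01,
                -0.3, 0.08, 0.0), 3, 3,
              dimnames = list(sprintf("n%d", 1:3), c("dull", "pos", "neg")))
  expect_setequal(filterSpatialGenes(CorrelationMatrix(r)), c("pos", "neg"))
  expect_identical(filterSpatialGenes(CorrelationMatrix(r),
                                      absolute = FALSE), "pos")
  expect_setequal(filterSpatialGenes(CorrelationMatrix(r), threshold = 0),
                  c("dull", "pos", "neg"))
})

test_that("correlation rank normalization follows the printed formula", {
  # per gene the top network reaches exactly 1; 3 distinct values give
  # (1/3 -> 0 after min-zeroing, 2/3, 1)
  r <- matrix(c(0.2, 0.5, 0.9), 3, 1,
              dimnames = list(sprintf("n%d", 1:3), "g"))
  rn <- values(rankNormalizeCorrelations(CorrelationMatrix(r)))
  expect_equal(unname(rn["g", ]), c(0, 2/3, 1))

  # a gene below 0.1 everywhere is zeroed entirely
  low <- matrix(c(0.05, -0.08, 0.09), 3, 1,
                dimnames = list(sprintf("n%d", 1:3), "g"))
  expect_equal(unname(values(
    rankNormalizeCorrelations(CorrelationMatrix(low)))["g", ]),
    c(0, 0, 0))

  # randomized oracle including ties and missing entries
  for (seed in 1:30) {
    set.seed(seed + 50)
    x <- sample(c(round(runif(8), 1), NA, NA))
    r3 <- matrix(x, 10, 1, dimnames = list(sprintf("n%d", 1:10), "g"))
    got <- values(rankNormalizeCorrelations(CorrelationMatrix(r3)))["g", ]
    expect_equal(unname(got), oracleRTilde(x, 10))
  }
})

test_that("correlation rank normalization is monotone-transform invariant", {
  set.seed(77)
  x <- runif(8, -0.9, 0.9)
  r1 <- CorrelationMatrix(matrix(x, 8, 1,
                                 dimnames = list(sprintf("n%d", 1:8), "g")))
  r2 <- CorrelationMatrix(matrix(tanh(2 * x), 8, 1,
                                 dimnames = list(sprintf("n%d", 1:8), "g")))
  expect_equal(values(rankNormalizeCorrelations(r1)),
               values(rankNormalizeCorrelations(r2)))
})

test_that("retained-gene flag honours the 0.75 criterion on either scale", {
  r <- matrix(c(0.8, 0.3, 0.2, 0.15,
                0.2, 0.18, 0.15, 0.12), 4, 2,
              dimnames = list(sprintf("n%d", 1:4), c("strong", "weak")))
  rn <- rankNormalizeCorrelations(CorrelationMatrix(r))
  # every gene's top network is rank 1 -> both retained on normalized scale
  expect_setequal(retainedGenes(rn), c("strong", "weak"))
  rnRaw <- rankNormalizeCorrelations(CorrelationMatrix(r), filterOn = "raw")
  expect_identical(retainedGenes(rnRaw), "strong")
})

test_that("concatenation assembles [omega | networks] for retained genes", {
  gs <- sprintf("g%d", 1:6)
  om <- OmegaTable(matrix(c(runif(5, 0.1, 2), NA), 6, 1,
                          dimnames = list(gs, "b1")))
  ot <- rankNormalizeOmega(om)
  r <- matrix(runif(4 * 6, -1, 1), 4, 6,
              dimnames = list(sprintf("n%d", 1:4), gs))
  rn <- rankNormalizeCorrelations(CorrelationMatrix(r), lowCorrCut = 0)
  expect_message(an <- concatenateAnalysis(ot, "b1", rn, gs), "dropped")
  expect_equal(dim(values(an)), c(5L, 5L))
  expect_identical(columnClasses(an), c("omega", rep("network", 4)))
  expect_identical(colnames(values(an))[1], "b1")
  expect_error(concatenateAnalysis(ot, "b1", rn, "absent"),
               "no genes left")
  expect_error(concatenateAnalysis(ot, "nope", rn), "branch not present")
})
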