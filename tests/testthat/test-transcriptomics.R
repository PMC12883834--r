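test_that("spearman correlation honours monotone transforms and pairwise deletion", {
  siteIds <- sprintf("s%02d", 1:20)
  set.seed(2)
  prof <- rnorm(20)
  fn <- FNSiteMatrix(matrix(prof, 1, 20, dimnames = list("net", siteIds)))
  exprVals <- rbind(
    same = prof,
    increasing = exp(prof),          # strictly increasing transform
    decreasing = -prof^3 - prof)     # strictly decreasing transform
  colnames(exprVals) <- siteIds
  expr <- ExpressionMatrix(exprVals)
  r <- values(spearmanCorrelate(expr, fn))
  expect_equal(unname(r["net", ]), c(1, 1, -1))

  # interleaved missing values: rank-then-product-moment oracle on the
  # complete-pair subset
  g <- rnorm(20); g[c(2, 5, 9)] <- NA
  f2 <- prof; f2[c(5, 12)] <- NA
  exprNA <- ExpressionMatrix(matrix(g, 1, 20,
                                    dimnames = list("gene", siteIds)))
  fnNA <- FNSiteMatrix(matrix(f2, 1, 20, dimnames = list("net", siteIds)))
  ok <- !is.na(g) & !is.na(f2)
  oracle <- cor(rank(g[ok]), rank(f2[ok]))
  expect_equal(values(spearmanCorrelate(exprNA, fnNA))[1, 1], oracle)
})

test_that("entries with too few complete pairs are missing and disjoint sites error", {
  siteIds <- sprintf("s%d", 1:5)
  g <- c(1, 2, NA, NA, NA)
  f <- c(2, 1, 3, NA, NA)
  expr <- ExpressionMatrix(matrix(g, 1, 5, dimnames = list("g", siteIds)))
  fn <- FNSiteMatrix(matrix(f, 1, 5, dimnames = list("n", siteIds)))
  expect_true(is.na(values(spearmanCorrelate(expr, fn))[1, 1]))

  fn2 <- FNSiteMatrix(matrix(1:5, 1, 5,
                             dimnames = list("n", paste0("other", 1:5))))
  expect_error(spearmanCorrelate(expr, fn2), "no shared sites")
})

test_that("domain clustering recovers planted groups and picks their k", {
  set.seed(7)
  centers <- matrix(rnorm(3 * 40, sd = 4), 3, 40)
  prof <- centers[rep(1:3, each = 5), ] + rnorm(15 * 40, sd = 0.5)
  dimnames(prof) <- list(sprintf("net%02d", 1:15), sprintf("g%02d", 1:40))
  corr <- CorrelationMatrix(prof / max(abs(prof)))
  da <- clusterDomains(corr, 2:8)
  expect_equal(da@k, 3L)
  truthLabels <- rep(1:3, each = 5)
  ari <- neuroselect:::.adjustedRandIndex(truthLabels, domainOf(da))
  expect_gte(ari, 0.9)
  expect_equal(unname(da@silhouetteByK[as.character(da@k)]),
               max(da@silhouetteByK))
})

test_that("duplicate network rows share a domain and bad k ranges error", {
  set.seed(8)
  prof <- matrix(runif(6 * 10, -1, 1), 6, 10,
                 dimnames = list(sprintf("n%d", 1:6), sprintf("g%d", 1:10)))
  prof[2, ] <- prof[1, ]
  corr <- CorrelationMatrix(prof)
  da <- clusterDomains(corr, 2:4)
  expect_identical(unname(domainOf(da)["n1"]), unname(domainOf(da)["n2"]))
  expect_error(clusterDomains(corr, 2:6), "kRange")
})

test_that("missing correlations are zero-imputed with a warning", {
  prof <- matrix(seq(-1, 1, length.out = 12), 4, 3,
                 dimnames = list(sprintf("n%d", 1:4), sprintf("g%d", 1:3)))
  prof[1, 2] <- NA
  expect_warning(clusterDomains(CorrelationMatrix(prof), 2:3),
                 "zero-imputed")
})

test_that("Dice coefficient evaluates the printed formula", {
  base <- array(0, c(4, 4, 4))
  A <- base; A[1:4, 1, 1] <- 1            # |A| = 4
  B <- base; B[3:4, 1, 1] <- 1; B[1:4, 2, 1] <- 1   # |B| = 6, overlap 2
  aff <- diag(4)
  vA <- VolumeMap(A, aff, "A"); vB <- VolumeMap(B, aff, "B")
  expect_equal(diceOverlap(vA, vB), 2 * 2 / (4 + 6))
  expect_equal(diceOverlap(vB, vA), diceOverlap(vA, vB))  # symmetric
  expect_equal(diceOverlap(vA, vA), 1)

  C <- base; C[1, 4, 4] <- 1              # disjoint from A
  expect_equal(diceOverlap(vA, VolumeMap(C, aff, "C")), 0)
  empty <- VolumeMap(base, aff, "E")
  expect_warning(d0 <- diceOverlap(empty, empty), "empty")
  expect_equal(d0, 0)
  wrong <- VolumeMap(array(0, c(3, 3, 3)), aff, "W")
  expect_error(diceOverlap(vA, wrong), "shape")
})

test_that("Pearson overlap matches the textbook formula", {
  set.seed(11)
  z <- rnorm(64)
  aff <- diag(4)
  vA <- VolumeMap(array(z, c(4, 4, 4)), aff, "A")
  vNeg <- VolumeMap(array(-z, c(4, 4, 4)), aff, "B")
  expect_equal(pearsonOverlap(vA, vA), 1)
  expect_equal(pearsonOverlap(vA, vNeg), -1)

  y <- rnorm(64)
  vY <- VolumeMap(array(y, c(4, 4, 4)), aff, "Y")
  oracle <- sum((z - mean(z)) * (y - mean(y))) /
    sqrt(sum((z - mean(z))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonOverlap(vA, vY), oracle)

  const <- VolumeMap(array(2, c(4, 4, 4)), aff, "C")
  expect_warning(res <- pearsonOverlap(vA, const), "constant")
  expect_true(is.na(res))
})

test_that("domain mean maps average voxelwise over the domain's networks", {
  aff <- diag(4)
  v1 <- VolumeMap(array(1, c(3, 3, 3)), aff, "n1")
  v3 <- VolumeMap(array(3, c(3, 3, 3)), aff, "n2")
  da <- new("DomainAssignment",
            assignment = c(n1 = "D1", n2 = "D1", n3 = "D2"),
            domains = c("D1", "D2"), k = 2L,
            silhouetteByK = c(`2` = 0.5))
  m <- domainMeanMap(list(v1, v3,
                          VolumeMap(array(9, c(3, 3, 3)), aff, "n3")),
                     da, "D1")
  expect_equal(unique(as.vector(m@grid)), 2)

  single <- domainMeanMap(list(v1, v3,
                               VolumeMap(array(9, c(3, 3, 3)), aff, "n3")),
                          da, "D2")
  expect_equal(unique(as.vector(single@grid)), 9)
  expect_error(domainMeanMap(list(v1), da, "D9"), "empty domain")

  # mean of two half-means equals the mean over the union for equal halves
  set.seed(3)
  g1 <- array(rnorm(27), c(3, 3, 3)); g2 <- array(rnorm(27), c(3, 3, 3))
  daAB <- new("DomainAssignment",
              assignment = c(a = "D", b = "D"), domains = "D", k = 1L,
              silhouetteByK = numeric())
  both <- domainMeanMap(list(VolumeMap(g1, aff, "a"),
                             VolumeMap(g2, aff, "b")), daAB, "D")
  expect_equal(both@grid, (g1 + g2) / 2)
})
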