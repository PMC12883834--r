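# Small in-code fixtures shared across test files.

# 1D-ish volume: voxel centres at x = 0, 2, 4, ... mm on the x axis
lineVolume <- function(z, networkId = "line") {
  VolumeMap(array(z, c(length(z), 1L, 1L)), diag(c(2, 2, 2, 1)), networkId)
}

# cubic volume with voxel centres at 2 mm spacing starting at the origin
cubeVolume <- function(values, n = 4L, networkId = "cube") {
  VolumeMap(array(values, c(n, n, n)), diag(c(2, 2, 2, 1)), networkId)
}

randomSites <- function(n, lim = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  SiteTable(sprintf("s%03d", seq_len(n)),
            matrix(runif(3 * n, -lim, lim), ncol = 3))
}

# brute-force oracle for the branch-wise omega rank normalization
oracleOmegaTilde <- function(x) {
  denom <- sum(!is.na(x) & x > 0)
  if (denom == 0L) return(rep(NA_real_, length(x)))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(NA_real_)
    (1 + sum(x[-i] < x[i], na.rm = TRUE)) / denom
  }, numeric(1))
}

# brute-force oracle for the per-gene correlation rank normalization
# (largest-tie ranks over non-missing entries, divided by #networks),
# followed by min-zeroing and the low-overall-correlation rule
oracleRTilde <- function(x, n, lowCorrCut = 0.1) {
  out <- vapply(seq_along(x), function(j) {
    if (is.na(x[j])) return(NA_real_)
    sum(x <= x[j], na.rm = TRUE) / n
  }, numeric(1))
  if (!all(is.na(out)))
    out[which(out == min(out, na.rm = TRUE))] <- 0
  mx <- suppressWarnings(max(abs(x), na.rm = TRUE))
  if (!is.finite(mx) || mx < lowCorrCut) out[] <- 0
  out[is.na(out)] <- 0
  out
}

# exhaustive maximum size score over network-column subsets
oracleMaxScore <- function(inc, minGenes = 5L, minNet = 1L) {
  nets <- which(attr(inc, "columnClass") == "network")
  om <- which(attr(inc, "columnClass") == "omega")
  best <- 0
  for (k in seq_along(nets)) {
    for (sub in utils::combn(nets, k, simplify = FALSE)) {
      cols <- c(om, sub)
      rows <- rowSums(inc[, cols, drop = FALSE]) == length(cols)
      if (sum(rows) >= minGenes && k >= minNet)
        best <- max(best, sum(rows) * length(cols))
    }
  }
  best
}

randomIncidence <- function(nGenes, nNet, density, seed) {
  set.seed(seed)
  inc <- matrix(rbinom(nGenes * (nNet + 1L), 1L, density), nGenes, nNet + 1L,
                dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                c("om", sprintf("n%02d", seq_len(nNet)))))
  attr(inc, "columnClass") <- c("omega", rep("network", nNet))
  inc
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

smallGabiParams <- function(...) {
  args <- list(amountOfBiclusterSearches = 4L, popsize = 120L,
               generations = 60L)
  override <- list(...)
  args[names(override)] <- override
  do.call(gabiParams, args)
}
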