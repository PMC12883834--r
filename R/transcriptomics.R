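# Gene-to-network spatial correlation, Ward clustering of networks into
# domains with silhouette model selection, and volumetric overlap measures.

#' Spearman correlation of gene expression with network site profiles
#'
#' Computes the rank correlation r(g, n) between every gene's expression
#' profile and every network's projected z-profile over the biopsy sites
#' shared by both matrices, using pairwise-complete observations. Entries
#' with fewer than 3 complete pairs are set missing.
#'
#' @param expr an [ExpressionMatrix-class] (genes x sites).
#' @param fn an [FNSiteMatrix-class] (networks x sites).
#' @param minPairs minimum complete pairs per entry. Default 3.
#' @return A [CorrelationMatrix-class] (networks x genes).
#' @export
spearmanCorrelate <- function(expr, fn, minPairs = 3L) {
  shared <- intersect(sites(expr), sites(fn))
  if (!length(shared)) stop("no shared sites between expression and FN data")
  G <- values(expr)[, shared, drop = FALSE]
  F <- values(fn)[, shared, drop = FALSE]
  r <- suppressWarnings(
    stats::cor(t(G), t(F), use = "pairwise.complete.obs",
               method = "spearman"))
  nPairs <- (!is.na(G)) %*% t(!is.na(F))
  r[nPairs < minPairs] <- NA_real_
  r[r > 1] <- 1; r[r < -1] <- -1   # guard rounding at |r| = 1
  CorrelationMatrix(t(r))
}

#' Cluster networks into domains by their gene-correlation profiles
#'
#' Agglomerative clustering of network rows of the correlation matrix with
#' Ward's minimum-variance method on squared Euclidean distances; the
#' number of domains is chosen by the average silhouette width over
#' `kRange` (ties broken toward smaller k). Missing correlations are
#' zero-imputed with a warning.
#'
#' @param corr a [CorrelationMatrix-class] (networks x genes).
#' @param kRange integer vector of candidate domain counts, within
#'   [2, #networks - 1]. Default 2:12.
#' @return A [DomainAssignment-class].
#' @export
clusterDomains <- function(corr, kRange = 2:12) {
  X <- values(corr)
  n <- nrow(X)
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie within [2, #networks - 1]")
  nMissing <- sum(is.na(X))
  if (nMissing > 0L) {
    warning(nMissing, " missing correlation(s) zero-imputed before clustering")
    X[is.na(X)] <- 0
  }
  d2 <- stats::dist(X)^2
  hc <- stats::hclust(d2, method = "ward.D")
  sil <- vapply(kRange, function(k) {
    labels <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(labels, d2)[, "sil_width"])
  }, numeric(1))
  names(sil) <- as.character(kRange)
  k <- kRange[which.max(sil)]   # which.max takes the first tie: smallest k
  labels <- stats::cutree(hc, k = k)
  assignment <- paste0("D", labels)
  names(assignment) <- rownames(X)
  new("DomainAssignment", assignment = assignment,
      domains = paste0("D", seq_len(k)), k = as.integer(k),
      silhouetteByK = sil)
}

.checkSameGrid <- function(a, b) {
  if (!identical(dim(a@grid), dim(b@grid)))
    stop("volume grids have different shapes")
  if (max(abs(a@affine - b@affine)) > 1e-6)
    stop("volume affines differ")
}

#' Dice coefficient between two thresholded activation maps
#'
#' Masks are `value > threshold` over finite voxels; the coefficient is
#' 2|A n B| / (|A| + |B|): 1 means perfect overlap of nonempty identical
#' masks, 0 no overlap. Two empty masks give 0 with a warning.
#'
#' @param a,b [VolumeMap-class] objects on the same grid.
#' @param threshold activation z threshold (strict). Default 0.
#' @return number in [0, 1].
#' @export
diceOverlap <- function(a, b, threshold = 0) {
  .checkSameGrid(a, b)
  A <- is.finite(a@grid) & a@grid > threshold
  B <- is.finite(b@grid) & b@grid > threshold
  denom <- sum(A) + sum(B)
  if (denom == 0L) {
    warning("both activation masks are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(A & B) / denom
}

#' Pearson correlation between two z-maps
#'
#' Product-moment correlation of voxelwise z-values over voxels finite in
#' both maps.
#'
#' @param a,b [VolumeMap-class] objects on the same grid.
#' @return number in [-1, 1]; `NA` with a warning if either map is
#'   constant over the shared voxels.
#' @export
pearsonOverlap <- function(a, b) {
  .checkSameGrid(a, b)
  ok <- is.finite(a@grid) & is.finite(b@grid)
  x <- a@grid[ok]; y <- b@grid[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant map; Pearson overlap undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Voxelwise mean map over one domain's networks
#'
#' @param volumes list of [VolumeMap-class] objects covering the domain's
#'   networks (matched by `networkId`).
#' @param assignment a [DomainAssignment-class].
#' @param domain domain label.
#' @return A [VolumeMap-class]; voxelwise mean ignoring non-finite
#'   entries, `NA` where no network had a finite value.
#' @export
domainMeanMap <- function(volumes, assignment, domain) {
  members <- names(domainOf(assignment))[domainOf(assignment) == domain]
  if (!length(members)) stop("empty domain: ", domain)
  ids <- vapply(volumes, function(v) v@networkId, character(1))
  miss <- setdiff(members, ids)
  if (length(miss))
    stop("no volume for network(s): ", paste(miss, collapse = ", "))
  vols <- volumes[match(members, ids)]
  for (v in vols[-1L]) .checkSameGrid(vols[[1L]], v)
  acc <- array(0, dim(vols[[1L]]@grid))
  cnt <- array(0L, dim(vols[[1L]]@grid))
  for (v in vols) {
    ok <- is.finite(v@grid)
    acc[ok] <- acc[ok] + v@grid[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  VolumeMap(out, vols[[1L]]@affine, networkId = domain)
}
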