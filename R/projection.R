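# Density-adaptive projection of volumetric network z-maps onto biopsy
# sites. Densely sampled sites (squared nearest-neighbour distance <= the
# density threshold) take the z-value of the closest voxel centre; sparse
# sites take a Gaussian-weighted mean over all finite voxels within the
# support radius.

#' Projection parameters
#'
#' @param densityThreshold squared Euclidean distance cutoff in mm^2
#'   separating the dense (direct-voxel) and sparse (Gaussian) regimes;
#'   inclusive ("equal to or below"). Default 5.
#' @param gaussMu Gaussian centre in mm. Default 0.
#' @param gaussSigma Gaussian width in mm. Default 20.
#' @param supportRadius voxels farther than this from a site are excluded
#'   from the Gaussian average. Default 3 * gaussSigma (weights beyond
#'   three sigma are negligible).
#' @return a validated parameter list.
#' @export
projectionParams <- function(densityThreshold = 5, gaussMu = 0,
                             gaussSigma = 20,
                             supportRadius = 3 * gaussSigma) {
  stopifnot(densityThreshold > 0, gaussSigma > 0, supportRadius > 0)
  list(densityThreshold = densityThreshold, gaussMu = gaussMu,
       gaussSigma = gaussSigma, supportRadius = supportRadius)
}

#' Squared distance from each biopsy site to its nearest other site
#'
#' @param siteTable a [SiteTable-class] with at least two sites.
#' @return numeric vector (mm^2), one entry per site; 0 where coordinates
#'   are duplicated.
#' @export
nnSqDistance <- function(siteTable) {
  xyz <- siteCoords(siteTable)
  n <- nrow(xyz)
  if (n < 2L) stop("nearest-neighbour distance needs at least 2 sites")
  # squared distances summed directly (no sqrt round-trip), so the
  # inclusive density-threshold comparison is exact
  d2 <- outer(xyz[, 1L], xyz[, 1L], "-")^2 +
    outer(xyz[, 2L], xyz[, 2L], "-")^2 +
    outer(xyz[, 3L], xyz[, 3L], "-")^2
  diag(d2) <- Inf
  out <- apply(d2, 1L, min)
  names(out) <- sites(siteTable)
  out
}

# mm coordinates of every voxel centre, 0-based indexing, column-major order
.voxelCenters <- function(dims, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dims[1L]) - 1L,
                               j = seq_len(dims[2L]) - 1L,
                               k = seq_len(dims[3L]) - 1L))
  t(affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

# Shared geometry: which rule fires per site, the nearest voxel, and the
# support set + Gaussian weights for the sparse rule. Independent of any
# particular volume's values, so computed once per site table and grid.
.projectionGeometry <- function(dims, affine, siteTable, params,
                                chunkSize = 512L) {
  vox <- .voxelCenters(dims, affine)
  xyz <- siteCoords(siteTable)
  nSite <- nrow(xyz)
  dense <- nnSqDistance(siteTable) <= params$densityThreshold
  nearest <- integer(nSite)
  support <- vector("list", nSite)
  voxNorm <- rowSums(vox^2)
  r2max <- params$supportRadius^2
  for (start in seq(1L, nSite, by = chunkSize)) {
    rows <- start:min(start + chunkSize - 1L, nSite)
    s <- xyz[rows, , drop = FALSE]
    d2 <- outer(rowSums(s^2), voxNorm, "+") - 2 * s %*% t(vox)
    d2[d2 < 0] <- 0
    nearest[rows] <- apply(d2, 1L, which.min)
    for (ii in seq_along(rows)) {
      keep <- which(d2[ii, ] <= r2max)
      d <- sqrt(d2[ii, keep])
      w <- exp(-(d - params$gaussMu)^2 / (2 * params$gaussSigma^2))
      support[[rows[ii]]] <- list(idx = keep, w = w)
    }
  }
  list(dense = dense, nearest = nearest, support = support)
}

.projectOne <- function(z, geometry, siteNames) {
  nSite <- length(geometry$nearest)
  out <- rep(NA_real_, nSite)
  fellThrough <- 0L
  noSupport <- 0L
  for (i in seq_len(nSite)) {
    if (geometry$dense[i]) {
      v <- z[geometry$nearest[i]]
      if (is.finite(v)) {
        out[i] <- v
        next
      }
      fellThrough <- fellThrough + 1L   # nearest voxel missing: Gaussian rule
    }
    sup <- geometry$support[[i]]
    zv <- z[sup$idx]
    ok <- is.finite(zv)
    if (!any(ok)) {
      noSupport <- noSupport + 1L
      next
    }
    out[i] <- sum(sup$w[ok] * zv[ok]) / sum(sup$w[ok])
  }
  if (fellThrough > 0L)
    message(fellThrough, " dense site(s) had a non-finite nearest voxel; ",
            "Gaussian rule used")
  if (noSupport > 0L)
    message(noSupport, " site(s) had no finite voxel in support; set missing")
  names(out) <- siteNames
  out
}

#' Project one network volume onto biopsy sites
#'
#' For each site: if its squared distance to the nearest other site is at
#' or below `densityThreshold`, the z-value of the voxel centre closest to
#' the site is taken (ties broken by lowest column-major voxel index);
#' otherwise the Gaussian-weighted mean
#' \eqn{\sum_v w_v z_v / \sum_v w_v} with
#' \eqn{w_v = \exp(-(d_v-\mu)^2/(2\sigma^2))} over finite voxels within
#' the support radius. Non-finite voxels are excluded from both rules; a
#' dense site whose nearest voxel is non-finite falls through to the
#' Gaussian rule.
#'
#' @param volume a [VolumeMap-class].
#' @param siteTable a [SiteTable-class] in the same MNI frame.
#' @param params see [projectionParams()].
#' @return named numeric vector of per-site z-values (`NA` where no finite
#'   voxel supported the site).
#' @export
projectNetwork <- function(volume, siteTable, params = projectionParams()) {
  geometry <- .projectionGeometry(dim(volume@grid), volume@affine,
                                  siteTable, params)
  .projectOne(as.vector(volume@grid), geometry, sites(siteTable))
}

#' Project a list of network volumes onto biopsy sites
#'
#' All volumes must share grid shape and affine; the site-to-voxel geometry
#' is then computed once and reused.
#'
#' @param volumes list of [VolumeMap-class] objects.
#' @param siteTable a [SiteTable-class].
#' @param params see [projectionParams()].
#' @return An [FNSiteMatrix-class] with one row per volume, in input order.
#' @export
projectAll <- function(volumes, siteTable, params = projectionParams()) {
  if (!length(volumes)) {
    return(FNSiteMatrix(matrix(numeric(), 0L, length(sites(siteTable)),
                               dimnames = list(NULL, sites(siteTable)))))
  }
  ref <- volumes[[1L]]
  for (v in volumes) {
    if (!identical(dim(v@grid), dim(ref@grid)))
      stop("grid shape mismatch for volume ", v@networkId)
    if (max(abs(v@affine - ref@affine)) > 1e-6)
      stop("affine mismatch for volume ", v@networkId)
  }
  geometry <- .projectionGeometry(dim(ref@grid), ref@affine, siteTable, params)
  rows <- vapply(volumes, function(v)
    .projectOne(as.vector(v@grid), geometry, sites(siteTable)),
    numeric(length(sites(siteTable))))
  out <- t(rows)
  rownames(out) <- vapply(volumes, function(v) v@networkId, character(1))
  FNSiteMatrix(out)
}
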