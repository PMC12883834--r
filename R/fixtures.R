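# Synthetic dataset generator with planted structure: smooth blob network
# volumes grouped into a planted domain partition, biopsy sites with mixed
# dense/sparse spacing, module genes co-expressed with their networks,
# extreme omega on their branch, and cell clusters over-expressing module
# genes. Every pipeline stage can be exercised against the planted truth.

#' Fixture configuration
#'
#' @param n_genes,n_sites,n_networks,n_branches,n_clusters dataset shape.
#'   Defaults 800, 300, 12, 6, 50.
#' @param grid_shape 3D grid dimensions. Default c(24, 24, 24).
#' @param voxel_size voxel edge length in mm. Default 2.
#' @param n_domains planted network-domain count. Default 3.
#' @param n_modules planted gene modules (each: gene set, network set,
#'   branch, direction). Default 3.
#' @param module_size genes per planted module. Default 40.
#' @param effect multiplier on the z-scored network site profile in module
#'   genes' expression. Default 2.
#' @param noise_sd standard deviation of the expression noise. Default 0.5.
#' @param pool_filler background genes per branch given high omega
#'   (uniform in (1.1, 2.0), below the planted modules' 2.5-3.5 range so
#'   harmonization keeps modules intact) and, separately, dN = 0 status,
#'   so every branch has nonempty high/low pools. Default 45.
#' @param seed master seed.
#' @return validated configuration list.
#' @export
fixtureConfig <- function(n_genes = 800L, n_sites = 300L, n_networks = 12L,
                          n_branches = 6L, n_clusters = 50L,
                          grid_shape = c(24L, 24L, 24L), voxel_size = 2,
                          n_domains = 3L, n_modules = 3L, module_size = 40L,
                          effect = 2, noise_sd = 0.5, pool_filler = 45L,
                          seed = 1L) {
  stopifnot(n_genes >= 2L, n_sites >= 2L, n_networks >= 2L,
            n_branches >= 2L, n_clusters >= 2L, length(grid_shape) == 3L,
            n_domains >= 2L, n_modules >= 1L, module_size >= 2L,
            n_modules <= n_branches, n_domains <= n_networks)
  if (n_modules * module_size + 2L * n_branches * pool_filler > n_genes)
    stop("planted gene sets exceed n_genes")
  list(n_genes = as.integer(n_genes), n_sites = as.integer(n_sites),
       n_networks = as.integer(n_networks),
       n_branches = as.integer(n_branches),
       n_clusters = as.integer(n_clusters),
       grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
       n_domains = as.integer(n_domains), n_modules = as.integer(n_modules),
       module_size = as.integer(module_size), effect = effect,
       noise_sd = noise_sd, pool_filler = as.integer(pool_filler),
       seed = as.integer(seed))
}

.blob <- function(vox, center, width, height) {
  d2 <- rowSums(sweep(vox, 2L, center)^2)
  height * exp(-d2 / (2 * width^2))
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Networks are smooth Gaussian-blob z-maps: networks of one planted
#' domain share a domain base pattern plus a per-network perturbation, so
#' their gene-correlation profiles cluster together. Sites mix dense pairs
#' (1 mm apart, triggering the direct-voxel rule) with sparse sites
#' (triggering the Gaussian rule). Module genes' expression is
#' `effect` x z-scored network site profile + Gaussian noise; background
#' genes are pure noise. Module genes get extreme omega on their branch
#' (high: uniform in (2.5, 3.5); low: exactly 0) with STABLE status; background omega is
#' exponential-like in (0, 1) with a scattering of DS_ZERO / DN_ZERO /
#' UNSTABLE / IDENTICAL statuses. One cell cluster per module
#' over-expresses the module genes. Bit-reproducible from `config$seed`.
#'
#' @param config see [fixtureConfig()].
#' @return list with `volumes`, `sites`, `expression`, `omega`, `cells`,
#'   `truth` (planted modules, enriched clusters, domain partition) and
#'   `config`.
#' @export
makeDataset <- function(config = fixtureConfig()) {
  set.seed(config$seed)
  dims <- config$grid_shape
  vs <- config$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4L] <- -(dims - 1) / 2 * vs
  vox <- .voxelCenters(dims, affine)
  half <- (dims - 1) / 2 * vs

  networkIds <- sprintf("N%02d", seq_len(config$n_networks))
  domainIds <- sprintf("D%d", seq_len(config$n_domains))
  domainOfNet <- domainIds[rep(seq_len(config$n_domains),
                               length.out = config$n_networks)]
  domainOfNet <- sort(domainOfNet)  # contiguous blocks N01.. per domain
  names(domainOfNet) <- networkIds

  randCenter <- function() stats::runif(3L, -0.6, 0.6) * half
  domainBase <- lapply(domainIds, function(d) {
    .blob(vox, randCenter(), width = 0.45 * min(half), height = 4) +
      .blob(vox, randCenter(), width = 0.35 * min(half), height = 3)
  })
  names(domainBase) <- domainIds
  volumes <- lapply(networkIds, function(nid) {
    z <- domainBase[[domainOfNet[nid]]] +
      .blob(vox, randCenter(), width = 0.25 * min(half), height = 1.5) +
      stats::rnorm(nrow(vox), sd = 0.15)
    VolumeMap(array(z, dims), affine, networkId = nid)
  })

  # sites: dense pairs (1 mm apart) plus sparse singletons, all in-grid
  nPairs <- max(1L, config$n_sites %/% 10L)
  nSingle <- config$n_sites - 2L * nPairs
  base <- matrix(stats::runif(3L * (nPairs + nSingle), -0.85, 0.85),
                 ncol = 3L) * matrix(half, nPairs + nSingle, 3L, byrow = TRUE)
  pairA <- base[seq_len(nPairs), , drop = FALSE]
  pairB <- pairA + matrix(c(1, 0, 0), nPairs, 3L, byrow = TRUE)
  xyz <- rbind(pairA, pairB, base[-seq_len(nPairs), , drop = FALSE])
  siteTable <- SiteTable(sprintf("S%04d", seq_len(nrow(xyz))), xyz)

  # true site profile of each network = value at the nearest voxel centre
  nearestVoxel <- function(p) {
    which.min(rowSums(sweep(vox, 2L, p)^2))
  }
  nearest <- apply(xyz, 1L, nearestVoxel)
  profiles <- t(vapply(volumes, function(v) as.vector(v@grid)[nearest],
                       numeric(nrow(xyz))))
  rownames(profiles) <- networkIds

  geneIds <- sprintf("G%04d", seq_len(config$n_genes))
  branchIds <- sprintf("B%d", seq_len(config$n_branches))
  pool <- geneIds
  takeGenes <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  netsPerDomain <- split(networkIds, domainOfNet)
  modules <- lapply(seq_len(config$n_modules), function(m) {
    dom <- domainIds[(m - 1L) %% config$n_domains + 1L]
    list(genes = takeGenes(config$module_size),
         networks = netsPerDomain[[dom]],
         branch = branchIds[m],
         direction = if (m %% 2L == 1L) "high" else "low",
         domain = dom)
  })
  fillerHigh <- lapply(branchIds, function(b) takeGenes(config$pool_filler))
  fillerLow <- lapply(branchIds, function(b) takeGenes(config$pool_filler))
  names(fillerHigh) <- names(fillerLow) <- branchIds

  expr <- matrix(stats::rnorm(config$n_genes * config$n_sites),
                 config$n_genes, config$n_sites,
                 dimnames = list(geneIds, sites(siteTable)))
  for (mod in modules) {
    prof <- colMeans(profiles[mod$networks, , drop = FALSE])
    prof <- (prof - mean(prof)) / stats::sd(prof)
    for (g in mod$genes) {
      expr[g, ] <- config$effect * prof +
        stats::rnorm(config$n_sites, sd = config$noise_sd)
    }
  }

  omega <- matrix(pmin(pmax(stats::rexp(config$n_genes * config$n_branches,
                                        rate = 4), 1e-4), 0.999),
                  config$n_genes, config$n_branches,
                  dimnames = list(geneIds, branchIds))
  status <- matrix("STABLE", config$n_genes, config$n_branches,
                   dimnames = dimnames(omega))
  for (mod in modules) {
    omega[mod$genes, mod$branch] <-
      if (mod$direction == "high") stats::runif(length(mod$genes), 2.5, 3.5)
      else 0
  }
  for (b in branchIds) {
    omega[fillerHigh[[b]], b] <- stats::runif(config$pool_filler, 1.1, 2.0)
    status[fillerLow[[b]], b] <- "DN_ZERO"
  }
  plantedGenes <- unique(unlist(lapply(modules, `[[`, "genes")))
  scatterable <- setdiff(geneIds, c(plantedGenes, unlist(fillerHigh),
                                    unlist(fillerLow)))
  for (code in c("DS_ZERO", "UNSTABLE", "IDENTICAL", "SHORT_EDGE_UNSTABLE")) {
    pick <- cbind(match(sample(scatterable, config$n_branches), geneIds),
                  seq_len(config$n_branches))
    status[pick] <- code
  }
  omega[status %in% c("UNSTABLE", "SHORT_EDGE_UNSTABLE", "DS_ZERO",
                      "DN_ZERO", "IDENTICAL")] <- NA_real_
  omegaTable <- OmegaTable(omega, status = status)

  clusterIds <- sprintf("C%03d", seq_len(config$n_clusters))
  cellVals <- matrix(stats::rlnorm(config$n_genes * config$n_clusters,
                                   meanlog = 0, sdlog = 0.5),
                     config$n_genes, config$n_clusters,
                     dimnames = list(geneIds, clusterIds))
  enrichedClusters <- character(length(modules))
  for (m in seq_along(modules)) {
    enrichedClusters[m] <- clusterIds[m]
    cellVals[modules[[m]]$genes, m] <-
      cellVals[modules[[m]]$genes, m] + 10
  }
  meta <- data.frame(
    supercluster = sprintf("SC%d", rep(seq_len(5L),
                                       length.out = config$n_clusters)),
    class = sprintf("CL%d", rep(seq_len(4L),
                                length.out = config$n_clusters)),
    neurotransmitter = sprintf("NT%d", rep(seq_len(3L),
                                           length.out = config$n_clusters)),
    neuronal = rep(c(TRUE, FALSE), length.out = config$n_clusters),
    row.names = clusterIds, stringsAsFactors = FALSE)
  cells <- CellTypeMatrix(cellVals, metadata = meta)

  truth <- list(modules = modules,
                enrichedClusters = stats::setNames(
                  enrichedClusters,
                  vapply(modules, `[[`, character(1), "branch")),
                domains = domainOfNet)
  list(volumes = volumes, sites = siteTable,
       expression = ExpressionMatrix(expr), omega = omegaTable,
       cells = cells, truth = truth, config = config)
}

# adjusted Rand index between two label vectors
.adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sumI * sumJ / comb2(n)
  mx <- (sumI + sumJ) / 2
  if (mx == expected) return(1)
  (sumIJ - expected) / (mx - expected)
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Score pipeline outputs against the planted truth
#'
#' For each planted module, the best gene-set Jaccard over the recovered
#' biclusters on the module's branch (and that bicluster's network-set
#' Jaccard); optionally the adjusted Rand index of the recovered domain
#' partition against the planted one, and the recall of planted enriched
#' cell clusters.
#'
#' @param truth the `truth` element of [makeDataset()] output.
#' @param biclusters list of recovered [Bicluster-class] objects.
#' @param assignment optional [DomainAssignment-class].
#' @param enriched optional character vector of cell clusters flagged
#'   enriched anywhere.
#' @return list with `modules` (data.frame: branch, direction,
#'   geneJaccard, networkJaccard), `domainARI`, `enrichedRecall`.
#' @export
truthCheck <- function(truth, biclusters, assignment = NULL,
                       enriched = NULL) {
  rows <- lapply(truth$modules, function(mod) {
    onBranch <- Filter(function(b) mod$branch %in% branches(b), biclusters)
    if (!length(onBranch)) {
      gj <- 0; nj <- 0
    } else {
      gjs <- vapply(onBranch, function(b) .jaccard(genes(b), mod$genes),
                    numeric(1))
      best <- which.max(gjs)
      gj <- gjs[best]
      nj <- .jaccard(networks(onBranch[[best]]), mod$networks)
    }
    data.frame(branch = mod$branch, direction = mod$direction,
               geneJaccard = gj, networkJaccard = nj,
               stringsAsFactors = FALSE)
  })
  out <- list(modules = do.call(rbind, rows))
  if (!is.null(assignment)) {
    nets <- intersect(names(truth$domains), networks(assignment))
    out$domainARI <- .adjustedRandIndex(truth$domains[nets],
                                        domainOf(assignment)[nets])
  }
  if (!is.null(enriched)) {
    out$enrichedRecall <- mean(truth$enrichedClusters %in% enriched)
  }
  out
}
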