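# Seeded genetic-algorithm biclustering of the concatenated analysis
# matrix. Candidates are binary masks over the network columns (the branch
# omega column is forced into every candidate); a candidate's gene set is
# the rows carrying 1 in every selected column of the binarized incidence
# matrix, and fitness is the size score. Searches iterate with tabu
# masking of already-found biclusters, isolated subpopulations, and an
# outer loop cycling weighting/tabu parameter combinations.

#' Genetic-algorithm biclustering parameters
#'
#' Field names mirror the algorithm's configuration vocabulary.
#'
#' @param amountOfBiclusterSearches number of iterated searches, each
#'   emitting at most one bicluster. Default 20.
#' @param nsubpops number of isolated subpopulations (no migration).
#'   Default 4.
#' @param popsize total candidate solutions, split evenly across
#'   subpopulations. Default 250 (high-omega runs; 1200 is the documented
#'   low-omega setting).
#' @param do_weighting weight omega and network columns differently in the
#'   score. Default FALSE.
#' @param variableClassNotOnTabuList logical pair for (omega, network)
#'   columns; TRUE means that class is NOT tabu-masked after a bicluster
#'   is emitted, FALSE means its qualifying cells are zeroed before
#'   subsequent searches. Default c(TRUE, FALSE).
#' @param global_optim iteration count for [globalOptimLoop()], ideally a
#'   multiple of 4. Default 0 (loop not used).
#' @param generations GA generations per search. Default 100.
#' @param mutation_rate per-bit mutation probability; `NULL` means
#'   1/#columns at run time.
#' @param crossover_rate probability a mated pair undergoes uniform
#'   crossover. Default 0.7.
#' @param min_genes minimum gene-set size of an emitted bicluster.
#'   Default 5.
#' @param min_network_cols minimum network columns. Default 1.
#' @param weight_omega,weight_network column weights used when
#'   `do_weighting` is on. Defaults 2 and 1.
#' @param init_density expected fraction of network columns switched on in
#'   initial candidates; `NULL` means 2/#network-columns (sparse starts
#'   keep early gene sets nonempty).
#' @param seed master seed; every random draw derives from it.
#' @return validated parameter list.
#' @export
gabiParams <- function(amountOfBiclusterSearches = 20L, nsubpops = 4L,
                       popsize = 250L, do_weighting = FALSE,
                       variableClassNotOnTabuList = c(TRUE, FALSE),
                       global_optim = 0L, generations = 100L,
                       mutation_rate = NULL, crossover_rate = 0.7,
                       min_genes = 5L, min_network_cols = 1L,
                       weight_omega = 2, weight_network = 1,
                       init_density = NULL, seed = 1L) {
  stopifnot(amountOfBiclusterSearches >= 1L, nsubpops >= 1L,
            popsize >= nsubpops, global_optim >= 0L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            min_genes >= 1L, min_network_cols >= 0L)
  if (!is.null(mutation_rate))
    stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  if (length(variableClassNotOnTabuList) != 2L)
    stop("variableClassNotOnTabuList must be a pair for (omega, network)")
  list(amountOfBiclusterSearches = as.integer(amountOfBiclusterSearches),
       nsubpops = as.integer(nsubpops), popsize = as.integer(popsize),
       do_weighting = isTRUE(do_weighting),
       variableClassNotOnTabuList = as.logical(variableClassNotOnTabuList),
       global_optim = as.integer(global_optim),
       generations = as.integer(generations),
       mutation_rate = mutation_rate, crossover_rate = crossover_rate,
       min_genes = as.integer(min_genes),
       min_network_cols = as.integer(min_network_cols),
       weight_omega = weight_omega, weight_network = weight_network,
       init_density = init_density, seed = as.integer(seed))
}

# deterministic 31-bit child seed from a master seed and an index
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483647)
}

#' Branch-specific rank thresholds from a gene pool
#'
#' The omega-rank window is anchored on the (harmonized) pool so exactly
#' the pool qualifies: high-omega runs use [min omega-tilde over the pool,
#' Inf), low-omega runs use (-Inf, max omega-tilde over the pool].
#'
#' @param omegaNorm a [NormalizedOmega-class].
#' @param pools result of [buildGenePools()].
#' @param branch branch label.
#' @param direction `"high"` or `"low"`.
#' @param networkMin minimum rank-normalized correlation a network column
#'   must reach (inclusive). Default 0.75.
#' @return threshold specification list with `omegaLo`, `omegaHi`
#'   (named by branch) and `networkMin`.
#' @export
branchThresholds <- function(omegaNorm, pools, branch,
                             direction = c("high", "low"),
                             networkMin = 0.75) {
  direction <- match.arg(direction)
  pool <- pools[[direction]][[branch]]
  if (is.null(pool) || !length(pool))
    stop("empty ", direction, "-omega pool for branch ", branch)
  ot <- values(omegaNorm)[pool, branch]
  ot <- ot[!is.na(ot)]
  if (!length(ot)) stop("pool has no normalized omega on branch ", branch)
  if (direction == "high") {
    lo <- min(ot); hi <- Inf
  } else {
    lo <- -Inf; hi <- max(ot)
  }
  out <- list(omegaLo = stats::setNames(lo, branch),
              omegaHi = stats::setNames(hi, branch),
              networkMin = networkMin, direction = direction)
  out
}

#' Binarize an analysis matrix against its thresholds
#'
#' Omega columns qualify inside their inclusive rank window; network
#' columns qualify at or above `networkMin`; missing cells become 0.
#'
#' @param analysis an [AnalysisMatrix-class].
#' @param spec threshold specification from [branchThresholds()].
#' @return integer 0/1 incidence matrix with a `columnClass` attribute.
#' @export
binarize <- function(analysis, spec) {
  X <- values(analysis)
  cls <- columnClasses(analysis)
  inc <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    ok <- if (cls[j] == "omega") {
      nm <- colnames(X)[j]
      lo <- if (nm %in% names(spec$omegaLo)) spec$omegaLo[[nm]] else -Inf
      hi <- if (nm %in% names(spec$omegaHi)) spec$omegaHi[[nm]] else Inf
      !is.na(v) & v >= lo & v <= hi
    } else {
      !is.na(v) & v >= spec$networkMin
    }
    inc[ok, j] <- 1L
  }
  attr(inc, "columnClass") <- cls
  inc
}

#' Size score of a bicluster
#'
#' Unweighted: #genes x (#omega columns + #network columns). With
#' `do_weighting`: #genes x (w_omega x #omega + w_network x #network).
#'
#' @param bicluster a [Bicluster-class].
#' @param params see [gabiParams()].
#' @return non-negative number.
#' @export
scoreBicluster <- function(bicluster, params = gabiParams()) {
  nO <- length(branches(bicluster))
  nN <- length(networks(bicluster))
  w <- if (params$do_weighting) {
    params$weight_omega * nO + params$weight_network * nN
  } else {
    nO + nN
  }
  length(genes(bicluster)) * w
}

# lexicographic key of a binary mask, for deterministic tie-breaking
.maskKey <- function(mask) paste(as.integer(mask), collapse = "")

# One GA run on the current (possibly tabu-masked) incidence matrix.
# Returns the best column mask and its fitness, or NULL.
.gaRun <- function(incNet, omegaOK, params) {
  L <- ncol(incNet)
  pMut <- if (is.null(params$mutation_rate)) 1 / (L + 1L) else
    params$mutation_rate
  pInit <- if (is.null(params$init_density)) min(0.5, 2 / L) else
    params$init_density
  subSize <- max(2L, params$popsize %/% params$nsubpops)
  wNet <- if (params$do_weighting) params$weight_network else 1
  wOm <- if (params$do_weighting) params$weight_omega else 1

  evalFitness <- function(masks) {
    # masks: pop x L. Gene qualifies iff omega cell = 1 and every selected
    # network column = 1.
    nSel <- rowSums(masks)
    cnt <- incNet %*% t(masks)                      # genes x pop
    qual <- sweep(cnt, 2L, nSel, "==") & omegaOK
    nGenes <- colSums(qual)
    fit <- nGenes * (wOm + wNet * nSel)
    fit[nGenes < params$min_genes | nSel < params$min_network_cols] <- 0
    fit
  }

  bestMask <- NULL; bestFit <- 0; bestKey <- NULL
  consider <- function(mask, fit) {
    if (fit > bestFit ||
        (fit == bestFit && fit > 0 && !is.null(bestKey) &&
         .maskKey(mask) < bestKey)) {
      bestMask <<- mask; bestFit <<- fit; bestKey <<- .maskKey(mask)
    }
  }

  for (sp in seq_len(params$nsubpops)) {
    pop <- matrix(stats::rbinom(subSize * L, 1L, pInit), subSize, L)
    fit <- evalFitness(pop)
    for (gen in seq_len(params$generations)) {
      # 1 elite; tournament(2) parents; uniform crossover; per-bit mutation
      eliteIdx <- which.max(fit)
      a <- sample.int(subSize, subSize, replace = TRUE)
      b <- sample.int(subSize, subSize, replace = TRUE)
      parents <- ifelse(fit[a] >= fit[b], a, b)
      off <- pop[parents, , drop = FALSE]
      for (p in seq(1L, subSize - 1L, by = 2L)) {
        if (stats::runif(1) < params$crossover_rate) {
          swap <- stats::runif(L) < 0.5
          tmp <- off[p, swap]
          off[p, swap] <- off[p + 1L, swap]
          off[p + 1L, swap] <- tmp
        }
      }
      flips <- matrix(stats::runif(subSize * L) < pMut, subSize, L)
      off[flips] <- 1L - off[flips]
      off[1L, ] <- pop[eliteIdx, ]
      pop <- off
      fit <- evalFitness(pop)
    }
    for (i in which(fit == max(fit) & fit > 0)) consider(pop[i, ], fit[i])
    if (max(fit) == 0 && is.null(bestMask)) {
      # keep NULL; nothing valid in this subpopulation
    }
  }
  if (is.null(bestMask)) return(NULL)
  list(mask = as.integer(bestMask), fitness = bestFit)
}

#' Iterated genetic-algorithm bicluster search
#'
#' Runs `amountOfBiclusterSearches` independent GA searches on a binarized
#' incidence matrix. Each search evolves `nsubpops` isolated
#' subpopulations of column masks for `generations` generations; the
#' omega column is forced into every candidate, a candidate's gene set is
#' the rows with 1 in all its columns, and fitness is the size score. The
#' best valid candidate per search is emitted and its qualifying cells are
#' tabu-masked (per `variableClassNotOnTabuList`) before the next search.
#' Fully reproducible from `params$seed`.
#'
#' @param incidence 0/1 matrix from [binarize()] (genes x columns).
#' @param columnClasses per-column "omega"/"network"; defaults to the
#'   matrix's `columnClass` attribute.
#' @param params see [gabiParams()].
#' @param runMetadata extra fields stored in each emitted bicluster.
#' @return list of [Bicluster-class] objects (possibly empty).
#' @export
gabiSearch <- function(incidence, columnClasses = NULL,
                       params = gabiParams(), runMetadata = list()) {
  if (is.null(columnClasses)) columnClasses <- attr(incidence, "columnClass")
  if (is.null(columnClasses) || length(columnClasses) != ncol(incidence))
    stop("columnClasses must label every incidence column")
  omegaCols <- which(columnClasses == "omega")
  netCols <- which(columnClasses == "network")
  if (!length(omegaCols)) stop("incidence has no omega column")
  inc <- incidence
  out <- list()
  tabuOmega <- !params$variableClassNotOnTabuList[1L]
  tabuNetwork <- !params$variableClassNotOnTabuList[2L]
  for (s in seq_len(params$amountOfBiclusterSearches)) {
    set.seed(.deriveSeed(params$seed, s))
    omegaOK <- rowSums(inc[, omegaCols, drop = FALSE]) == length(omegaCols)
    incNet <- inc[, netCols, drop = FALSE]
    best <- .gaRun(incNet, omegaOK, params)
    if (is.null(best)) next
    selNet <- netCols[best$mask == 1L]
    rows <- omegaOK &
      rowSums(inc[, selNet, drop = FALSE]) == length(selNet)
    if (sum(rows) < params$min_genes) next
    bc <- Bicluster(genes = rownames(inc)[rows],
                    branches = colnames(inc)[omegaCols],
                    networks = colnames(inc)[selNet],
                    runMetadata = c(list(seed = params$seed, search = s,
                                         do_weighting = params$do_weighting),
                                    runMetadata))
    bc@score <- scoreBicluster(bc, params)
    out[[length(out) + 1L]] <- bc
    if (tabuOmega) inc[rows, omegaCols] <- 0L
    if (tabuNetwork) inc[rows, selNet] <- 0L
  }
  out
}

#' Parameter-cycling outer optimization loop
#'
#' Cycles in fixed order through the four combinations
#' (do_weighting TRUE/FALSE) x (variableClassNotOnTabuList (TRUE, TRUE) /
#' (TRUE, FALSE)), running [gabiSearch()] once per iteration with a child
#' seed derived from the master seed and iteration index; results are
#' pooled with the combination recorded in each bicluster's run metadata.
#'
#' @param incidence,columnClasses as in [gabiSearch()].
#' @param params see [gabiParams()]; `global_optim` >= 1 gives the number
#'   of iterations (ideally a multiple of 4 so every combination runs
#'   equally often).
#' @return pooled list of [Bicluster-class] objects.
#' @export
globalOptimLoop <- function(incidence, columnClasses = NULL,
                            params = gabiParams(global_optim = 4L)) {
  if (params$global_optim < 1L)
    stop("global_optim must be >= 1 for the optimization loop")
  combos <- list(
    list(do_weighting = TRUE, tabu = c(TRUE, TRUE)),
    list(do_weighting = TRUE, tabu = c(TRUE, FALSE)),
    list(do_weighting = FALSE, tabu = c(TRUE, TRUE)),
    list(do_weighting = FALSE, tabu = c(TRUE, FALSE)))
  out <- list()
  for (it in seq_len(params$global_optim)) {
    combo <- combos[[(it - 1L) %% 4L + 1L]]
    p <- params
    p$do_weighting <- combo$do_weighting
    p$variableClassNotOnTabuList <- combo$tabu
    p$seed <- .deriveSeed(params$seed, it * 7919L)
    res <- gabiSearch(incidence, columnClasses, p,
                      runMetadata = list(
                        combo = (it - 1L) %% 4L + 1L, iteration = it,
                        variableClassNotOnTabuList = combo$tabu))
    out <- c(out, res)
  }
  out
}

# union-find for similarity components
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in edges) {
    ra <- find(e[1L]); rb <- find(e[2L])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

.mergeOnce <- function(biclusters, overlapFrac, params) {
  n <- length(biclusters)
  if (n <= 1L) return(biclusters)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      gi <- genes(biclusters[[i]]); gj <- genes(biclusters[[j]])
      ov <- length(intersect(gi, gj)) / min(length(gi), length(gj))
      sameNet <- setequal(networks(biclusters[[i]]),
                          networks(biclusters[[j]]))
      if (ov > overlapFrac || sameNet)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  comp <- .components(n, edges)
  out <- lapply(unique(comp), function(cc) {
    members <- biclusters[comp == cc]
    if (length(members) == 1L) return(members[[1L]])
    bc <- Bicluster(
      genes = sort(unique(unlist(lapply(members, genes)))),
      branches = sort(unique(unlist(lapply(members, branches)))),
      networks = sort(unique(unlist(lapply(members, networks)))),
      runMetadata = list(merged_from = length(members)))
    bc@score <- scoreBicluster(bc, params)
    bc
  })
  out
}

#' Merge similar biclusters and recompute their size scores
#'
#' Two biclusters are similar when their gene sets overlap by more than
#' `overlapFrac` of the smaller set, or when their network sets are
#' identical. Connected components of the similarity graph are merged by
#' union of genes, branches and networks, and the merge is iterated to a
#' fixed point so the operation is idempotent.
#'
#' @param biclusters list of [Bicluster-class] objects from one branch run.
#' @param overlapFrac gene-overlap fraction (strict >). Default 0.5.
#' @param params scoring parameters for the merged records.
#' @return list of merged [Bicluster-class] objects.
#' @export
mergeBiclusters <- function(biclusters, overlapFrac = 0.5,
                            params = gabiParams()) {
  cur <- biclusters
  repeat {
    nxt <- .mergeOnce(cur, overlapFrac, params)
    if (length(nxt) == length(cur)) return(nxt)
    cur <- nxt
  }
}
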