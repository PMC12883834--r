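# Cell-type enrichment of bicluster gene sets: top-percentile expression
# filtering, point-biserial correlation of set membership against cluster
# expression over the shared gene universe, within-branch z-scoring with a
# critical value of 1.96, and metadata collapse.

#' Zero out expression below a per-cluster percentile
#'
#' Within every cluster column, values strictly below that column's
#' `pct`-th percentile (linear-interpolation quantile) are set to 0;
#' values at the boundary are retained. Focuses enrichment on each
#' cluster's highly expressed genes.
#'
#' @param cells a [CellTypeMatrix-class].
#' @param pct percentile in (0, 100). Default 90.
#' @return A filtered [CellTypeMatrix-class].
#' @export
percentileFilter <- function(cells, pct = 90) {
  stopifnot(pct > 0, pct < 100)
  X <- values(cells)
  for (j in seq_len(ncol(X))) {
    cut <- stats::quantile(X[, j], pct / 100, na.rm = TRUE, names = FALSE)
    low <- !is.na(X[, j]) & X[, j] < cut
    X[low, j] <- 0
  }
  new("CellTypeMatrix", values = X, metadata = cells@metadata)
}

#' Correlate a gene set with every cell cluster
#'
#' Point-biserial correlation between the binary membership indicator of
#' the gene set (over the shared gene universe) and each cluster's
#' filtered expression column.
#'
#' @param geneSet character vector, a strict nonempty subset of
#'   `universe`.
#' @param cellsFiltered a [CellTypeMatrix-class], typically after
#'   [percentileFilter()].
#' @param universe ordered gene labels shared between the omega table and
#'   the cell matrix; defaults to the cell matrix's genes.
#' @return named numeric vector of per-cluster correlations (`NA` with a
#'   warning for constant expression columns).
#' @export
enrichGeneSet <- function(geneSet, cellsFiltered, universe = NULL) {
  if (is.null(universe)) universe <- genes(cellsFiltered)
  geneSet <- intersect(geneSet, universe)
  if (!length(geneSet) || length(geneSet) == length(universe))
    stop("gene set must be a nonempty strict subset of the universe")
  X <- values(cellsFiltered)[universe, , drop = FALSE]
  ind <- as.numeric(universe %in% geneSet)
  sds <- apply(X, 2L, stats::sd)
  out <- rep(NA_real_, ncol(X))
  names(out) <- colnames(X)
  ok <- !is.na(sds) & sds > 0
  if (any(!ok))
    warning(sum(!ok), " constant expression column(s); correlation undefined")
  if (any(ok)) out[ok] <- as.vector(stats::cor(ind, X[, ok, drop = FALSE]))
  out
}

#' Z-score correlations across clusters and flag enriched cell types
#'
#' Within every (branch, domain) column, correlations are standardized
#' across clusters to mean 0 / sd 1; a cluster is enriched when its z
#' strictly exceeds `criticalZ`.
#'
#' @param correlations numeric matrix, clusters x (branch|domain) cells.
#' @param cellMetadata per-cluster metadata data.frame (supercluster,
#'   class, neurotransmitter, neuronal).
#' @param criticalZ the critical value (strict). Default 1.96.
#' @return An [EnrichmentResult-class]. Columns with zero variance yield
#'   no enrichment and a warning.
#' @export
zscoreBinarize <- function(correlations, cellMetadata,
                           criticalZ = 1.96) {
  Z <- correlations
  for (j in seq_len(ncol(Z))) {
    x <- correlations[, j]
    mu <- mean(x, na.rm = TRUE)
    sdev <- stats::sd(x, na.rm = TRUE)
    if (is.na(sdev) || sdev == 0) {
      warning("zero variance across clusters in ", colnames(Z)[j],
              "; no enrichment")
      Z[, j] <- NA_real_
      next
    }
    Z[, j] <- (x - mu) / sdev
  }
  enriched <- !is.na(Z) & Z > criticalZ
  new("EnrichmentResult", correlation = correlations, z = Z,
      enriched = enriched, criticalZ = criticalZ,
      clusterMetadata = cellMetadata)
}

#' Collapse enrichment flags by cell-type metadata
#'
#' Per metadata group (supercluster, auto-annotated class or
#' neurotransmitter): the number of (branch, domain) cells containing at
#' least one enriched cluster of that group — presence, not multiplicity.
#' Neuronal and non-neuronal clusters are counted separately.
#'
#' @param result an [EnrichmentResult-class].
#' @param by `"supercluster"`, `"class"` or `"neurotransmitter"`.
#' @return data.frame with columns `group`, `neuronal`, `count`.
#' @export
collapseEnrichment <- function(result,
                               by = c("supercluster", "class",
                                      "neurotransmitter")) {
  by <- match.arg(by)
  meta <- result@clusterMetadata
  if (!by %in% colnames(meta)) stop("unknown metadata key: ", by)
  groups <- meta[[by]]
  rows <- list()
  for (g in sort(unique(groups))) {
    for (neuro in c(TRUE, FALSE)) {
      members <- which(groups == g & meta$neuronal == neuro)
      count <- if (length(members)) {
        sum(apply(result@enriched[members, , drop = FALSE], 2L, any))
      } else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, neuronal = neuro, count = as.integer(count),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
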