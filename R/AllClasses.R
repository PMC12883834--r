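#' @import methods
NULL

#' Recognised PAML outcome status codes for omega cells
#'
#' `STABLE` cells carry a usable maximum-likelihood omega estimate.
#' `UNSTABLE` and `SHORT_EDGE_UNSTABLE` cells are unreliable and are always
#' filtered. `DN_ZERO` (dN = 0, so dN/dS = 0), `DS_ZERO` (dS = 0, so dN/dS
#' diverges) and `IDENTICAL` (identical sequences) are resolvable only under
#' the relaxed constraint mode.
#'
#' @export
OMEGA_STATUS_CODES <- c("STABLE", "UNSTABLE", "SHORT_EDGE_UNSTABLE",
                        "DN_ZERO", "DS_ZERO", "IDENTICAL")

#' VolumeMap: a volumetric z-score map in MNI space
#'
#' Holds one functional network's 3D grid of z-scores together with the 4x4
#' affine mapping 0-based voxel indices to MNI millimetre coordinates.
#'
#' @slot grid 3D numeric array of z-scores; non-finite entries mark missing
#'   voxels.
#' @slot affine 4x4 numeric voxel-to-mm transform (0-based voxel indexing).
#' @slot networkId single character label for the network.
#' @export
setClass("VolumeMap", representation(
  grid = "array", affine = "matrix", networkId = "character"
))

setValidity("VolumeMap", function(object) {
  msg <- NULL
  if (length(dim(object@grid)) != 3L || any(dim(object@grid) <= 0L))
    msg <- c(msg, "grid must be a 3D array with positive dimensions")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (!is.finite(det(object@affine)) || abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(object@networkId) != 1L)
    msg <- c(msg, "networkId must be a single label")
  if (is.null(msg)) TRUE else msg
})

#' SiteTable: biopsy-site identifiers and MNI coordinates
#'
#' @slot siteId character vector of unique site labels.
#' @slot coords numeric matrix (#sites x 3) of finite MNI mm coordinates,
#'   columns x, y, z.
#' @export
setClass("SiteTable", representation(siteId = "character", coords = "matrix"))

setValidity("SiteTable", function(object) {
  msg <- NULL
  if (anyDuplicated(object@siteId))
    msg <- c(msg, "site ids must be unique")
  if (ncol(object@coords) != 3L || nrow(object@coords) != length(object@siteId))
    msg <- c(msg, "coords must be (#sites x 3)")
  if (length(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (is.null(msg)) TRUE else msg
})

#' ExpressionMatrix: gene x biopsy-site expression values G(g,s)
#'
#' @slot values numeric matrix, rows = genes (unique labels), columns =
#'   sites in the order of the matching [SiteTable]. `NA` marks missing.
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

.validMatrixLabels <- function(values, what = "gene") {
  msg <- NULL
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    msg <- c(msg, "values must carry row and column labels")
  else if (anyDuplicated(rownames(values)))
    msg <- c(msg, sprintf("%s labels must be unique", what))
  msg
}

setValidity("ExpressionMatrix", function(object) {
  msg <- .validMatrixLabels(object@values, "gene")
  if (is.null(msg)) TRUE else msg
})

#' OmegaTable: gene x branch raw dN/dS estimates with PAML status codes
#'
#' @slot omega numeric matrix, genes x branches, values >= 0 or `NA`.
#' @slot status character matrix of the same shape with codes from
#'   [OMEGA_STATUS_CODES].
#' @export
setClass("OmegaTable", representation(omega = "matrix", status = "matrix"))

setValidity("OmegaTable", function(object) {
  msg <- .validMatrixLabels(object@omega, "gene")
  if (!identical(dim(object@omega), dim(object@status)))
    msg <- c(msg, "omega and status must have identical shape")
  bad <- setdiff(unique(as.vector(object@status)), c(OMEGA_STATUS_CODES, NA))
  if (length(bad))
    msg <- c(msg, paste("unknown status code(s):", paste(bad, collapse = ", ")))
  ok <- object@omega[!is.na(object@omega)]
  if (length(ok) && any(ok < 0))
    msg <- c(msg, "omega values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' CorrelationMatrix: network x gene spatial correlations r(g,n)
#'
#' @slot values numeric matrix, rows = networks, columns = genes, entries in
#'   [-1, 1] or `NA`.
#' @export
setClass("CorrelationMatrix", representation(values = "matrix"))

setValidity("CorrelationMatrix", function(object) {
  msg <- .validMatrixLabels(object@values, "network")
  ok <- object@values[!is.na(object@values)]
  if (length(ok) && (any(ok < -1 - 1e-12) || any(ok > 1 + 1e-12)))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' FNSiteMatrix: network x biopsy-site projected z-scores F(n,s)
#'
#' @slot values numeric matrix, rows = networks, columns = sites; `NA`
#'   where a site had no finite voxel support.
#' @export
setClass("FNSiteMatrix", representation(values = "matrix"))

setValidity("FNSiteMatrix", function(object) {
  msg <- .validMatrixLabels(object@values, "network")
  if (is.null(msg)) TRUE else msg
})

#' NormalizedOmega: branch-wise rank-normalized omega
#'
#' Entries live in [0, 1 + eps]; the formula's denominator counts only
#' strictly positive omega so zero-heavy branches can exceed 1 slightly.
#'
#' @slot values numeric matrix, genes x branches, or `NA`.
#' @export
setClass("NormalizedOmega", representation(values = "matrix"))

setValidity("NormalizedOmega", function(object) {
  msg <- .validMatrixLabels(object@values, "gene")
  if (is.null(msg)) TRUE else msg
})

#' NormalizedCorrelation: per-gene rank-normalized network correlations
#'
#' @slot values numeric matrix, genes x networks, in \{0\} or (0, 1].
#' @slot retained named logical, per-gene flag from the rank-threshold
#'   gene filter.
#' @export
setClass("NormalizedCorrelation",
         representation(values = "matrix", retained = "logical"))

setValidity("NormalizedCorrelation", function(object) {
  msg <- .validMatrixLabels(object@values, "gene")
  if (length(object@retained) != nrow(object@values))
    msg <- c(msg, "retained flag must have one entry per gene")
  if (is.null(msg)) TRUE else msg
})

#' AnalysisMatrix: per-branch concatenation [omega-tilde | r-tilde]
#'
#' @slot values numeric matrix, genes x (omega column(s) then network
#'   columns).
#' @slot columnClass character vector, one of "omega"/"network" per column.
#' @export
setClass("AnalysisMatrix",
         representation(values = "matrix", columnClass = "character"))

setValidity("AnalysisMatrix", function(object) {
  msg <- .validMatrixLabels(object@values, "gene")
  if (length(object@columnClass) != ncol(object@values))
    msg <- c(msg, "columnClass must have one entry per column")
  if (!all(object@columnClass %in% c("omega", "network")))
    msg <- c(msg, "columnClass entries must be 'omega' or 'network'")
  if (is.null(msg)) TRUE else msg
})

#' DomainAssignment: network-to-domain partition with silhouette trace
#'
#' @slot assignment named character, network label -> domain label.
#' @slot domains ordered character vector of domain labels.
#' @slot k number of domains selected.
#' @slot silhouetteByK named numeric, average silhouette width per k.
#' @export
setClass("DomainAssignment", representation(
  assignment = "character", domains = "character",
  k = "integer", silhouetteByK = "numeric"
))

setValidity("DomainAssignment", function(object) {
  msg <- NULL
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by network")
  if (!all(object@assignment %in% object@domains))
    msg <- c(msg, "every assigned domain must appear in domains")
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Bicluster: a gene set x (branch + network) column set with its score
#'
#' @slot genes character vector (nonempty).
#' @slot branches character vector of branch labels.
#' @slot networks character vector of network labels.
#' @slot score non-negative number; the configured size score.
#' @slot runMetadata list (seed, parameter combo, search index, ...).
#' @export
setClass("Bicluster", representation(
  genes = "character", branches = "character", networks = "character",
  score = "numeric", runMetadata = "list"
))

setValidity("Bicluster", function(object) {
  msg <- NULL
  if (length(object@genes) == 0L)
    msg <- c(msg, "gene set must be nonempty")
  if (length(object@branches) + length(object@networks) == 0L)
    msg <- c(msg, "branch and network sets cannot both be empty")
  if (length(object@score) != 1L || is.na(object@score) || object@score < 0)
    msg <- c(msg, "score must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' CellTypeMatrix: gene x cell-cluster mean expression with metadata
#'
#' @slot values non-negative numeric matrix, genes x clusters.
#' @slot metadata data.frame with one row per cluster (rownames = cluster
#'   labels) and columns `supercluster`, `class`, `neurotransmitter`,
#'   `neuronal` (logical).
#' @export
setClass("CellTypeMatrix",
         representation(values = "matrix", metadata = "data.frame"))

setValidity("CellTypeMatrix", function(object) {
  msg <- .validMatrixLabels(object@values, "gene")
  need <- c("supercluster", "class", "neurotransmitter", "neuronal")
  if (!all(need %in% colnames(object@metadata)))
    msg <- c(msg, paste("metadata must contain columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@metadata) != ncol(object@values))
    msg <- c(msg, "metadata must have one row per cluster")
  ok <- object@values[!is.na(object@values)]
  if (length(ok) && any(ok < 0))
    msg <- c(msg, "expression values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' BranchDomainSummary: branch x domain cumulative bicluster evidence
#'
#' @slot normalizedScore branch x domain matrix in [0, 1].
#' @slot uniqueGenes branch x domain matrix of unique gene counts.
#' @slot contributors list of contributing bicluster indices, named
#'   "branch|domain".
#' @export
setClass("BranchDomainSummary", representation(
  normalizedScore = "matrix", uniqueGenes = "matrix", contributors = "list"
))

setValidity("BranchDomainSummary", function(object) {
  msg <- NULL
  if (!identical(dim(object@normalizedScore), dim(object@uniqueGenes)))
    msg <- c(msg, "score and gene-count matrices must share a shape")
  mx <- suppressWarnings(max(object@normalizedScore, 0))
  if (is.finite(mx) && mx > 1 + 1e-9)
    msg <- c(msg, "normalized scores must not exceed 1")
  if (is.null(msg)) TRUE else msg
})

#' EnrichmentResult: cell-cluster enrichment per branch x domain gene set
#'
#' Columns of the three matrices are (branch, domain) cells labelled
#' "branch|domain"; rows are cell clusters.
#'
#' @slot correlation numeric matrix of point-biserial correlations.
#' @slot z numeric matrix of within-cell z-scores across clusters.
#' @slot enriched logical matrix, `TRUE` iff z > the critical value.
#' @slot criticalZ the critical z used (strict inequality).
#' @slot clusterMetadata the cluster metadata carried over from the
#'   [CellTypeMatrix].
#' @export
setClass("EnrichmentResult", representation(
  correlation = "matrix", z = "matrix", enriched = "matrix",
  criticalZ = "numeric", clusterMetadata = "data.frame"
))

setValidity("EnrichmentResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@correlation), dim(object@z)) ||
      !identical(dim(object@z), dim(object@enriched)))
    msg <- c(msg, "correlation, z and enriched must share a shape")
  if (nrow(object@clusterMetadata) != nrow(object@z))
    msg <- c(msg, "clusterMetadata must have one row per cluster")
  if (is.null(msg)) TRUE else msg
})
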