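# Constructors, accessors and show() methods for the core classes.

#' Construct a VolumeMap
#'
#' @param grid 3D numeric array of z-scores.
#' @param affine 4x4 voxel(0-based)-to-MNI-mm transform.
#' @param networkId network label.
#' @return A [VolumeMap-class] object.
#' @export
VolumeMap <- function(grid, affine, networkId = "network") {
  new("VolumeMap", grid = grid, affine = affine,
      networkId = as.character(networkId))
}

#' Construct a SiteTable
#'
#' @param siteId character vector of unique site labels.
#' @param coords numeric matrix or data.frame with columns x, y, z (MNI mm).
#' @return A [SiteTable-class] object.
#' @export
SiteTable <- function(siteId, coords) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- siteId
  new("SiteTable", siteId = as.character(siteId), coords = coords)
}

.labelledMatrix <- function(values, rows, cols) {
  values <- as.matrix(values)
  if (!missing(rows) && !is.null(rows)) rownames(values) <- rows
  if (!missing(cols) && !is.null(cols)) colnames(values) <- cols
  values
}

#' Construct an ExpressionMatrix
#' @param values gene x site numeric matrix.
#' @param genes,sites optional label vectors overriding dimnames.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, genes = NULL, sites = NULL) {
  new("ExpressionMatrix", values = .labelledMatrix(values, genes, sites))
}

#' Construct an OmegaTable
#' @param omega gene x branch numeric matrix of raw dN/dS values.
#' @param status matching character matrix of PAML status codes; defaults
#'   to STABLE wherever omega is present.
#' @param genes,branches optional label vectors overriding dimnames.
#' @return An [OmegaTable-class] object.
#' @export
OmegaTable <- function(omega, status = NULL, genes = NULL, branches = NULL) {
  omega <- .labelledMatrix(omega, genes, branches)
  if (is.null(status)) {
    status <- matrix("STABLE", nrow(omega), ncol(omega),
                     dimnames = dimnames(omega))
    status[is.na(omega)] <- "UNSTABLE"
  } else {
    status <- .labelledMatrix(status, rownames(omega), colnames(omega))
  }
  new("OmegaTable", omega = omega, status = status)
}

#' Construct a CorrelationMatrix
#' @param values network x gene numeric matrix in [-1, 1].
#' @param networks,genes optional label vectors overriding dimnames.
#' @return A [CorrelationMatrix-class] object.
#' @export
CorrelationMatrix <- function(values, networks = NULL, genes = NULL) {
  new("CorrelationMatrix", values = .labelledMatrix(values, networks, genes))
}

#' Construct an FNSiteMatrix
#' @param values network x site numeric matrix of projected z-scores.
#' @param networks,sites optional label vectors overriding dimnames.
#' @return An [FNSiteMatrix-class] object.
#' @export
FNSiteMatrix <- function(values, networks = NULL, sites = NULL) {
  new("FNSiteMatrix", values = .labelledMatrix(values, networks, sites))
}

#' Construct a Bicluster
#' @param genes,branches,networks label sets.
#' @param score non-negative size score.
#' @param runMetadata free-form list (seed, combo, search index).
#' @return A [Bicluster-class] object.
#' @export
Bicluster <- function(genes, branches = character(), networks = character(),
                      score = 0, runMetadata = list()) {
  new("Bicluster", genes = as.character(genes),
      branches = as.character(branches), networks = as.character(networks),
      score = as.numeric(score), runMetadata = runMetadata)
}

#' Construct a CellTypeMatrix
#' @param values gene x cluster non-negative mean-expression matrix.
#' @param metadata data.frame with one row per cluster and columns
#'   supercluster, class, neurotransmitter, neuronal.
#' @return A [CellTypeMatrix-class] object.
#' @export
CellTypeMatrix <- function(values, metadata) {
  values <- as.matrix(values)
  rownames(metadata) <- colnames(values)
  new("CellTypeMatrix", values = values, metadata = metadata)
}

#' @rdname neuroselect-accessors
#' @param object a neuroselect data object.
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' Accessors for neuroselect data classes
#'
#' `values()` returns the underlying labelled matrix; `genes()`,
#' `networks()`, `branches()`, `sites()` and `clusters()` return the
#' corresponding label vectors; `score()` the bicluster score.
#'
#' @name neuroselect-accessors
#' @return The requested component.
NULL

#' @rdname neuroselect-accessors
#' @export
setMethod("values", "ExpressionMatrix", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "CorrelationMatrix", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "FNSiteMatrix", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "NormalizedOmega", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "NormalizedCorrelation", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "AnalysisMatrix", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "CellTypeMatrix", function(object) object@values)
#' @rdname neuroselect-accessors
#' @export
setMethod("values", "OmegaTable", function(object) object@omega)

#' @rdname neuroselect-accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "ExpressionMatrix", function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "OmegaTable", function(object) rownames(object@omega))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "CorrelationMatrix", function(object) colnames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "Bicluster", function(object) object@genes)
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "CellTypeMatrix", function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "NormalizedOmega", function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "NormalizedCorrelation",
          function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("genes", "AnalysisMatrix", function(object) rownames(object@values))

#' @rdname neuroselect-accessors
#' @export
setGeneric("networks", function(object) standardGeneric("networks"))
#' @rdname neuroselect-accessors
#' @export
setMethod("networks", "CorrelationMatrix",
          function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("networks", "FNSiteMatrix", function(object) rownames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("networks", "Bicluster", function(object) object@networks)
#' @rdname neuroselect-accessors
#' @export
setMethod("networks", "DomainAssignment",
          function(object) names(object@assignment))

#' @rdname neuroselect-accessors
#' @export
setGeneric("branches", function(object) standardGeneric("branches"))
#' @rdname neuroselect-accessors
#' @export
setMethod("branches", "OmegaTable", function(object) colnames(object@omega))
#' @rdname neuroselect-accessors
#' @export
setMethod("branches", "NormalizedOmega", function(object) colnames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("branches", "Bicluster", function(object) object@branches)

#' @rdname neuroselect-accessors
#' @export
setGeneric("sites", function(object) standardGeneric("sites"))
#' @rdname neuroselect-accessors
#' @export
setMethod("sites", "SiteTable", function(object) object@siteId)
#' @rdname neuroselect-accessors
#' @export
setMethod("sites", "ExpressionMatrix", function(object) colnames(object@values))
#' @rdname neuroselect-accessors
#' @export
setMethod("sites", "FNSiteMatrix", function(object) colnames(object@values))

#' @rdname neuroselect-accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))
#' @rdname neuroselect-accessors
#' @export
setMethod("clusters", "CellTypeMatrix", function(object) colnames(object@values))

#' @rdname neuroselect-accessors
#' @export
setGeneric("score", function(object) standardGeneric("score"))
#' @rdname neuroselect-accessors
#' @export
setMethod("score", "Bicluster", function(object) object@score)

#' @rdname neuroselect-accessors
#' @export
setGeneric("statusCodes", function(object) standardGeneric("statusCodes"))
#' @rdname neuroselect-accessors
#' @export
setMethod("statusCodes", "OmegaTable", function(object) object@status)

#' @rdname neuroselect-accessors
#' @export
setGeneric("siteCoords", function(object) standardGeneric("siteCoords"))
#' @rdname neuroselect-accessors
#' @export
setMethod("siteCoords", "SiteTable", function(object) object@coords)

#' @rdname neuroselect-accessors
#' @export
setGeneric("domainOf", function(object) standardGeneric("domainOf"))
#' @rdname neuroselect-accessors
#' @export
setMethod("domainOf", "DomainAssignment", function(object) object@assignment)

#' @rdname neuroselect-accessors
#' @export
setGeneric("retainedGenes", function(object) standardGeneric("retainedGenes"))
#' @rdname neuroselect-accessors
#' @export
setMethod("retainedGenes", "NormalizedCorrelation",
          function(object) names(object@retained)[object@retained])

#' @rdname neuroselect-accessors
#' @export
setGeneric("columnClasses", function(object) standardGeneric("columnClasses"))
#' @rdname neuroselect-accessors
#' @export
setMethod("columnClasses", "AnalysisMatrix", function(object) object@columnClass)

setMethod("show", "VolumeMap", function(object) {
  cat(sprintf("VolumeMap '%s': %s grid, %d finite voxels\n",
              object@networkId, paste(dim(object@grid), collapse = "x"),
              sum(is.finite(object@grid))))
})

setMethod("show", "SiteTable", function(object) {
  cat(sprintf("SiteTable: %d biopsy sites (MNI mm)\n", length(object@siteId)))
})

.showMatrixClass <- function(object, what, rows, cols) {
  cat(sprintf("%s: %d %s x %d %s\n", class(object),
              nrow(object@values), rows, ncol(object@values), cols))
}

setMethod("show", "ExpressionMatrix",
          function(object) .showMatrixClass(object, , "genes", "sites"))
setMethod("show", "CorrelationMatrix",
          function(object) .showMatrixClass(object, , "networks", "genes"))
setMethod("show", "FNSiteMatrix",
          function(object) .showMatrixClass(object, , "networks", "sites"))
setMethod("show", "NormalizedOmega",
          function(object) .showMatrixClass(object, , "genes", "branches"))
setMethod("show", "NormalizedCorrelation", function(object) {
  .showMatrixClass(object, , "genes", "networks")
  cat(sprintf("  retained genes: %d\n", sum(object@retained)))
})
setMethod("show", "AnalysisMatrix", function(object) {
  cat(sprintf("AnalysisMatrix: %d genes x %d columns (%d omega, %d network)\n",
              nrow(object@values), ncol(object@values),
              sum(object@columnClass == "omega"),
              sum(object@columnClass == "network")))
})
setMethod("show", "CellTypeMatrix",
          function(object) .showMatrixClass(object, , "genes", "cell clusters"))

setMethod("show", "OmegaTable", function(object) {
  cat(sprintf("OmegaTable: %d genes x %d branches\n",
              nrow(object@omega), ncol(object@omega)))
  print(table(factor(object@status, levels = OMEGA_STATUS_CODES)))
})

setMethod("show", "DomainAssignment", function(object) {
  cat(sprintf("DomainAssignment: %d networks in %d domains (k = %d)\n",
              length(object@assignment), length(object@domains), object@k))
})

setMethod("show", "Bicluster", function(object) {
  cat(sprintf("Bicluster: %d genes x [%s | %s], score %.4g\n",
              length(object@genes), paste(object@branches, collapse = ","),
              paste(object@networks, collapse = ","), object@score))
})

setMethod("show", "BranchDomainSummary", function(object) {
  cat(sprintf("BranchDomainSummary: %d branches x %d domains\n",
              nrow(object@normalizedScore), ncol(object@normalizedScore)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: %d clusters x %d branch|domain cells, %d enriched (Z > %.3g)\n",
    nrow(object@z), ncol(object@z), sum(object@enriched, na.rm = TRUE),
    object@criticalZ))
})
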