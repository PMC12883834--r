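# Readers and writers for the pipeline's on-disk formats:
# NIfTI volumes, TSV matrices (tab-separated, UTF-8, '.' decimal, empty
# cell = missing), JSON biclusters/domains.

.readTSVTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (!length(lines)) stop("empty TSV file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad to the header width
  width <- length(cells[[1L]])
  cells <- lapply(cells, function(x) {
    if (length(x) < width) c(x, rep("", width - length(x))) else x
  })
  n <- lengths(cells)
  if (any(n != width))
    stop("ragged TSV (expected ", width, " fields): ", path)
  header <- cells[[1L]][-1L]
  body <- cells[-1L]
  rowLabels <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(rowLabels))
    stop("duplicate row labels in ", path)
  mat <- do.call(rbind, lapply(body, function(x) x[-1L]))
  if (is.null(mat)) mat <- matrix(character(), 0L, length(header))
  dimnames(mat) <- list(rowLabels, header)
  mat
}

.asNumericMatrix <- function(chr) {
  out <- suppressWarnings(
    matrix(as.numeric(ifelse(chr == "", NA, chr)),
           nrow(chr), ncol(chr), dimnames = dimnames(chr)))
  out
}

#' Read a typed matrix from TSV
#'
#' Expects a header row of column labels and a first column of row labels;
#' empty cells become `NA`. Row and column label order is preserved as in
#' the file.
#'
#' @param path TSV file path.
#' @param kind one of `"expression"` (genes x sites), `"omega"` (genes x
#'   branches; pass `statusPath`), `"correlation"` (networks x genes),
#'   `"celltype"` (genes x clusters; pass `metaPath`), or `"fn"` (networks
#'   x sites).
#' @param statusPath for `kind = "omega"`: parallel TSV of PAML status
#'   codes with identical labels. If omitted, present cells are STABLE and
#'   missing cells UNSTABLE.
#' @param metaPath for `kind = "celltype"`: TSV of cluster metadata with
#'   columns supercluster, class, neurotransmitter, neuronal.
#' @return The matching S4 object.
#' @export
readMatrix <- function(path, kind = c("expression", "omega", "correlation",
                                      "celltype", "fn"),
                       statusPath = NULL, metaPath = NULL) {
  kind <- match.arg(kind)
  chr <- .readTSVTable(path)
  num <- .asNumericMatrix(chr)
  switch(kind,
    expression = ExpressionMatrix(num),
    correlation = CorrelationMatrix(num),
    fn = FNSiteMatrix(num),
    omega = {
      if (is.null(statusPath)) return(OmegaTable(num))
      st <- .readTSVTable(statusPath)
      if (!identical(dimnames(st), dimnames(chr)))
        stop("status TSV labels do not match omega TSV labels")
      st[st == ""] <- NA
      OmegaTable(num, status = st)
    },
    celltype = {
      if (is.null(metaPath))
        stop("celltype matrices require a metadata TSV (metaPath)")
      meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
      rownames(meta) <- meta[[1L]]
      meta <- meta[colnames(num), -1L, drop = FALSE]
      meta$neuronal <- as.logical(meta$neuronal)
      CellTypeMatrix(num, metadata = meta)
    })
}

.formatCell <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 15))
}

.writeTSVMatrix <- function(values, path, charValues = NULL) {
  body <- if (is.null(charValues)) {
    matrix(.formatCell(values), nrow(values), ncol(values))
  } else {
    ifelse(is.na(charValues), "", charValues)
  }
  lines <- c(paste(c("", colnames(values)), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i], body[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a matrix-like object to TSV
#'
#' @param object an [ExpressionMatrix-class], [CorrelationMatrix-class],
#'   [FNSiteMatrix-class], [NormalizedOmega-class], [AnalysisMatrix-class],
#'   [CellTypeMatrix-class] or [OmegaTable-class].
#' @param path output TSV path. For `OmegaTable`, `statusPath` receives the
#'   aligned status-code TSV.
#' @param statusPath see above.
#' @return `path`, invisibly.
#' @export
setGeneric("writeMatrix",
           function(object, path, statusPath = NULL)
             standardGeneric("writeMatrix"))

#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "ExpressionMatrix", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "CorrelationMatrix", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "FNSiteMatrix", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "NormalizedOmega", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "AnalysisMatrix", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "CellTypeMatrix", function(object, path, statusPath)
  .writeTSVMatrix(object@values, path))
#' @rdname writeMatrix
#' @export
setMethod("writeMatrix", "OmegaTable", function(object, path, statusPath) {
  .writeTSVMatrix(object@omega, path)
  if (!is.null(statusPath))
    .writeTSVMatrix(object@omega, statusPath, charValues = object@status)
  invisible(path)
})

#' Write cell-cluster metadata to TSV
#' @param object a [CellTypeMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCellMetadata <- function(object, path) {
  meta <- object@metadata
  df <- cbind(cluster = rownames(meta), meta)
  df$neuronal <- ifelse(df$neuronal, "TRUE", "FALSE")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a NIfTI z-score volume
#'
#' @param path path to a 3D NIfTI file (.nii or .nii.gz).
#' @param networkId network label; defaults to the filename stem.
#' @return A [VolumeMap-class].
#' @export
readVolume <- function(path, networkId = NULL) {
  img <- RNifti::readNifti(path)
  grid <- array(as.vector(img), dim(img))
  if (length(dim(grid)) != 3L)
    stop("expected a 3D image, got ", length(dim(grid)), "D: ", path)
  affine <- structure(RNifti::xform(img), class = NULL)
  attributes(affine) <- list(dim = dim(affine))
  if (is.null(networkId)) {
    networkId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  VolumeMap(grid, affine, networkId)
}

#' Write a VolumeMap to NIfTI
#'
#' @param volume a [VolumeMap-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@grid)
  # pixdim must match the affine's column scales or the writer rescales
  RNifti::pixdim(img) <- sqrt(colSums(volume@affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(volume@affine, code = 2L)
  RNifti::sform(img) <- structure(volume@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.biclusterToList <- function(b) {
  list(genes = as.list(sort(b@genes)),
       branches = as.list(b@branches),
       networks = as.list(sort(b@networks)),
       score = b@score,
       run_metadata = b@runMetadata)
}

#' Write biclusters to JSON
#'
#' Serializes a list of biclusters as a JSON array with a deterministic
#' key order (genes, branches, networks, score, run_metadata); gene and
#' network sets are sorted so equal inputs yield byte-identical files.
#'
#' @param biclusters list of [Bicluster-class] objects (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBiclusters <- function(biclusters, path) {
  payload <- lapply(biclusters, .biclusterToList)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read biclusters back from JSON
#' @param path JSON file written by [writeBiclusters()].
#' @return list of [Bicluster-class] objects.
#' @export
readBiclusters <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    Bicluster(genes = unlist(x$genes),
              branches = as.character(unlist(x$branches)),
              networks = as.character(unlist(x$networks)),
              score = x$score,
              runMetadata = lapply(x$run_metadata, identity))
  })
}

#' Write a domain assignment to JSON
#' @param assignment a [DomainAssignment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDomains <- function(assignment, path) {
  payload <- list(k = assignment@k,
                  domains = as.list(assignment@domains),
                  assignment = as.list(assignment@assignment),
                  silhouette_by_k = as.list(assignment@silhouetteByK))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path, useBytes = TRUE)
  invisible(path)
}

#' Read a domain assignment from JSON
#' @param path JSON file written by [writeDomains()].
#' @return A [DomainAssignment-class].
#' @export
readDomains <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  new("DomainAssignment",
      assignment = unlist(raw$assignment),
      domains = as.character(raw$domains),
      k = as.integer(raw$k),
      silhouetteByK = unlist(raw$silhouette_by_k))
}
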