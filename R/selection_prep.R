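# Relaxed/conservative handling of PAML omega status codes, branch-wise
# rank normalization of omega, per-gene rank normalization of network
# correlations, high/low-omega gene pools with cross-branch harmonization,
# and assembly of the concatenated analysis matrix [omega-tilde | r-tilde].

#' Apply omega status-code constraints
#'
#' Cells with a STABLE estimate are kept in both modes; UNSTABLE and
#' SHORT_EDGE_UNSTABLE cells are always set missing. Under `relaxed`
#' handling, dN = 0 cells become 0 (purifying selection), dS = 0 cells
#' become the maximum retained omega of their branch (adaptive selection)
#' and identical-sequence cells become 0 (neutral evolution); under
#' `conservative` handling all three are set missing.
#'
#' @param raw an [OmegaTable-class] with status codes.
#' @param mode `"relaxed"` (default) or `"conservative"`.
#' @return An [OmegaTable-class] with constraints applied.
#' @export
applyOmegaConstraints <- function(raw, mode = c("relaxed", "conservative")) {
  mode <- match.arg(mode)
  status <- statusCodes(raw)
  bad <- setdiff(unique(as.vector(status)), c(OMEGA_STATUS_CODES, NA))
  if (length(bad))
    stop("unknown status code(s): ", paste(bad, collapse = ", "))
  omega <- values(raw)
  omega[status %in% c("UNSTABLE", "SHORT_EDGE_UNSTABLE")] <- NA_real_
  omega[is.na(status)] <- NA_real_
  if (mode == "conservative") {
    omega[status %in% c("DN_ZERO", "DS_ZERO", "IDENTICAL")] <- NA_real_
  } else {
    omega[status %in% c("DN_ZERO", "IDENTICAL")] <- 0
    for (j in seq_len(ncol(omega))) {
      dsz <- status[, j] == "DS_ZERO" & !is.na(status[, j])
      if (!any(dsz)) next
      kept <- omega[status[, j] == "STABLE" & !is.na(status[, j]), j]
      kept <- kept[!is.na(kept)]
      if (!length(kept)) {
        warning("branch ", colnames(omega)[j],
                ": no stable omega to anchor dS = 0 cells; set missing")
        omega[dsz, j] <- NA_real_
      } else {
        omega[dsz, j] <- max(kept)
      }
    }
  }
  new("OmegaTable", omega = omega, status = status)
}

#' Branch-wise rank normalization of omega
#'
#' For branch j, each present cell gets
#' \eqn{(1 + |\{k \ne i: \omega_{kj} < \omega_{ij}\}|) / |\{k: \omega_{kj}
#' \mathrm{\ present\ and} > 0\}|}, i.e. the competition (minimum-tie) rank
#' over present cells divided by the number of strictly positive cells.
#' Values approaching 1 mark the branch's largest omega; because the
#' denominator excludes zeros, zero-heavy branches can slightly exceed 1.
#'
#' @param omega an [OmegaTable-class] with constraints already applied.
#' @return A [NormalizedOmega-class]; a branch with no strictly positive
#'   cell comes back all-missing with a warning.
#' @export
rankNormalizeOmega <- function(omega) {
  X <- values(omega)
  out <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    denom <- sum(!is.na(x) & x > 0)
    if (denom == 0L) {
      warning("branch ", colnames(X)[j],
              " has no strictly positive omega; all entries set missing")
      next
    }
    out[, j] <- rank(x, ties.method = "min", na.last = "keep") / denom
  }
  new("NormalizedOmega", values = out)
}

#' Select and harmonize high-/low-omega gene pools per branch
#'
#' High pools hold genes with omega > `highCut`; low pools hold genes with
#' omega <= `lowCut` + `tol` (after constraint application, exact zeros by
#' default). With `harmonize = TRUE` every branch's high pool is truncated
#' to the smallest cross-branch high-pool size keeping the largest-omega
#' genes, and low pools symmetrically keeping the smallest.
#'
#' @param omega an [OmegaTable-class] with constraints applied.
#' @param highCut omega threshold for adaptive-selection pools. Default 1.
#' @param lowCut omega threshold for purifying-selection pools. Default 0.
#' @param tol slack added to `lowCut`. Default 1e-9.
#' @param harmonize equalize pool sizes across branches. Default TRUE.
#' @return list with per-branch character vectors `high` and `low`, plus
#'   `highSize`/`lowSize`.
#' @export
buildGenePools <- function(omega, highCut = 1, lowCut = 0, tol = 1e-9,
                           harmonize = TRUE) {
  X <- values(omega)
  gs <- rownames(X)
  pickOrdered <- function(x, idx, decreasing) {
    idx[order(x[idx], gs[idx], decreasing = c(decreasing, FALSE),
              method = "radix")]
  }
  high <- low <- list()
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    hi <- which(!is.na(x) & x > highCut)
    lo <- which(!is.na(x) & x <= lowCut + tol)
    high[[colnames(X)[j]]] <- gs[pickOrdered(x, hi, TRUE)]
    low[[colnames(X)[j]]] <- gs[pickOrdered(x, lo, FALSE)]
  }
  if (harmonize) {
    nHigh <- min(lengths(high))
    nLow <- min(lengths(low))
    if (nHigh == 0L)
      stop("empty high-omega pool after harmonization in branch ",
           names(high)[which.min(lengths(high))])
    if (nLow == 0L)
      stop("empty low-omega pool after harmonization in branch ",
           names(low)[which.min(lengths(low))])
    high <- lapply(high, utils::head, nHigh)
    low <- lapply(low, utils::head, nLow)
  }
  list(high = high, low = low,
       highSize = lengths(high), lowSize = lengths(low))
}

#' Spatially informative genes
#'
#' Genes whose correlation with at least one network exceeds the threshold
#' (on absolute values by default: a strong negative spatial correlation
#' is informative too).
#'
#' @param corr a [CorrelationMatrix-class].
#' @param threshold raw-correlation cutoff (strict >). Default 0.1.
#' @param absolute compare |r| rather than signed r. Default TRUE.
#' @return character vector of retained gene labels.
#' @export
filterSpatialGenes <- function(corr, threshold = 0.1, absolute = TRUE) {
  R <- values(corr)
  if (absolute) R <- abs(R)
  mx <- suppressWarnings(apply(R, 2L, max, na.rm = TRUE))
  colnames(R)[is.finite(mx) & mx > threshold]
}

#' Per-gene rank normalization of network correlations
#'
#' For gene i and network j,
#' \eqn{\tilde r_{ij} = (1 + |\{k \ne j: r_{ik} < r_{ij}\}|)/|n|} with ties
#' taking the largest rank of the tied block, so each gene's best network
#' maps to 1. Afterwards each gene's minimum entry is set to 0, and genes
#' whose overall correlation with every network is low (maximum raw
#' |r| < `lowCorrCut`) have their whole row set to 0. Genes are flagged
#' retained when at least one entry reaches `geneFilterCut` (applied to
#' the rank-normalized row by default, or to raw correlations with
#' `filterOn = "raw"`).
#'
#' @param corr a [CorrelationMatrix-class] (networks x genes).
#' @param lowCorrCut raw-correlation floor under which a gene's row is
#'   zeroed. Default 0.1.
#' @param geneFilterCut retained-gene criterion. Default 0.75.
#' @param absolute use |r| for the `lowCorrCut` test. Default TRUE.
#' @param filterOn apply `geneFilterCut` to `"normalized"` (default) or
#'   `"raw"` values.
#' @return A [NormalizedCorrelation-class] (genes x networks).
#' @export
rankNormalizeCorrelations <- function(corr, lowCorrCut = 0.1,
                                      geneFilterCut = 0.75, absolute = TRUE,
                                      filterOn = c("normalized", "raw")) {
  filterOn <- match.arg(filterOn)
  R <- t(values(corr))            # genes x networks
  n <- ncol(R)
  if (n == 0L) stop("correlation matrix has no networks")
  tilde <- t(apply(R, 1L, function(x)
    rank(x, ties.method = "max", na.last = "keep"))) / n
  dimnames(tilde) <- dimnames(R)
  for (i in seq_len(nrow(tilde))) {
    x <- tilde[i, ]
    if (all(is.na(x))) next
    tilde[i, which(x == min(x, na.rm = TRUE))] <- 0
  }
  rawTest <- if (absolute) abs(R) else R
  mx <- suppressWarnings(apply(rawTest, 1L, max, na.rm = TRUE))
  lowRows <- !is.finite(mx) | mx < lowCorrCut
  tilde[lowRows, ] <- 0
  tilde[is.na(tilde)] <- 0
  retained <- if (filterOn == "normalized") {
    apply(tilde, 1L, function(x) any(x >= geneFilterCut))
  } else {
    apply(R, 1L, function(x) any(!is.na(x) & x > geneFilterCut))
  }
  names(retained) <- rownames(tilde)
  new("NormalizedCorrelation", values = tilde, retained = retained)
}

#' Concatenate one branch's normalized omega with normalized correlations
#'
#' Builds the per-branch analysis matrix [omega-tilde(., branch) |
#' r-tilde], restricted to the requested genes present in both inputs;
#' genes missing the branch's omega-tilde are dropped with a message.
#'
#' @param omegaNorm a [NormalizedOmega-class].
#' @param branch branch label present in `omegaNorm`.
#' @param rNorm a [NormalizedCorrelation-class].
#' @param geneSet genes to keep (e.g. from [filterSpatialGenes()]);
#'   defaults to all genes shared by the two inputs.
#' @return An [AnalysisMatrix-class] with column classes
#'   (omega, network, network, ...).
#' @export
concatenateAnalysis <- function(omegaNorm, branch, rNorm, geneSet = NULL) {
  if (!branch %in% branches(omegaNorm))
    stop("branch not present in normalized omega: ", branch)
  shared <- intersect(genes(omegaNorm), genes(rNorm))
  if (!is.null(geneSet)) shared <- intersect(shared, geneSet)
  om <- values(omegaNorm)[shared, branch]
  drop <- is.na(om)
  if (any(drop))
    message(sum(drop), " gene(s) without omega-tilde on branch ", branch,
            " dropped")
  shared <- shared[!drop]
  if (!length(shared)) stop("no genes left after intersecting inputs")
  out <- cbind(values(omegaNorm)[shared, branch, drop = FALSE],
               values(rNorm)[shared, , drop = FALSE])
  colnames(out)[1L] <- branch
  new("AnalysisMatrix", values = out,
      columnClass = c("omega", rep("network", ncol(out) - 1L)))
}
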