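# Top-N bicluster selection, domain assignment, and branch x domain
# summary matrices.

#' Select the top-scoring biclusters
#'
#' @param biclusters list of [Bicluster-class] objects.
#' @param mode `"overall"` (n highest overall) or `"per_branch"` (n
#'   highest per branch).
#' @param n how many to keep. Ties at the boundary are broken by larger
#'   gene count, then by stable input order.
#' @return list of selected biclusters, sorted by non-increasing score
#'   (within branch for `per_branch`).
#' @export
selectTop <- function(biclusters, mode = c("overall", "per_branch"), n) {
  mode <- match.arg(mode)
  if (n <= 0) stop("n must be positive")
  if (!length(biclusters)) return(list())
  orderOf <- function(idx) {
    sc <- vapply(biclusters[idx], score, numeric(1))
    ng <- vapply(biclusters[idx], function(b) length(genes(b)), numeric(1))
    idx[order(-sc, -ng, seq_along(idx), method = "radix")]
  }
  if (mode == "overall") {
    picked <- utils::head(orderOf(seq_along(biclusters)), n)
    return(biclusters[picked])
  }
  keys <- vapply(biclusters, function(b)
    paste(sort(branches(b)), collapse = "+"), character(1))
  picked <- unlist(lapply(unique(keys), function(k)
    utils::head(orderOf(which(keys == k)), n)))
  biclusters[picked]
}

#' Domains spanned by a bicluster's networks
#'
#' A bicluster whose network composition spans several domains belongs to
#' all of them.
#'
#' @param bicluster a [Bicluster-class].
#' @param assignment a [DomainAssignment-class] covering every network of
#'   the bicluster.
#' @return character vector of domain labels (sorted, unique).
#' @export
assignDomains <- function(bicluster, assignment) {
  map <- domainOf(assignment)
  unknown <- setdiff(networks(bicluster), names(map))
  if (length(unknown))
    stop("network(s) not in the domain assignment: ",
         paste(unknown, collapse = ", "))
  sort(unique(unname(map[networks(bicluster)])))
}

#' Branch x domain summary of a bicluster set
#'
#' Per (branch, domain) cell: the cumulative score of the contributing
#' biclusters, normalized to [0, 1] (by the global matrix maximum, or per
#' branch row), and the number of unique genes in the union of the
#' contributing biclusters. A bicluster spanning several domains (or
#' branches) contributes to each of its cells.
#'
#' @param biclusters list of [Bicluster-class] objects.
#' @param assignment a [DomainAssignment-class].
#' @param normalize `"global"` (default) or `"per_branch"`.
#' @return A [BranchDomainSummary-class].
#' @export
summarizeBiclusters <- function(biclusters, assignment,
                                normalize = c("global", "per_branch")) {
  normalize <- match.arg(normalize)
  branchLabels <- sort(unique(unlist(lapply(biclusters, branches))))
  domainLabels <- assignment@domains
  dims <- list(branchLabels, domainLabels)
  scoreMat <- matrix(0, length(branchLabels), length(domainLabels),
                     dimnames = dims)
  contrib <- list()
  for (i in seq_along(biclusters)) {
    b <- biclusters[[i]]
    doms <- assignDomains(b, assignment)
    for (br in branches(b)) {
      for (d in doms) {
        scoreMat[br, d] <- scoreMat[br, d] + score(b)
        key <- paste(br, d, sep = "|")
        contrib[[key]] <- c(contrib[[key]], i)
      }
    }
  }
  geneMat <- matrix(0L, length(branchLabels), length(domainLabels),
                    dimnames = dims)
  for (key in names(contrib)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    u <- unique(unlist(lapply(biclusters[contrib[[key]]], genes)))
    geneMat[parts[1L], parts[2L]] <- length(u)
  }
  if (normalize == "global") {
    mx <- max(scoreMat)
    if (mx > 0) scoreMat <- scoreMat / mx
  } else {
    for (i in seq_len(nrow(scoreMat))) {
      mx <- max(scoreMat[i, ])
      if (mx > 0) scoreMat[i, ] <- scoreMat[i, ] / mx
    }
  }
  new("BranchDomainSummary", normalizedScore = scoreMat,
      uniqueGenes = geneMat, contributors = contrib)
}
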