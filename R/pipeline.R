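# End-to-end orchestration: projection -> correlation -> domain clustering
# -> omega/correlation preparation -> per-branch, per-direction GA
# biclustering -> merging, top-N selection, branch x domain summary ->
# cell-type enrichment. Deterministic under the master seed; optionally
# writes every intermediate plus a manifest with file hashes.

#' Pipeline configuration
#'
#' Collects every stage's tunables. Inputs may be given in memory
#' (`data = ` output of [makeDataset()] or an equivalently named list) or
#' as file paths (`paths = ` list with volumes dir / sites, expression,
#' omega + status, cells + cellMeta TSVs).
#'
#' @param data in-memory inputs: list with volumes, sites, expression,
#'   omega, cells.
#' @param paths on-disk inputs (see above); ignored when `data` is given.
#' @param projection see [projectionParams()].
#' @param kRange domain-count search range. Default 2:12 (capped at
#'   #networks - 1 at run time).
#' @param clusterNetworks set FALSE to skip domain clustering; every
#'   network then forms its own singleton domain and biclusters are
#'   analyzed at single-network level.
#' @param omegaMode `"relaxed"` or `"conservative"`.
#' @param spatialThreshold raw-correlation informativeness filter.
#'   Default 0.1.
#' @param geneFilterCut rank-normalized retained-gene criterion.
#'   Default 0.75.
#' @param networkMin incidence threshold on rank-normalized correlations.
#'   Default 0.75.
#' @param highCut,lowCut omega pool thresholds. Defaults 1 and 0.
#' @param gabiHigh,gabiLow [gabiParams()] per direction; documented
#'   defaults use popsize 250 (high) and 1200 (low).
#' @param directions which omega directions to mine. Default both.
#' @param topMode,topN bicluster selection. Defaults "per_branch", 20.
#' @param enrichPct cell-expression percentile filter. Default 90.
#' @param criticalZ enrichment critical z. Default 1.96.
#' @param seed master seed; per-run child seeds derive from it.
#' @param outDir optional output directory for all intermediates.
#' @return configuration list.
#' @export
pipelineConfig <- function(data = NULL, paths = NULL,
                           projection = projectionParams(),
                           kRange = 2:12, clusterNetworks = TRUE,
                           omegaMode = "relaxed", spatialThreshold = 0.1,
                           geneFilterCut = 0.75, networkMin = 0.75,
                           highCut = 1, lowCut = 0,
                           gabiHigh = gabiParams(popsize = 250L),
                           gabiLow = gabiParams(popsize = 1200L),
                           directions = c("high", "low"),
                           topMode = "per_branch", topN = 20L,
                           enrichPct = 90, criticalZ = 1.96,
                           seed = 1L, outDir = NULL) {
  list(data = data, paths = paths, projection = projection,
       kRange = kRange, clusterNetworks = isTRUE(clusterNetworks),
       omegaMode = omegaMode, spatialThreshold = spatialThreshold,
       geneFilterCut = geneFilterCut, networkMin = networkMin,
       highCut = highCut, lowCut = lowCut,
       gabiHigh = gabiHigh, gabiLow = gabiLow,
       directions = match.arg(directions, c("high", "low"),
                              several.ok = TRUE),
       topMode = topMode, topN = as.integer(topN),
       enrichPct = enrichPct, criticalZ = criticalZ,
       seed = as.integer(seed), outDir = outDir)
}

#' Validate a pipeline configuration
#'
#' Returns findings instead of stopping: missing input files,
#' out-of-range thresholds, and a `global_optim` that is not a multiple
#' of 4 (the parameter-cycling loop covers all four combinations only
#' then).
#'
#' @param config see [pipelineConfig()].
#' @return data.frame with columns `level` ("error"/"warning") and
#'   `message`; empty when the configuration is clean.
#' @export
validateConfig <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  if (!is.null(config$paths)) {
    for (p in unlist(config$paths)) {
      if (!file.exists(p)) add("error", paste("missing input file:", p))
    }
  }
  if (config$projection$gaussSigma <= 0)
    add("error", "gaussSigma must be positive")
  if (config$projection$densityThreshold <= 0)
    add("error", "densityThreshold must be positive")
  for (nm in c("spatialThreshold", "geneFilterCut", "networkMin")) {
    v <- config[[nm]]
    if (v < 0 || v > 1) add("error", paste(nm, "must lie in [0, 1]"))
  }
  for (dir in c("gabiHigh", "gabiLow")) {
    go <- config[[dir]]$global_optim
    if (go > 0L && go %% 4L != 0L)
      add("warning", paste0(dir, ": global_optim = ", go,
                            " is not a multiple of 4; the parameter cycle",
                            " will be uneven"))
  }
  if (!length(findings))
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

.loadInputs <- function(config) {
  if (!is.null(config$data)) return(config$data)
  p <- config$paths
  if (is.null(p)) stop("pipeline needs either in-memory data or paths")
  volFiles <- sort(list.files(p$volumes, pattern = "\\.nii(\\.gz)?$",
                              full.names = TRUE))
  siteDf <- utils::read.delim(p$sites, stringsAsFactors = FALSE)
  list(volumes = lapply(volFiles, readVolume),
       sites = SiteTable(siteDf[[1L]], siteDf[, c("x", "y", "z")]),
       expression = readMatrix(p$expression, "expression"),
       omega = readMatrix(p$omega, "omega", statusPath = p$status),
       cells = readMatrix(p$cells, "celltype", metaPath = p$cellMeta))
}

.stageLog <- function(stage, detail) {
  message(sprintf("[%s] %s", stage, detail))
}

#' Run the full workflow
#'
#' Executes projection, correlation, domain clustering, preparation, GA
#' biclustering per branch and direction, merging, top-N selection,
#' branch x domain summarization and cell-type enrichment. When
#' `config$outDir` is set, every intermediate is written in its standard
#' format together with a manifest (md5 hashes, seed, timings).
#'
#' @param config see [pipelineConfig()].
#' @return list with fn, correlation, domains, omegaNorm, pools, rNorm,
#'   biclusters (merged, all runs), top, summary, enrichment (result +
#'   collapsed counts), manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  findings <- validateConfig(config)
  if (any(findings$level == "error"))
    stop("invalid configuration:\n  ",
         paste(findings$message[findings$level == "error"],
               collapse = "\n  "))
  inputs <- .loadInputs(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  fn <- projectAll(inputs$volumes, inputs$sites, config$projection)
  .stageLog("project", sprintf("%d networks x %d sites", nrow(values(fn)),
                               ncol(values(fn))))
  tick("project")

  corr <- spearmanCorrelate(inputs$expression, fn)
  .stageLog("correlate", sprintf("%d networks x %d genes",
                                 nrow(values(corr)), ncol(values(corr))))
  tick("correlate")

  nNet <- nrow(values(corr))
  if (config$clusterNetworks) {
    kR <- config$kRange[config$kRange <= nNet - 1L & config$kRange >= 2L]
    domains <- clusterDomains(corr, kR)
  } else {
    assignment <- stats::setNames(paste0("D", seq_len(nNet)),
                                  networks(corr))
    domains <- new("DomainAssignment", assignment = assignment,
                   domains = unname(assignment), k = nNet,
                   silhouetteByK = numeric())
  }
  .stageLog("domains", sprintf("k = %d", domains@k))
  tick("domains")

  omegaC <- applyOmegaConstraints(inputs$omega, config$omegaMode)
  omegaNorm <- rankNormalizeOmega(omegaC)
  pools <- buildGenePools(omegaC, highCut = config$highCut,
                          lowCut = config$lowCut)
  spatial <- filterSpatialGenes(corr, config$spatialThreshold)
  rNorm <- rankNormalizeCorrelations(corr,
                                     lowCorrCut = config$spatialThreshold,
                                     geneFilterCut = config$geneFilterCut)
  .stageLog("prep", sprintf("%d spatially informative genes, pools %d/%d",
                            length(spatial), pools$highSize[1L],
                            pools$lowSize[1L]))
  tick("prep")

  allBiclusters <- list()
  branchIdx <- 0L
  for (branch in branches(omegaNorm)) {
    branchIdx <- branchIdx + 1L
    for (direction in config$directions) {
      params <- if (direction == "high") config$gabiHigh else config$gabiLow
      params$seed <- .deriveSeed(config$seed,
                                 branchIdx * 2L +
                                   (direction == "low") + 1000L)
      analysis <- concatenateAnalysis(omegaNorm, branch, rNorm, spatial)
      spec <- branchThresholds(omegaNorm, pools, branch, direction,
                               networkMin = config$networkMin)
      inc <- binarize(analysis, spec)
      found <- if (params$global_optim >= 1L) {
        globalOptimLoop(inc, params = params)
      } else {
        gabiSearch(inc, params = params)
      }
      found <- lapply(found, function(b) {
        b@runMetadata$direction <- direction
        b
      })
      merged <- mergeBiclusters(found, params = params)
      allBiclusters <- c(allBiclusters, merged)
    }
  }
  .stageLog("gabi", sprintf("%d merged biclusters", length(allBiclusters)))
  tick("gabi")

  top <- selectTop(allBiclusters, mode = config$topMode, n = config$topN)
  summary <- summarizeBiclusters(top, domains)
  tick("postprocess")

  enrichment <- NULL
  collapsed <- NULL
  if (!is.null(inputs$cells)) {
    universe <- intersect(genes(inputs$omega), genes(inputs$cells))
    cellsF <- percentileFilter(inputs$cells, config$enrichPct)
    cols <- names(summary@contributors)
    corMat <- NULL
    usable <- character()
    for (key in cols) {
      gset <- intersect(
        unique(unlist(lapply(top[summary@contributors[[key]]], genes))),
        universe)
      if (!length(gset) || length(gset) == length(universe)) next
      cc <- enrichGeneSet(gset, cellsF, universe)
      corMat <- cbind(corMat, cc)
      usable <- c(usable, key)
    }
    if (!is.null(corMat)) {
      colnames(corMat) <- usable
      enrichment <- zscoreBinarize(corMat, cellsF@metadata,
                                   criticalZ = config$criticalZ)
      collapsed <- lapply(
        c(supercluster = "supercluster", class = "class",
          neurotransmitter = "neurotransmitter"),
        function(by) collapseEnrichment(enrichment, by))
    }
  }
  tick("enrich")

  result <- list(fn = fn, correlation = corr, domains = domains,
                 omegaNorm = omegaNorm, pools = pools, rNorm = rNorm,
                 biclusters = allBiclusters, top = top, summary = summary,
                 enrichment = enrichment, collapsed = collapsed,
                 seed = config$seed, timings = timings)

  if (!is.null(config$outDir)) {
    result$manifest <- .writeOutputs(result, config)
  }
  result
}

.writeOutputs <- function(result, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(config$outDir, ...)
  writeMatrix(result$fn, f("fn.tsv"))
  writeMatrix(result$correlation, f("corr.tsv"))
  writeDomains(result$domains, f("domains.json"))
  writeMatrix(result$omegaNorm, f("omega_norm.tsv"))
  writeBiclusters(result$biclusters, f("biclusters.json"))
  writeBiclusters(result$top, f("top_biclusters.json"))
  summaryPayload <- list(
    normalized_score = as.data.frame(result$summary@normalizedScore),
    unique_genes = as.data.frame(result$summary@uniqueGenes),
    contributors = result$summary@contributors)
  writeLines(jsonlite::toJSON(summaryPayload, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             f("summary.json"), useBytes = TRUE)
  if (!is.null(result$enrichment)) {
    enr <- result$enrichment
    payload <- list(
      critical_z = enr@criticalZ,
      z = as.data.frame(enr@z),
      enriched = as.data.frame(enr@enriched),
      collapsed = result$collapsed)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, dataframe = "columns"),
               f("enrichment.json"), useBytes = TRUE)
  }
  files <- list.files(config$outDir, full.names = TRUE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   timings = as.list(result$timings),
                   files = as.list(tools::md5sum(files)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             f("manifest.json"), useBytes = TRUE)
  manifest
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; `paths`,
#' `projection`, `gabiHigh` and `gabiLow` are nested maps whose fields
#' mirror [projectionParams()] and [gabiParams()].
#'
#' @param path YAML file.
#' @return configuration list, as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$projection))
    args$projection <- do.call(projectionParams, raw$projection)
  if (!is.null(raw$gabiHigh))
    args$gabiHigh <- do.call(gabiParams, raw$gabiHigh)
  if (!is.null(raw$gabiLow))
    args$gabiLow <- do.call(gabiParams, raw$gabiLow)
  if (!is.null(raw$kRange)) args$kRange <- raw$kRange[1L]:raw$kRange[2L]
  do.call(pipelineConfig, args)
}
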