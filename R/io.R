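#' Serialize a region graph to JSON
#'
#' @param graph a [RegionGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegionGraphJSON <- function(graph, path) {
  obj <- list(
    region_ids = regionIds(graph),
    edges = if (nrow(regionEdges(graph))) regionEdges(graph)
      else matrix(integer(), 0L, 2L),
    coords = regionCoords(graph),
    demographics = demographics(graph),
    kernel_bandwidth = kernelBandwidth(graph)
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a region graph from JSON
#'
#' @param path JSON file written by [writeRegionGraphJSON()].
#' @return A [RegionGraph-class].
#' @export
readRegionGraphJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) matrix(as.integer(obj$edges), ncol = 2L)
    else matrix(integer(), 0L, 2L)
  new("RegionGraph",
      regionIds = as.character(obj$region_ids),
      edges = edges,
      coords = matrix(as.numeric(obj$coords), ncol = 2L),
      demographics = as.data.frame(obj$demographics,
                                   stringsAsFactors = FALSE),
      kernelBandwidth = as.numeric(obj$kernel_bandwidth))
}

#' Write a summary series as long-format CSV
#'
#' Columns: `time`, `region`, `feature`, `value`, plus `label` when
#' anomaly labels are present.
#'
#' @param series a [SummarySeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSummarySeriesCSV <- function(series, path) {
  Z <- seriesValues(series)
  d <- dim(Z)
  df <- data.frame(
    time = rep(timeIndex(series), times = d[2L] * d[3L]),
    region = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    feature = rep(featureNames(series), each = d[1L] * d[2L]),
    value = as.vector(Z)
  )
  if (nrow(anomalyLabels(series)))
    df$label <- rep(as.vector(anomalyLabels(series)), times = d[3L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a summary series from long-format CSV
#'
#' @param path CSV written by [writeSummarySeriesCSV()].
#' @return A [SummarySeries-class].
#' @export
readSummarySeriesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  feats <- unique(df$feature)
  times <- sort(unique(df$time))
  regions <- sort(unique(df$region))
  T <- length(times); M <- length(regions); k <- length(feats)
  Z <- array(NA_real_, dim = c(T, M, k))
  ti <- match(df$time, times); rj <- match(df$region, regions)
  fk <- match(df$feature, feats)
  Z[cbind(ti, rj, fk)] <- df$value
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- matrix(0L, T, M)
    labels[cbind(ti, rj)] <- as.integer(df$label)
  }
  newSummarySeries(Z, featureNames = feats, timeIndex = times,
                   anomalyLabels = labels)
}

#' Write a policy series as CSV with a JSON scheme sidecar
#'
#' Columns: `time`, `region`, one column per encoded component, and
#' `missing`. The encoding scheme is written to `<path>.scheme.json`.
#'
#' @param policy a [PolicySeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePolicySeriesCSV <- function(policy, path) {
  P <- seriesValues(policy)
  d <- dim(P)
  scheme <- policyScheme(policy)
  df <- data.frame(
    time = rep(seq_len(d[1L]), times = d[2L]),
    region = rep(seq_len(d[2L]), each = d[1L])
  )
  comp <- matrix(P, d[1L] * d[2L], d[3L])
  colnames(comp) <- scheme$layout %||% paste0("component_", seq_len(d[3L]))
  df <- cbind(df, comp)
  df$missing <- as.integer(as.vector(missingMask(policy)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(scheme, paste0(path, ".scheme.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a policy series from CSV (+ JSON scheme sidecar)
#'
#' @param path CSV written by [writePolicySeriesCSV()].
#' @return A [PolicySeries-class].
#' @export
readPolicySeriesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  schemePath <- paste0(path, ".scheme.json")
  scheme <- if (file.exists(schemePath))
    jsonlite::read_json(schemePath, simplifyVector = TRUE)
  else defaultPolicyScheme()
  compCols <- setdiff(names(df), c("time", "region", "missing"))
  times <- sort(unique(df$time)); regions <- sort(unique(df$region))
  T <- length(times); M <- length(regions); r <- length(compCols)
  P <- array(0, dim = c(T, M, r))
  mask <- matrix(FALSE, T, M)
  ti <- match(df$time, times); rj <- match(df$region, regions)
  for (cc in seq_len(r)) P[cbind(ti, rj, cc)] <- df[[compCols[cc]]]
  mask[cbind(ti, rj)] <- df$missing == 1L
  scheme$r <- r
  new("PolicySeries", values = P, missingMask = mask, scheme = scheme)
}

#' Write an alarm stream as CSV
#'
#' @param alarms alarm data.frame from [detectStream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAlarmsCSV <- function(alarms, path) {
  write.csv(alarms, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model
#'
#' The parameter set is serialized with `saveRDS` and the configuration is
#' mirrored into a human-readable JSON sidecar (`<path>.config.json`).
#'
#' @param model a [HetModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveHetModel <- function(model, path) {
  saveRDS(model, path)
  cfg <- model@config
  jsonlite::write_json(
    list(nFeatures = cfg@nFeatures, policyDim = cfg@policyDim,
         depth = cfg@depth, dModel = cfg@dModel, nHeads = cfg@nHeads,
         dFf = cfg@dFf, latentDim = cfg@latentDim,
         intHidden = cfg@intHidden, dropout = cfg@dropout,
         useKernelPrior = cfg@useKernelPrior,
         varianceFloor = cfg@varianceFloor, seed = cfg@seed,
         fitted = model@fitted),
    paste0(path, ".config.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveHetModel
#' @export
loadHetModel <- function(path) {
  readRDS(path)
}
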