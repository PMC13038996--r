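#' Kernelized spatial influence matrix
#'
#' Squared-exponential influence weights between regions,
#' `W[j,k] = exp(-||g_j - g_k||^2 / sigma^2)`, computed from the region
#' coordinates. The matrix is symmetric with unit diagonal, entries in
#' (0, 1], and strictly decreasing in pairwise distance.
#'
#' @param graph a [RegionGraph-class].
#' @param sigma kernel bandwidth; defaults to the graph's bandwidth.
#' @return numeric M x M matrix.
#' @export
kernelInfluenceMatrix <- function(graph, sigma = kernelBandwidth(graph)) {
  stopIfNot(is.numeric(sigma) && length(sigma) == 1L && sigma > 0,
            "sigma must be a positive scalar")
  co <- regionCoords(graph)
  d2 <- as.matrix(dist(co))^2
  W <- exp(-d2 / sigma^2)
  dimnames(W) <- list(regionIds(graph), regionIds(graph))
  W
}

#' Assign detections to regions
#'
#' Maps each detection centroid to the region whose nearest-neighbour cell
#' contains it (the region coordinate closest in Euclidean distance).
#' Boundary ties break deterministically to the lowest region index.
#'
#' @param detections detection table (see [simulateDetections()]).
#' @param graph a [RegionGraph-class].
#' @return integer vector of region indices, one per detection row, with
#'   the region ids as names.
#' @export
assignRegions <- function(detections, graph) {
  stopIfNot(nRegions(graph) >= 1L, "graph must contain regions")
  co <- regionCoords(graph)
  n <- nrow(detections)
  if (n == 0L) return(setNames(integer(), character()))
  d2 <- outer(detections$x, co[, 1L], "-")^2 +
    outer(detections$y, co[, 2L], "-")^2
  idx <- max.col(-d2, ties.method = "first")
  setNames(idx, regionIds(graph)[idx])
}

#' Aggregate detections into region-level summaries
#'
#' The aggregation operator pools individual detections over non-overlapping
#' left-aligned half-open time windows `[t0, t0 + window)` and computes, per
#' region and window: per-frame density (count / window length), mean
#' velocity, mean activity, and the compliance fraction. Region-windows with
#' no detections yield zeros and are flagged invalid (the grid stays dense).
#'
#' @param detections detection table.
#' @param assignment integer region assignment from [assignRegions()].
#' @param graph a [RegionGraph-class].
#' @param window window length in frames (>= 1). A window longer than the
#'   series produces a single truncated window with a warning.
#' @return A [SummarySeries-class] with features
#'   `density`, `mean_velocity`, `mean_activity`, `compliance_rate` and a
#'   `validMask` marking populated cells.
#' @export
aggregateWindow <- function(detections, assignment, graph, window = 5L) {
  stopIfNot(window >= 1, "window must be >= 1")
  window <- as.integer(window)
  M <- nRegions(graph)
  Tmax <- if (nrow(detections)) max(detections$time) else 1L
  if (window > Tmax) {
    warning("window longer than the series; producing one truncated window")
  }
  nW <- max(1L, ceiling(Tmax / window))
  feats <- c("density", "mean_velocity", "mean_activity", "compliance_rate")
  vals <- array(0, dim = c(nW, M, length(feats)))
  valid <- matrix(FALSE, nW, M)
  if (nrow(detections)) {
    win <- ((as.integer(detections$time) - 1L) %/% window) + 1L
    grp <- interaction(win, assignment, drop = TRUE)
    split_idx <- split(seq_len(nrow(detections)), grp)
    for (idx in split_idx) {
      w <- win[idx[1L]]
      j <- assignment[idx[1L]]
      # effective window length accounts for truncation at the series end
      len <- min(window, Tmax - (w - 1L) * window)
      vals[w, j, 1L] <- length(idx) / len
      vals[w, j, 2L] <- mean(detections$velocity[idx])
      vals[w, j, 3L] <- mean(detections$activity[idx])
      vals[w, j, 4L] <- mean(detections$compliance[idx])
      valid[w, j] <- TRUE
    }
  }
  newSummarySeries(vals, featureNames = feats,
                   timeIndex = (seq_len(nW) - 1L) * window + 1L,
                   validMask = valid)
}
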