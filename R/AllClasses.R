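#' @import methods
NULL

#' RegionGraph: spatial units, adjacency and demographics
#'
#' An undirected graph over `M` spatial surveillance units. Each region
#' carries a coordinate in the unit square (used by the Gaussian influence
#' kernel and by detection-to-region assignment) and categorical demographic
#' attributes (age band, income band, urbanicity) used for subgroup fairness
#' stratification.
#'
#' @slot regionIds character vector of M unique region identifiers.
#' @slot edges integer matrix with two columns; each row an unordered pair of
#'   region indices. No self-edges are stored (self-influence is handled by
#'   convention downstream).
#' @slot coords numeric M x 2 matrix of region coordinates in the unit square.
#' @slot demographics data.frame with one row per region and columns
#'   `ageBand`, `incomeBand`, `urbanicity`.
#' @slot kernelBandwidth positive scalar bandwidth sigma of the squared
#'   exponential influence kernel.
#'
#' @seealso [makeRegionGraph()], [kernelInfluenceMatrix()]
#' @exportClass RegionGraph
setClass("RegionGraph",
  representation(
    regionIds = "character",
    edges = "matrix",
    coords = "matrix",
    demographics = "data.frame",
    kernelBandwidth = "numeric"
  )
)

setValidity("RegionGraph", function(object) {
  M <- length(object@regionIds)
  msg <- character()
  if (M < 1L) msg <- c(msg, "need at least one region")
  if (anyDuplicated(object@regionIds)) msg <- c(msg, "region ids must be unique")
  if (nrow(object@coords) != M || ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be an M x 2 matrix")
  if (nrow(object@demographics) != M)
    msg <- c(msg, "demographics must have one row per region")
  if (!all(c("ageBand", "incomeBand", "urbanicity") %in% names(object@demographics)))
    msg <- c(msg, "demographics needs ageBand, incomeBand, urbanicity columns")
  if (length(object@kernelBandwidth) != 1L || object@kernelBandwidth <= 0)
    msg <- c(msg, "kernelBandwidth must be a positive scalar")
  e <- object@edges
  if (nrow(e) > 0L) {
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else {
      if (any(e < 1L) || any(e > M)) msg <- c(msg, "edge endpoints out of range")
      if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-edges are not stored")
      key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SummarySeries: region-level multivariate health summaries
#'
#' A dense T x M x k grid of region-level summary features (for example
#' density, mean activity and compliance rate), with optional exogenous
#' covariate channels, optional binary anomaly labels per region-time cell,
#' and an optional validity mask for cells produced from empty
#' detection windows.
#'
#' @slot values numeric T x M x k array, no missing entries.
#' @slot covariates optional numeric T x M x c array (0-extent third
#'   dimension when absent).
#' @slot anomalyLabels integer T x M matrix in {0,1}; zero-row matrix when
#'   labels are absent.
#' @slot featureNames character vector of k feature labels.
#' @slot timeIndex strictly increasing numeric time stamps of length T.
#' @slot validMask logical T x M matrix; FALSE marks cells synthesised as
#'   zeros from empty aggregation windows.
#' @exportClass SummarySeries
setClass("SummarySeries",
  representation(
    values = "array",
    covariates = "array",
    anomalyLabels = "matrix",
    featureNames = "character",
    timeIndex = "numeric",
    validMask = "matrix"
  )
)

setValidity("SummarySeries", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a T x M x k array")
  if (anyNA(object@values)) msg <- c(msg, "values must have no missing entries")
  if (length(object@featureNames) != d[3L])
    msg <- c(msg, "featureNames length must equal k")
  if (length(object@timeIndex) != d[1L])
    msg <- c(msg, "timeIndex length must equal T")
  if (d[1L] > 1L && any(diff(object@timeIndex) <= 0))
    msg <- c(msg, "timeIndex must be strictly increasing")
  if (nrow(object@anomalyLabels) > 0L) {
    if (!all(dim(object@anomalyLabels) == d[1:2]))
      msg <- c(msg, "anomalyLabels must be T x M")
    else if (!all(object@anomalyLabels %in% c(0L, 1L)))
      msg <- c(msg, "anomalyLabels must be binary")
  }
  if (nrow(object@validMask) > 0L && !all(dim(object@validMask) == d[1:2]))
    msg <- c(msg, "validMask must be T x M")
  cv <- dim(object@covariates)
  if (length(cv) == 3L && cv[3L] > 0L && !all(cv[1:2] == d[1:2]))
    msg <- c(msg, "covariates must align with values on T and M")
  if (length(msg)) msg else TRUE
})

#' PolicySeries: encoded intervention vectors with missingness
#'
#' A T x M x r grid of encoded policy vectors together with a cell-level
#' missingness mask (a masked cell hides the whole r-vector at one
#' region-time) and the encoding scheme metadata.
#'
#' @slot values numeric T x M x r array of encoded intervention vectors.
#' @slot missingMask logical T x M matrix; TRUE marks masked cells.
#' @slot scheme list describing the encoding (index scale, category levels,
#'   component layout); see [defaultPolicyScheme()].
#' @exportClass PolicySeries
setClass("PolicySeries",
  representation(
    values = "array",
    missingMask = "matrix",
    scheme = "list"
  )
)

setValidity("PolicySeries", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a T x M x r array")
  if (!all(dim(object@missingMask) == d[1:2]))
    msg <- c(msg, "missingMask must be T x M")
  if (!is.logical(object@missingMask))
    msg <- c(msg, "missingMask must be logical")
  obs <- !object@missingMask
  if (any(obs)) {
    stringency <- object@values[, , 1L, drop = FALSE][obs]
    if (any(is.finite(stringency) & (stringency < 0 | stringency > 1)))
      msg <- c(msg, "observed stringency components must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' GaussianForecast: per-cell predictive mean and diagonal variance
#'
#' Predictive Gaussian distributions for a T x M grid of k-dimensional
#' summaries. Variances are stored as a diagonal (one value per feature),
#' floored at a small positive constant.
#'
#' @slot mean numeric T x M x k array of predictive means.
#' @slot variance numeric T x M x k array of positive predictive variances.
#' @slot varianceFloor positive scalar floor applied to the variances.
#' @exportClass GaussianForecast
setClass("GaussianForecast",
  representation(
    mean = "array",
    variance = "array",
    varianceFloor = "numeric"
  )
)

setValidity("GaussianForecast", function(object) {
  msg <- character()
  if (!all(dim(object@mean) == dim(object@variance)))
    msg <- c(msg, "mean and variance must share dimensions")
  v <- object@variance
  if (length(v) && any(v < object@varianceFloor - 1e-12, na.rm = TRUE))
    msg <- c(msg, "variances must respect the floor")
  if (length(msg)) msg else TRUE
})

#' HetConfig: architecture configuration for the hierarchical forecaster
#'
#' Holds the widths and depths of the spatio-temporal transformer: the
#' temporal stack depth `depth`, model width `dModel`, number of attention
#' heads `nHeads` (head width is `dModel / nHeads`), feed-forward width
#' `dFf`, graph-attention/latent width `latentDim`, intervention-encoder
#' hidden width `intHidden`, dropout rate, and the variance floor of the
#' Gaussian head. `useKernelPrior` multiplies graph-attention scores by the
#' spatial kernel prior.
#'
#' @exportClass HetConfig
setClass("HetConfig",
  representation(
    nFeatures = "integer",
    policyDim = "integer",
    depth = "integer",
    dModel = "integer",
    nHeads = "integer",
    dFf = "integer",
    latentDim = "integer",
    intHidden = "integer",
    dropout = "numeric",
    useKernelPrior = "logical",
    varianceFloor = "numeric",
    seed = "integer"
  )
)

setValidity("HetConfig", function(object) {
  msg <- character()
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  for (s in c("nFeatures", "policyDim", "dModel", "nHeads", "dFf",
              "latentDim", "intHidden")) {
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
  }
  if (object@depth < 0L) msg <- c(msg, "depth must be >= 0")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@varianceFloor <= 0) msg <- c(msg, "varianceFloor must be positive")
  if (length(msg)) msg else TRUE
})

#' HetModel: parameterized hierarchical forecaster
#'
#' Bundles a [HetConfig-class] with the full parameter set (projection,
#' temporal transformer layers, graph attention, intervention encoders,
#' gating, prediction heads) as a named list of numeric matrices/vectors.
#'
#' @slot config a [HetConfig-class].
#' @slot params named list of parameter arrays.
#' @slot fitted logical; TRUE after gradient training.
#' @exportClass HetModel
setClass("HetModel",
  representation(
    config = "HetConfig",
    params = "list",
    fitted = "logical"
  )
)

#' CalibrationState: feedback-driven latent calibration state
#'
#' Per-region state of the divergence-gated latent calibration: the
#' exponential-moving-average baseline latent, the EMA decay, the gate
#' parameters mapping a scalar divergence to an m-dimensional gate, and the
#' append-only divergence history.
#'
#' @slot baseline numeric latent baseline vector (length m), NA before
#'   initialization.
#' @slot rho EMA decay in (0,1).
#' @slot wDelta,bDelta numeric length-m gate parameters:
#'   gate = sigmoid(wDelta * delta + bDelta).
#' @slot history numeric vector of observed divergences, time ordered.
#' @exportClass CalibrationState
setClass("CalibrationState",
  representation(
    baseline = "numeric",
    rho = "numeric",
    wDelta = "numeric",
    bDelta = "numeric",
    history = "numeric"
  )
)

setValidity("CalibrationState", function(object) {
  msg <- character()
  if (object@rho <= 0 || object@rho >= 1) msg <- c(msg, "rho must lie in (0,1)")
  if (length(object@wDelta) != length(object@baseline) ||
      length(object@bDelta) != length(object@baseline))
    msg <- c(msg, "gate parameters must match the latent dimension")
  if (length(msg)) msg else TRUE
})

#' ThresholdState: dynamic alarm threshold controller state
#'
#' State of the rolling-quantile alarm threshold controller: the current
#' threshold, the target false-alarm rate, the miss-penalty weight (in
#' divergence units), the rolling window length, and realized
#' false-alarm / miss-rate histories.
#'
#' @slot tau current threshold.
#' @slot targetFaRate target false-alarm rate in (0,1).
#' @slot missPenalty nonnegative miss-penalty weight (divergence units).
#' @slot window rolling window length (>= 1).
#' @slot faHistory,missHistory realized false-alarm and miss rates per update.
#' @exportClass ThresholdState
setClass("ThresholdState",
  representation(
    tau = "numeric",
    targetFaRate = "numeric",
    missPenalty = "numeric",
    window = "integer",
    faHistory = "numeric",
    missHistory = "numeric"
  )
)

setValidity("ThresholdState", function(object) {
  msg <- character()
  if (object@targetFaRate <= 0 || object@targetFaRate >= 1)
    msg <- c(msg, "targetFaRate must lie in (0,1)")
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (object@missPenalty < 0) msg <- c(msg, "missPenalty must be >= 0")
  if (!is.finite(object@tau)) msg <- c(msg, "tau must be finite")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: gradient-training configuration
#'
#' Composite-loss weights (`alpha` on the squared forecast error, `beta` on
#' the Gaussian negative log-likelihood), Adam learning rate with linear
#' warm-up and decay, weight decay, epoch budget, early-stopping patience on
#' validation AUC, window/batch sizes and the training seed.
#'
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    alpha = "numeric",
    beta = "numeric",
    learningRate = "numeric",
    weightDecay = "numeric",
    warmupEpochs = "integer",
    maxEpochs = "integer",
    patience = "integer",
    batchSize = "integer",
    windowLen = "integer",
    stepsPerEpoch = "integer",
    aucTolerance = "numeric",
    splitFractions = "numeric",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@beta < 0) msg <- c(msg, "alpha, beta must be >= 0")
  if (object@alpha == 0 && object@beta == 0)
    msg <- c(msg, "alpha and beta must not both be zero")
  if (abs(sum(object@splitFractions) - 1) > 1e-8)
    msg <- c(msg, "splitFractions must sum to 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@windowLen < 2L) msg <- c(msg, "windowLen must be >= 2")
  if (length(msg)) msg else TRUE
})
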