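# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG state. All user-facing stochastic operations route through this so
# seed determinism is bitwise.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Build a SummarySeries, filling optional slots with zero-extent defaults.
newSummarySeries <- function(values, featureNames, timeIndex = NULL,
                             anomalyLabels = NULL, covariates = NULL,
                             validMask = NULL) {
  d <- dim(values)
  if (is.null(timeIndex)) timeIndex <- seq_len(d[1L])
  if (is.null(anomalyLabels)) anomalyLabels <- matrix(integer(), 0L, 0L)
  if (is.null(validMask)) validMask <- matrix(logical(), 0L, 0L)
  if (is.null(covariates)) covariates <- array(numeric(), dim = c(d[1L], d[2L], 0L))
  new("SummarySeries", values = values, covariates = covariates,
      anomalyLabels = anomalyLabels, featureNames = featureNames,
      timeIndex = as.numeric(timeIndex), validMask = validMask)
}

# softplus with overflow guard; used by the Gaussian variance head.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

leakyRelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
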