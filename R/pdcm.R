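#' Mahalanobis divergence of an observation from a Gaussian forecast
#'
#' The quadratic form `(z - mu)' Sigma^-1 (z - mu)` for a diagonal
#' covariance, used as the per-cell anomaly divergence. Zero exactly when
#' the observation equals the predictive mean; distributed chi-square with
#' k degrees of freedom when the observation is drawn from the forecast
#' itself.
#'
#' @param z observed k-vector.
#' @param mu predictive mean k-vector.
#' @param variance positive predictive variance k-vector (diagonal).
#' @return nonnegative scalar divergence.
#' @export
mahalanobisDivergence <- function(z, mu, variance) {
  stopIfNot(all(is.finite(z)) && all(is.finite(mu)) && all(is.finite(variance)),
            "non-finite inputs to the divergence")
  stopIfNot(all(variance > 0), "variances must be positive")
  sum((z - mu)^2 / variance)
}

#' Symmetric-Gaussian KL divergence (alternative alarm metric)
#'
#' KL divergence from the predictive Gaussian to a unit-variance Gaussian
#' centred at the observation, exposed behind the metric flag of
#' [detectStream()] for ablation against the default Mahalanobis score.
#'
#' @inheritParams mahalanobisDivergence
#' @return nonnegative scalar.
#' @export
gaussianKlDivergence <- function(z, mu, variance) {
  sum(0.5 * (variance + (z - mu)^2 - 1 - log(variance)))
}

#' Create a latent calibration state
#'
#' Gate parameter defaults are derived from the chi-square null geometry of
#' the divergence: with `k` summary features the null divergence has mean
#' `k`, and the gate `xi = sigmoid(wDelta * delta + bDelta)` is set to cross
#' 1/2 at the 95th percentile of chi-square(k), with slope `8 / delta0`.
#' Divergences typical under the null thus leave the latent nearly
#' untouched (`xi` close to 1), while anomalous divergences blend the
#' latent towards its EMA baseline (`xi` towards 0), preventing the
#' forecaster from absorbing an anomaly into its state.
#'
#' @param m latent dimension.
#' @param k number of summary features (degrees of freedom of the null
#'   divergence).
#' @param rho EMA decay of the baseline in (0,1).
#' @return A [CalibrationState-class] with an uninitialized baseline.
#' @export
newCalibrationState <- function(m, k, rho = 0.9) {
  delta0 <- qchisq(0.95, df = k)
  gain <- 8 / delta0
  new("CalibrationState",
      baseline = rep(NA_real_, m), rho = rho,
      wDelta = rep(-gain, m), bDelta = rep(gain * delta0, m),
      history = numeric())
}

#' Feedback-driven latent calibration
#'
#' Blends the current latent with its historical EMA baseline through a
#' divergence-driven gate:
#' `xi = sigmoid(wDelta * delta + bDelta)`,
#' `hTilde = xi * h + (1 - xi) * hBar`, after which the baseline is
#' updated as `hBar <- rho * hBar + (1 - rho) * hTilde` and the divergence
#' appended to the history. On the first call the baseline initializes to
#' the incoming latent.
#'
#' @param h latent m-vector.
#' @param state a [CalibrationState-class].
#' @param delta nonnegative scalar divergence.
#' @return list with `latent` (calibrated m-vector, componentwise between
#'   `h` and the baseline) and the updated `state`.
#' @export
calibrateLatent <- function(h, state, delta) {
  stopIfNot(is.numeric(delta) && length(delta) == 1L && delta >= 0,
            "delta must be a nonnegative scalar")
  if (anyNA(state@baseline)) state@baseline <- h
  xi <- sigmoid(state@wDelta * delta + state@bDelta)
  htilde <- xi * h + (1 - xi) * state@baseline
  state@baseline <- state@rho * state@baseline + (1 - state@rho) * htilde
  state@history <- c(state@history, delta)
  list(latent = htilde, state = state)
}

#' Policy-conditioned forecast correction
#'
#' Computes an adaptive intervention correction
#' `etaPrime = MLP(I, delta)` (a tanh hidden layer over the policy vector
#' concatenated with the divergence) and applies the shared point head to
#' the shifted latent: `zPrime = Wout (hTilde + etaPrime) + bout`. The
#' correction network is zero-initialized, so an untrained model reduces
#' exactly to the base head.
#'
#' @param htilde calibrated latent m-vector.
#' @param policyVec observed/imputed policy r-vector.
#' @param delta scalar divergence.
#' @param model a [HetModel-class].
#' @return list with `pointForecast` (corrected k-vector), `etaPrime`, and
#'   `latentShifted` (`htilde + etaPrime`).
#' @export
conditionForecast <- function(htilde, policyVec, delta, model) {
  p <- model@params
  stopIfNot(length(policyVec) == model@config@policyDim,
            "policy vector dimension mismatch")
  stopIfNot(length(htilde) == model@config@latentDim,
            "latent dimension mismatch")
  x <- c(policyVec, delta)
  h1 <- tanh(drop(x %*% p$Wp1) + p$bp1)
  etaPrime <- drop(h1 %*% p$Wp2) + p$bp2
  hs <- htilde + etaPrime
  list(pointForecast = drop(hs %*% p$Wout) + p$bout,
       etaPrime = etaPrime, latentShifted = hs)
}

# distribution head applied to a single (possibly shifted) latent vector;
# shares the parameters of the model's Gaussian head.
distHead <- function(h, model) {
  p <- model@params
  mu <- drop(h %*% p$Wmu) + p$bmu
  va <- softplus(drop(h %*% p$Wsig) + p$bsig) + model@config@varianceFloor
  list(mean = mu, variance = va)
}

#' Monte-Carlo forecast refinement
#'
#' Draws `nSamples` vectors from the calibrated diagonal Gaussian and
#' returns the componentwise median, a robust aggregate that suppresses
#' outlier draws; the median converges to the mean at rate
#' `O(1/sqrt(nSamples))` for the symmetric Gaussian.
#'
#' @param mu calibrated predictive mean k-vector.
#' @param variance nonnegative predictive variance k-vector.
#' @param nSamples number of Monte-Carlo draws (>= 1).
#' @param seed integer seed.
#' @return refined forecast k-vector.
#' @export
stochasticRefine <- function(mu, variance, nSamples = 64L, seed = 1L) {
  stopIfNot(nSamples >= 1, "nSamples must be >= 1")
  stopIfNot(all(variance >= 0), "variances must be nonnegative")
  k <- length(mu)
  withSeed(seed, {
    draws <- matrix(rnorm(nSamples * k, mean = rep(mu, each = nSamples),
                          sd = rep(sqrt(variance), each = nSamples)),
                    nSamples, k)
    apply(draws, 2L, median)
  })
}

#' Create a dynamic threshold controller state
#'
#' @param targetFaRate target false-alarm rate in (0,1).
#' @param missPenalty miss-penalty weight (divergence units) subtracted in
#'   proportion to the rolling miss rate when labels are available.
#' @param window rolling window length.
#' @param tau initial threshold.
#' @return A [ThresholdState-class].
#' @export
newThresholdState <- function(targetFaRate = 0.05, missPenalty = 0,
                              window = 250L, tau = Inf) {
  new("ThresholdState", tau = if (is.finite(tau)) tau else .Machine$double.xmax,
      targetFaRate = targetFaRate, missPenalty = missPenalty,
      window = as.integer(window), faHistory = numeric(),
      missHistory = numeric())
}

#' Dynamic alarm threshold tuning
#'
#' The rolling-quantile controller: the threshold is set to the empirical
#' `1 - targetFaRate` quantile (type-7 convention of [stats::quantile()])
#' of the recent divergence window, shifted down by
#' `missPenalty * (rolling miss rate)` when recent anomaly labels are
#' available. The threshold is monotone nonincreasing in the target
#' false-alarm rate. The realized false-alarm and miss rates of the window
#' under the new threshold are appended to the state histories.
#'
#' @param state a [ThresholdState-class].
#' @param recentDelta nonempty numeric vector of recent divergences
#'   (time ordered; at most the last `window` entries are used).
#' @param recentLabels optional binary labels aligned with `recentDelta`.
#' @return the updated [ThresholdState-class] with the new `tau`.
#' @export
tuneThreshold <- function(state, recentDelta, recentLabels = NULL) {
  if (length(recentDelta) == 0L)
    stop("empty divergence window", call. = FALSE)
  n <- length(recentDelta)
  use <- max(1L, n - state@window + 1L):n
  win <- recentDelta[use]
  tau <- unname(quantile(win, probs = 1 - state@targetFaRate, type = 7))
  missRate <- 0
  if (!is.null(recentLabels) && any(recentLabels[use] == 1)) {
    missRate <- mean(win[recentLabels[use] == 1] <= tau)
    tau <- tau - state@missPenalty * missRate
  }
  faRate <- if (is.null(recentLabels)) mean(win > tau)
    else if (any(recentLabels[use] == 0)) mean(win[recentLabels[use] == 0] > tau)
    else 0
  state@tau <- tau
  state@faHistory <- c(state@faHistory, faRate)
  state@missHistory <- c(state@missHistory, missRate)
  state
}

#' Raise an alarm from a divergence and a threshold
#'
#' The alarm indicator is strict: an alarm fires only when the divergence
#' strictly exceeds the threshold, so `D == tau` never alarms.
#'
#' @param D scalar divergence.
#' @param tau scalar threshold.
#' @param time,region optional identifiers carried into the record.
#' @return one-row data.frame (an alarm record) with columns
#'   `time`, `region`, `score`, `threshold`, `alarm`.
#' @export
raiseAlarm <- function(D, tau, time = NA_integer_, region = NA_character_) {
  stopIfNot(is.finite(D) && is.finite(tau), "divergence and threshold must be finite")
  data.frame(time = time, region = region, score = D, threshold = tau,
             alarm = D > tau)
}
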