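#' Construct a training configuration
#'
#' Composite-loss weights, AdamW-style optimizer settings with linear
#' warm-up and decay, early stopping on validation AUC, and the window /
#' batch geometry of the gradient sampler.
#'
#' @param alpha weight of the squared-error forecast loss.
#' @param beta weight of the Gaussian negative log-likelihood.
#' @param learningRate peak Adam learning rate.
#' @param weightDecay decoupled weight decay applied to matrices.
#' @param warmupEpochs epochs of linear learning-rate warm-up.
#' @param maxEpochs epoch budget.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param batchSize training windows per gradient step.
#' @param windowLen training window length in steps.
#' @param stepsPerEpoch gradient steps per epoch.
#' @param aucTolerance model-selection tolerance on validation AUC: among
#'   epochs whose validation AUC is within this band of the best, the one
#'   with the lowest validation loss is restored (a one-standard-error
#'   style rule that avoids freezing an undertrained forecaster on AUC
#'   noise).
#' @param splitFractions train/validation/test fractions (sum to 1,
#'   time ordered).
#' @param seed training seed.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(alpha = 1, beta = 0.5, learningRate = 8e-3,
                        weightDecay = 0.01, warmupEpochs = 3L,
                        maxEpochs = 30L, patience = 8L, batchSize = 8L,
                        windowLen = 64L, stepsPerEpoch = 10L,
                        aucTolerance = 0.015,
                        splitFractions = c(0.8, 0.1, 0.1), seed = 1L) {
  cfg <- new("TrainConfig", alpha = alpha, beta = beta,
             learningRate = learningRate, weightDecay = weightDecay,
             warmupEpochs = as.integer(warmupEpochs),
             maxEpochs = as.integer(maxEpochs),
             patience = as.integer(patience),
             batchSize = as.integer(batchSize),
             windowLen = as.integer(windowLen),
             stepsPerEpoch = as.integer(stepsPerEpoch),
             aucTolerance = aucTolerance,
             splitFractions = splitFractions, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Time-ordered train/validation/test split indices
#'
#' @param T series length.
#' @param fractions length-3 nonnegative fractions summing to 1.
#' @return list of integer index vectors `train`, `val`, `test`
#'   (non-overlapping, in time order).
#' @export
timeSplit <- function(T, fractions = c(0.8, 0.1, 0.1)) {
  nTrain <- floor(T * fractions[1L])
  nVal <- floor(T * fractions[2L])
  list(train = seq_len(nTrain),
       val = if (nVal > 0) nTrain + seq_len(nVal) else integer(),
       test = if (nTrain + nVal < T) (nTrain + nVal + 1L):T else integer())
}

#' Composite training loss
#'
#' `alpha * MSE + beta * GaussianNLL`, averaged over region-time cells.
#' The squared error is averaged over features within a cell; the negative
#' log-likelihood of the diagonal Gaussian is summed over features (so for
#' `k = 1`, `mu = z`, `variance = 1` the per-cell NLL is `log(2*pi)/2`).
#'
#' @param pointForecast array/matrix of point forecasts.
#' @param mu,variance Gaussian head outputs, same shape.
#' @param observed observed values, same shape.
#' @param alpha,beta nonnegative loss weights, not both zero.
#' @return scalar loss.
#' @export
compositeLoss <- function(pointForecast, mu, variance, observed,
                          alpha = 1, beta = 0.5) {
  stopIfNot(alpha >= 0 && beta >= 0 && (alpha + beta) > 0,
            "alpha and beta must be nonnegative and not both zero")
  stopIfNot(all(variance > 0), "variances must be positive")
  toMat <- function(x) {
    d <- dim(x)
    if (is.null(d)) matrix(x, ncol = 1L)
    else if (length(d) == 3L) matrix(x, d[1L] * d[2L], d[3L])
    else x
  }
  P <- toMat(pointForecast); Mu <- toMat(mu); V <- toMat(variance)
  Z <- toMat(observed)
  mse <- mean(rowMeans((P - Z)^2))
  nll <- mean(rowSums(0.5 * (log(2 * pi * V) + (Z - Mu)^2 / V)))
  alpha * mse + beta * nll
}

# slice helpers ---------------------------------------------------------

sliceSeries <- function(series, idx) {
  newSummarySeries(seriesValues(series)[idx, , , drop = FALSE],
                   featureNames = featureNames(series),
                   timeIndex = timeIndex(series)[idx],
                   anomalyLabels = if (nrow(anomalyLabels(series)))
                     anomalyLabels(series)[idx, , drop = FALSE] else NULL)
}

slicePolicy <- function(policy, idx) {
  new("PolicySeries", values = seriesValues(policy)[idx, , , drop = FALSE],
      missingMask = missingMask(policy)[idx, , drop = FALSE],
      scheme = policyScheme(policy))
}

# midrank AUC of scores against binary labels (ties handled by midranks)
aucMidrank <- function(scores, labels) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined for single-class labels")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mahalanobis scores of a stream against plain model forecasts; row t of
# the score matrix compares z_t with the forecast made at t-1 (NA at t=1).
plainDivergences <- function(model, series, policy, graph, blockLen = 64L) {
  fc <- hetForecast(model, series, policy, graph, blockLen = blockLen)
  Z <- seriesValues(series)
  d <- dim(Z)
  mu <- forecastMean(fc$dist); va <- forecastVariance(fc$dist)
  sc <- matrix(NA_real_, d[1L], d[2L])
  for (t in 2:d[1L]) for (j in seq_len(d[2L]))
    sc[t, j] <- sum((Z[t, j, ] - mu[t - 1L, j, ])^2 / va[t - 1L, j, ])
  list(scores = sc, forecast = fc)
}

#' Fit the forecaster by gradient training
#'
#' Minimizes the composite loss with Adam (decoupled weight decay on the
#' projection matrices), a linear learning-rate warm-up over the first
#' epochs followed by linear decay, sampling fixed-length causal training
#' windows uniformly from the training span. After each epoch the
#' validation span is scored (Mahalanobis divergence of the plain forecast
#' against the validation anomaly labels) and training stops early when
#' the validation AUC has not improved for `patience` epochs. The restored
#' checkpoint is chosen among the epochs whose validation AUC lies within
#' `aucTolerance` of the best as the one with the lowest validation loss
#' (validation AUC saturates quickly and then fluctuates within its
#' sampling noise, while the forecast keeps improving; the tolerance rule
#' picks the best forecaster among operationally equivalent detectors).
#' When the validation span carries no two-class labels, the negative
#' validation loss replaces AUC as the early-stopping criterion.
#'
#' @param series a [SummarySeries-class] covering the full stream
#'   (anomaly labels, when present, drive early stopping).
#' @param policy an imputed [PolicySeries-class] aligned with `series`.
#' @param graph a [RegionGraph-class].
#' @param config a [HetConfig-class].
#' @param train a [TrainConfig-class].
#' @return list with `model` (fitted [HetModel-class]), `log` (per-epoch
#'   data.frame: trainLoss, valLoss, valAuc, lr) and `split` (the index
#'   split used).
#' @export
fitModel <- function(series, policy, graph, config, train = trainConfig()) {
  Z <- seriesValues(series)
  T <- dim(Z)[1L]
  split <- timeSplit(T, train@splitFractions)
  stopIfNot(length(split$val) > 0L, "validation split is empty")
  stopIfNot(length(split$train) > train@windowLen,
            "training split shorter than one window")
  Ipol <- seriesValues(policy)
  if (any(missingMask(policy)))
    stop("policy series contains masked cells; impute before fitting",
         call. = FALSE)
  adj <- adjacencyWithSelf(graph)
  logPrior <- if (config@useKernelPrior)
    log(kernelInfluenceMatrix(graph)) else NULL
  model <- initHetModel(config)
  params <- model@params
  flat <- flattenParams(params)
  mAd <- numeric(length(flat))
  vAd <- numeric(length(flat))
  decayMask <- unlist(rapply(params, function(x)
    if (is.matrix(x)) rep(1, length(x)) else rep(0, length(x)),
    how = "unlist"), use.names = FALSE)
  beta1 <- 0.9; beta2 <- 0.999; epsAd <- 1e-8
  nTrainStart <- length(split$train) - train@windowLen + 1L
  valSeries <- sliceSeries(series, split$val)
  valPolicy <- slicePolicy(policy, split$val)
  valLabels <- if (nrow(anomalyLabels(series)))
    anomalyLabels(series)[split$val, , drop = FALSE] else NULL
  hasTwoClassVal <- !is.null(valLabels) &&
    length(unique(as.vector(valLabels))) == 2L
  bestCrit <- -Inf; bestEpoch <- 0L
  epochFlats <- list()
  logRows <- list()
  stepCount <- 0L
  totalSteps <- train@maxEpochs * train@stepsPerEpoch
  warmSteps <- train@warmupEpochs * train@stepsPerEpoch

  withSeed(train@seed, {
    for (epoch in seq_len(train@maxEpochs)) {
      epochLoss <- 0; lrLast <- NA_real_
      for (s in seq_len(train@stepsPerEpoch)) {
        stepCount <- stepCount + 1L
        lr <- if (stepCount <= warmSteps && warmSteps > 0)
          train@learningRate * stepCount / warmSteps
        else train@learningRate *
          max(0.1, 1 - (stepCount - warmSteps) / max(1, totalSteps - warmSteps))
        lrLast <- lr
        starts <- sample.int(nTrainStart, train@batchSize, replace = TRUE)
        gAcc <- NULL; lossAcc <- 0
        for (b in starts) {
          span <- b:(b + train@windowLen - 1L)
          out <- hetLossGrad(params, config,
                             Z[span, , , drop = FALSE],
                             Ipol[span, , , drop = FALSE],
                             adj, logPrior, train@alpha, train@beta,
                             training = TRUE)
          lossAcc <- lossAcc + out$loss
          gFlat <- flattenParams(out$grads)
          gAcc <- if (is.null(gAcc)) gFlat else gAcc + gFlat
        }
        gAcc <- gAcc / train@batchSize
        epochLoss <- epochLoss + lossAcc / train@batchSize
        mAd <- beta1 * mAd + (1 - beta1) * gAcc
        vAd <- beta2 * vAd + (1 - beta2) * gAcc^2
        mHat <- mAd / (1 - beta1^stepCount)
        vHat <- vAd / (1 - beta2^stepCount)
        flat <- flat - lr * (mHat / (sqrt(vHat) + epsAd) +
                               train@weightDecay * decayMask * flat)
        params <- relistParams(flat, params)
      }
      model@params <- params
      pv <- plainDivergences(model, valSeries, valPolicy, graph,
                             blockLen = train@windowLen)
      vz <- seriesValues(valSeries)
      nv <- dim(vz)[1L]
      valLoss <- compositeLoss(
        fcAligned(pv$forecast$pointForecast, nv),
        fcAligned(forecastMean(pv$forecast$dist), nv),
        fcAligned(forecastVariance(pv$forecast$dist), nv),
        vz[2:nv, , , drop = FALSE],
        train@alpha, train@beta)
      valAuc <- if (hasTwoClassVal)
        aucMidrank(as.vector(pv$scores), as.vector(valLabels)) else NA_real_
      crit <- if (hasTwoClassVal) valAuc else -valLoss
      logRows[[epoch]] <- data.frame(
        epoch = epoch, trainLoss = epochLoss / train@stepsPerEpoch,
        valLoss = valLoss, valAuc = valAuc, lr = lrLast)
      epochFlats[[epoch]] <- flat
      if (is.finite(crit) && crit > bestCrit + 1e-12) {
        bestCrit <- crit; bestEpoch <- epoch
      } else if (epoch - bestEpoch >= train@patience) {
        break
      }
    }
  })
  log <- do.call(rbind, logRows)
  crits <- if (hasTwoClassVal) log$valAuc else -log$valLoss
  tol <- if (hasTwoClassVal) train@aucTolerance else 0
  cand <- which(is.finite(crits) & crits >= max(crits, na.rm = TRUE) - tol)
  restore <- cand[which.min(log$valLoss[cand])]
  model@params <- relistParams(epochFlats[[restore]], params)
  model@fitted <- TRUE
  log$restored <- seq_len(nrow(log)) == restore
  list(model = model, log = log, split = split)
}

# forecasts at rows 1..(T-1) predict rows 2..T
fcAligned <- function(a, T) a[seq_len(T - 1L), , , drop = FALSE]

#' Persistence-baseline divergence scores and forecasts
#'
#' The minimal-skill reference: the forecast for `z[t]` is `z[t-1]`, with a
#' diagonal covariance estimated as the per-feature variance of the
#' one-step differences over a training span. Scores are Mahalanobis
#' divergences against that forecast.
#'
#' @param series a [SummarySeries-class].
#' @param trainIdx time indices used to estimate the difference variances
#'   (defaults to the whole series).
#' @return list with `scores` (T x M matrix, NA at t = 1), `pointForecast`
#'   (T x M x k array; row t predicts t + 1) and `diffVariance`.
#' @export
persistenceBaseline <- function(series, trainIdx = NULL) {
  Z <- seriesValues(series)
  d <- dim(Z)
  if (is.null(trainIdx)) trainIdx <- seq_len(d[1L])
  dv <- vapply(seq_len(d[3L]), function(f) {
    dd <- apply(Z[trainIdx, , f, drop = FALSE], 2L, diff)
    var(as.vector(dd))
  }, numeric(1L))
  dv[dv <= 0] <- 1e-8
  sc <- matrix(NA_real_, d[1L], d[2L])
  for (t in 2:d[1L]) for (j in seq_len(d[2L]))
    sc[t, j] <- sum((Z[t, j, ] - Z[t - 1L, j, ])^2 / dv)
  list(scores = sc, pointForecast = Z, diffVariance = dv)
}

#' Run the calibrated detection pass over a stream
#'
#' One strictly causal pass per time step and region: the previous step's
#' forecast is compared with the incoming observation (Mahalanobis
#' divergence by default), the divergence drives the latent calibration
#' gate, the calibrated latent is shifted by the policy-conditioned
#' correction, the shared Gaussian head produces the next forecast, the
#' Monte-Carlo median refines the point forecast, and the rolling-quantile
#' controller updates the alarm threshold (always from divergences strictly
#' before the current step). With `pdcm = FALSE` the pass scores the plain
#' forecaster without calibration, conditioning or refinement.
#'
#' @param model a fitted [HetModel-class].
#' @param series a [SummarySeries-class].
#' @param policy an imputed [PolicySeries-class].
#' @param graph a [RegionGraph-class].
#' @param pdcm logical; apply the calibration mechanism.
#' @param metric divergence metric for scoring, `mahalanobis` (default) or
#'   `gaussian_kl`.
#' @param threshold a [ThresholdState-class]; thresholds pool divergences
#'   across regions (`poolRegions = FALSE` keeps per-region controllers).
#' @param calibration optional list of per-region
#'   [CalibrationState-class]s; created from the model dimensions when
#'   `NULL`.
#' @param refineSamples Monte-Carlo draws for forecast refinement.
#' @param poolRegions pool divergences across regions for thresholding.
#' @param warmupSteps steps before the first threshold is available (no
#'   alarms are raised during warm-up).
#' @param blockLen causal processing block length.
#' @param seed seed for the Monte-Carlo refinement draws.
#' @return list with `alarms` (data.frame: time, region, score, threshold,
#'   alarm), `scores` (T x M, NA at t = 1), `pointForecast`
#'   (T x M x k; row t predicts t + 1; refined when `pdcm`), `calibration`
#'   and `threshold` final states.
#' @export
detectStream <- function(model, series, policy, graph, pdcm = TRUE,
                         metric = c("mahalanobis", "gaussian_kl"),
                         threshold = newThresholdState(),
                         calibration = NULL, refineSamples = 64L,
                         poolRegions = TRUE, warmupSteps = 50L,
                         blockLen = 64L, seed = 1L) {
  metric <- match.arg(metric)
  divFun <- if (metric == "mahalanobis") mahalanobisDivergence
    else gaussianKlDivergence
  Z <- seriesValues(series)
  d <- dim(Z)
  T <- d[1L]; M <- d[2L]; k <- d[3L]
  Ipol <- seriesValues(policy)
  stopIfNot(dim(Ipol)[1L] == T && dim(Ipol)[2L] == M,
            "series and policy lengths are misaligned")
  fc <- hetForecast(model, series, policy, graph, blockLen = blockLen)
  mu0 <- forecastMean(fc$dist); va0 <- forecastVariance(fc$dist)
  m <- model@config@latentDim
  if (pdcm && is.null(calibration))
    calibration <- replicate(M, newCalibrationState(m, k), simplify = FALSE)
  perRegionThr <- if (poolRegions) NULL else
    replicate(M, threshold, simplify = FALSE)
  scores <- matrix(NA_real_, T, M)
  pf <- fc$pointForecast
  muP <- mu0; vaP <- va0
  alarms <- vector("list", T)
  pooled <- numeric(0)
  tauCur <- .Machine$double.xmax
  withSeed(seed, {
    for (t in seq_len(T)) {
      recs <- vector("list", M)
      for (j in seq_len(M)) {
        if (t >= 2L) {
          delta <- divFun(Z[t, j, ], muP[t - 1L, j, ], vaP[t - 1L, j, ])
          scores[t, j] <- delta
        } else delta <- 0
        if (pdcm) {
          cal <- calibrateLatent(fc$latent[t, j, ], calibration[[j]], delta)
          calibration[[j]] <- cal$state
          cond <- conditionForecast(cal$latent, Ipol[t, j, ], delta, model)
          dh <- distHead(cond$latentShifted, model)
          muP[t, j, ] <- dh$mean
          vaP[t, j, ] <- dh$variance
          if (refineSamples > 0L) {
            draws <- matrix(rnorm(refineSamples * k), refineSamples, k)
            pf[t, j, ] <- apply(
              draws * matrix(sqrt(dh$variance), refineSamples, k, byrow = TRUE) +
                matrix(dh$mean, refineSamples, k, byrow = TRUE),
              2L, median)
          } else pf[t, j, ] <- cond$pointForecast
        }
        if (t >= 2L) {
          tauUse <- if (poolRegions) tauCur else perRegionThr[[j]]@tau
          haveThr <- t > warmupSteps
          recs[[j]] <- raiseAlarm(
            scores[t, j],
            if (haveThr) tauUse else .Machine$double.xmax,
            time = t, region = regionIds(graph)[j])
        }
      }
      # threshold update uses divergences up to and including t, applied
      # from t+1 on (strictly causal alarms)
      if (t >= 2L) {
        if (poolRegions) {
          pooled <- c(pooled, scores[t, ])
          if (length(pooled) > 4L * threshold@window)
            pooled <- pooled[(length(pooled) - 2L * threshold@window + 1L):
                               length(pooled)]
          threshold <- tuneThreshold(threshold, pooled)
          tauCur <- threshold@tau
        } else {
          for (j in seq_len(M)) {
            hist <- scores[2:t, j]
            perRegionThr[[j]] <- tuneThreshold(perRegionThr[[j]], hist)
          }
        }
      }
      alarms[[t]] <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
    }
  })
  list(alarms = do.call(rbind, alarms[!vapply(alarms, is.null, TRUE)]),
       scores = scores, pointForecast = pf,
       calibration = calibration,
       threshold = if (poolRegions) threshold else perRegionThr)
}

#' Classification and forecast metrics
#'
#' AUC is computed from midranks (tie-safe); recall, precision and F1 are
#' taken at the supplied operating threshold (the dynamically tuned alarm
#' threshold in the detection pipeline, not the F1-maximizing one); MSE
#' compares aligned forecasts with observations when both are supplied.
#' Single-class labels make AUC undefined: it is reported as `NA` with a
#' warning.
#'
#' @param scores numeric anomaly scores (vector or matrix; NA entries are
#'   dropped pairwise with labels).
#' @param labels binary labels aligned with `scores`.
#' @param alarms optional logical alarm flags aligned with `scores` (used
#'   for recall/F1); when absent and `threshold` is given, flags are
#'   `scores > threshold`.
#' @param threshold optional scalar operating threshold.
#' @param forecasts,observed optional aligned arrays for MSE.
#' @return list with `auc`, `recall`, `precision`, `f1`, `mse` and the
#'   confusion counts.
#' @export
evaluateMetrics <- function(scores, labels, alarms = NULL, threshold = NULL,
                            forecasts = NULL, observed = NULL) {
  s <- as.vector(scores); y <- as.vector(labels)
  keep <- is.finite(s) & !is.na(y)
  auc <- aucMidrank(s, y)
  out <- list(auc = auc, recall = NA_real_, precision = NA_real_,
              f1 = NA_real_, mse = NA_real_,
              counts = c(tp = NA, fp = NA, fn = NA, tn = NA))
  flags <- if (!is.null(alarms)) as.vector(alarms)
    else if (!is.null(threshold)) s > threshold else NULL
  if (!is.null(flags)) {
    f <- flags[keep]; yy <- y[keep]
    tp <- sum(f & yy == 1); fp <- sum(f & yy == 0)
    fn <- sum(!f & yy == 1); tn <- sum(!f & yy == 0)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
      2 * precision * recall / (precision + recall) else 0
    out$recall <- recall; out$precision <- precision; out$f1 <- f1
    out$counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  if (!is.null(forecasts) && !is.null(observed))
    out$mse <- mean((as.vector(forecasts) - as.vector(observed))^2)
  out
}

#' Subgroup fairness: bias gap and bias reduction
#'
#' The bias gap is the maximum absolute deviation of the per-group F1
#' scores from their pooled mean (`method = "max_dev_mean"`, the default);
#' `method = "max_minus_min"` is provided as the alternative range-based
#' reading. The bias reduction against a reference gap is
#' `(gapRef - gap) / gapRef * 100`, rounded to one decimal.
#'
#' @param groupF1 named numeric vector of per-group F1 scores.
#' @param referenceGap optional positive reference bias gap.
#' @param method bias-gap definition.
#' @return list with `gap`, per-group deviations, and `reduction`
#'   (percent, when a reference gap is supplied).
#' @export
fairnessReport <- function(groupF1, referenceGap = NULL,
                           method = c("max_dev_mean", "max_minus_min")) {
  method <- match.arg(method)
  stopIfNot(length(groupF1) >= 1L, "need at least one group")
  gap <- if (method == "max_dev_mean")
    max(abs(groupF1 - mean(groupF1)))
  else diff(range(groupF1))
  out <- list(gap = gap, deviations = groupF1 - mean(groupF1),
              method = method)
  if (!is.null(referenceGap))
    out$reduction <- biasReduction(referenceGap, gap)
  out
}

#' @rdname fairnessReport
#' @param gapRef reference bias gap (> 0).
#' @param gap achieved bias gap.
#' @export
biasReduction <- function(gapRef, gap) {
  stopIfNot(is.numeric(gapRef) && gapRef > 0,
            "reference gap must be positive")
  round((gapRef - gap) / gapRef * 100, 1)
}

#' Gaussian residual diagnostics
#'
#' Summarizes the agreement of forecast residuals with the normal
#' assumption: histogram bin counts of the standardized residuals, Q-Q
#' points of the raw residual quantiles against the standard normal
#' quantile function, the least-squares slope/intercept of the Q-Q line
#' (estimating the residual sd and mean; slope near 1 for standard-normal
#' residuals), and the Kolmogorov-Smirnov statistic of the standardized
#' residuals. Constant residuals are flagged degenerate and nothing is
#' fitted.
#'
#' @param mu forecast means (vector or array).
#' @param observed observations aligned with `mu`.
#' @param bins approximate number of histogram bins.
#' @return list with `residuals`, `standardized`, `histogram`
#'   (mids/counts), `qq` (theoretical/sample), `slope`, `intercept`,
#'   `ksStatistic`, `degenerate`.
#' @export
residualDiagnostics <- function(mu, observed, bins = 30L) {
  res <- as.vector(observed) - as.vector(mu)
  res <- res[is.finite(res)]
  stopIfNot(length(res) >= 30L, "need at least 30 residuals")
  s <- sd(res)
  if (s == 0)
    return(list(residuals = res, degenerate = TRUE))
  std <- (res - mean(res)) / s
  h <- hist(std, breaks = bins, plot = FALSE)
  theo <- qnorm(ppoints(length(res)))
  samp <- sort(res)
  fit <- lm.fit(cbind(1, theo), samp)
  ks <- suppressWarnings(ks.test(std, "pnorm"))
  list(residuals = res, standardized = std,
       histogram = list(mids = h$mids, counts = h$counts),
       qq = list(theoretical = theo, sample = samp),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       ksStatistic = unname(ks$statistic),
       degenerate = FALSE)
}
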