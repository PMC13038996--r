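test_that("composite loss matches a hand-summed oracle", {
  # beta = 0 with a perfect point forecast is exactly zero
  z <- array(rnorm(12), c(2, 3, 2))
  expect_equal(compositeLoss(z, z, z * 0 + 1, z, alpha = 1, beta = 0), 0)

  # alpha = 0, k = 1, mu = z, unit variance: log(2*pi)/2 per cell
  z1 <- matrix(rnorm(5), 5, 1)
  expect_equal(compositeLoss(z1, z1, z1 * 0 + 1, z1, alpha = 0, beta = 1),
               log(2 * pi) / 2)

  # random batch against an independent elementwise sum
  set.seed(3)
  P <- matrix(rnorm(12), 4, 3); Mu <- matrix(rnorm(12), 4, 3)
  V <- matrix(runif(12, 0.2, 2), 4, 3); Z <- matrix(rnorm(12), 4, 3)
  manual <- 0
  for (i in 1:4) {
    mse <- mean((P[i, ] - Z[i, ])^2)
    nll <- sum(0.5 * (log(2 * pi * V[i, ]) + (Z[i, ] - Mu[i, ])^2 / V[i, ]))
    manual <- manual + (2 * mse + 0.7 * nll) / 4
  }
  expect_equal(compositeLoss(P, Mu, V, Z, alpha = 2, beta = 0.7), manual)

  expect_error(compositeLoss(P, Mu, V, Z, alpha = 0, beta = 0), "both zero")
})

test_that("time splits are ordered and exhaustive", {
  sp <- timeSplit(100, c(0.8, 0.1, 0.1))
  expect_equal(sp$train, 1:80)
  expect_equal(sp$val, 81:90)
  expect_equal(sp$test, 91:100)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
})

smokeFit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- tinyGraph(3, seed = 41)
      pol <- simulatePolicySeries(g, 220, seed = 42)
      sim <- simulateSurveillance(g, pol, 220, seed = 43)
      ser <- injectAnomalies(sim$series, ratio = 0.12, seed = 46)
      cfg <- tinyConfig(k = 3, depth = 1, dModel = 8, nHeads = 2,
                        dropout = 0.1, seed = 45)
      tc <- trainConfig(maxEpochs = 6L, stepsPerEpoch = 4L, batchSize = 3L,
                        windowLen = 32L, patience = 6L, warmupEpochs = 1L,
                        learningRate = 5e-3, seed = 46)
      cache <<- list(g = g, pol = pol, ser = ser, cfg = cfg, tc = tc,
                     fit = fitModel(ser, pol, g, cfg, tc))
    }
    cache
  }
})

test_that("gradient training reduces the loss and is reproducible", {
  sf <- smokeFit()
  log <- sf$fit$log
  expect_lt(log$trainLoss[5], log$trainLoss[1])
  expect_true(sf$fit$model@fitted)

  fit2 <- fitModel(sf$ser, sf$pol, sf$g, sf$cfg, sf$tc)
  expect_identical(sf$fit$log, fit2$log)
  expect_identical(sf$fit$model@params, fit2$model@params)

  # early stopping halts within `patience` epochs of the best epoch
  tcStop <- sf$tc; tcStop@patience <- 2L; tcStop@maxEpochs <- 8L
  fit3 <- fitModel(sf$ser, sf$pol, sf$g, sf$cfg, tcStop)
  crit <- if (all(is.na(fit3$log$valAuc))) -fit3$log$valLoss
    else fit3$log$valAuc
  expect_lte(nrow(fit3$log), which.max(crit) + 2L)

  tcBad <- sf$tc
  tcBad@splitFractions <- c(1, 0, 0)
  expect_error(fitModel(sf$ser, sf$pol, sf$g, sf$cfg, tcBad),
               "validation split")
})

test_that("the detection pass is causal, calibrated and thresholded", {
  sf <- smokeFit()
  det <- detectStream(sf$fit$model, sf$ser, sf$pol, sf$g, pdcm = TRUE,
                      seed = 9)
  T <- 220L; M <- 3L
  expect_true(all(is.na(det$scores[1, ])))
  expect_true(all(is.finite(det$scores[-1, ])))
  expect_equal(nrow(det$alarms), (T - 1L) * M)
  # the recorded flag always equals the strict comparison
  expect_identical(det$alarms$alarm,
                   det$alarms$score > det$alarms$threshold)

  # warm-up beyond the horizon: thresholds never available, zero alarms
  det0 <- detectStream(sf$fit$model, sf$ser, sf$pol, sf$g,
                       warmupSteps = 10 * T, seed = 9)
  expect_equal(sum(det0$alarms$alarm), 0L)

  short <- sentinet:::slicePolicy(sf$pol, 1:100)
  expect_error(detectStream(sf$fit$model, sf$ser, short, sf$g),
               "misaligned")
})

test_that("self-generated observations score at the chi-square mean", {
  cfg <- tinyConfig(k = 2, depth = 1, dModel = 8, nHeads = 2, seed = 12)
  mod <- initHetModel(cfg)
  g <- tinyGraph(2, seed = 13)
  polAll <- tinyPolicy(T = 300, M = 2)
  B <- 20L
  Tn <- 300L
  Z <- array(0, c(Tn, 2, 2))
  set.seed(14)
  Z[1, , ] <- rnorm(4)
  # generate z[t+1] from the model's own forecast at t, block-aligned so
  # that the subsequent detection pass sees exactly these forecasts
  for (t in 1:(Tn - 1L)) {
    s <- ((t - 1L) %/% B) * B + 1L
    ser <- sentinet:::newSummarySeries(Z[s:t, , , drop = FALSE],
                                       featureNames = c("f1", "f2"))
    pol <- sentinet:::slicePolicy(polAll, s:t)
    h <- spatialPolicyFuse(temporalEncode(embedSequence(ser, mod), mod),
                           g, pol, mod)
    hd <- predictHeads(h, mod)
    n <- t - s + 1L
    mu <- forecastMean(hd$dist)[n, , ]
    va <- forecastVariance(hd$dist)[n, , ]
    Z[t + 1L, , ] <- rnorm(4, mean = mu, sd = sqrt(va))
  }
  serAll <- sentinet:::newSummarySeries(Z, featureNames = c("f1", "f2"))
  det <- detectStream(mod, serAll, polAll, g, pdcm = FALSE, blockLen = B)
  sc <- det$scores[-1, ]
  expect_lt(abs(mean(sc) - 2) / 2, 0.15)   # chi-square_2 mean oracle

  # one large injected shift dominates the stream's scores
  Zs <- Z
  Zs[150, 1, ] <- Zs[150, 1, ] + 10 * sd(Z[, 1, 1])
  serS <- sentinet:::newSummarySeries(Zs, featureNames = c("f1", "f2"))
  detS <- detectStream(mod, serS, polAll, g, pdcm = FALSE, blockLen = B)
  expect_equal(which.max(apply(detS$scores, 1, max)), 150L)
})

test_that("metrics match rank and confusion-matrix oracles", {
  # perfect separation
  s <- c(rep(1, 5), rep(0, 5)); y <- c(rep(1, 5), rep(0, 5))
  r <- evaluateMetrics(s, y, threshold = 0.5)
  expect_equal(r$auc, 1); expect_equal(r$f1, 1); expect_equal(r$recall, 1)

  # worked confusion example: TP=8 FP=2 FN=2 TN=88
  sc <- c(rep(1, 8), rep(1, 2), rep(0, 2), rep(0, 88))
  yy <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 88))
  r2 <- evaluateMetrics(sc, yy, alarms = sc > 0.5)
  expect_equal(r2$recall, 0.8)
  expect_equal(r2$f1, 0.8)

  # independent scores: null AUC concentrates at 1/2
  set.seed(10)
  sN <- rnorm(10000); yN <- rbinom(10000, 1, 0.3)
  rN <- evaluateMetrics(sN, yN)
  expect_gte(rN$auc, 0.48); expect_lte(rN$auc, 0.52)

  expect_warning(evaluateMetrics(sN, rep(1, 10000)), "single-class")

  # AUC equals the Wilcoxon rank-sum statistic
  set.seed(11)
  sW <- c(rnorm(300), rnorm(200, 1)); yW <- rep(c(0, 1), c(300, 200))
  w <- wilcox.test(sW[yW == 1], sW[yW == 0], exact = FALSE)
  expect_equal(evaluateMetrics(sW, yW)$auc,
               unname(w$statistic) / (300 * 200))
  # and the independent pROC implementation
  expect_equal(evaluateMetrics(sW, yW)$auc,
               as.numeric(pROC::auc(pROC::roc(yW, sW, quiet = TRUE))))

  # MSE on aligned forecasts
  f <- c(1, 2, 3); o <- c(1, 2.5, 2)
  expect_equal(evaluateMetrics(c(1, 1, 1), c(0, 1, 0), forecasts = f,
                               observed = o)$mse, mean((f - o)^2))
})

test_that("bias gap and reduction arithmetic follow the definitions", {
  f1 <- c(a = 0.8, b = 0.8, c = 0.8)
  expect_equal(fairnessReport(f1)$gap, 0)

  f2 <- c(g1 = 0.90, g2 = 0.80, g3 = 0.70)
  expect_equal(fairnessReport(f2)$gap, 0.10)
  expect_equal(fairnessReport(f2, method = "max_minus_min")$gap, 0.20)

  rep1 <- fairnessReport(f2, referenceGap = 0.25)
  expect_equal(rep1$reduction, round((0.25 - 0.1) / 0.25 * 100, 1))
  expect_error(biasReduction(0, 0.1), "positive")
})

test_that("residual diagnostics recover the normal reference line", {
  set.seed(20)
  res <- rnorm(10000)
  d <- residualDiagnostics(rep(0, 10000), res)
  expect_gte(d$slope, 0.97); expect_lte(d$slope, 1.03)
  expect_lt(abs(d$intercept), 0.05)
  expect_false(d$degenerate)
  expect_equal(sum(d$histogram$counts), 10000)

  dc <- residualDiagnostics(rep(0, 50), rep(2, 50))
  expect_true(dc$degenerate)

  # residuals that are exactly normal quantiles sit on the identity line
  q <- qnorm(ppoints(200))
  dq <- residualDiagnostics(rep(0, 200), q)
  expect_equal(dq$qq$sample, dq$qq$theoretical)
  expect_equal(dq$slope, 1)
  expect_error(residualDiagnostics(0, rnorm(10)), "at least 30")
})

test_that("the trained forecaster beats the persistence baseline", {
  st <- studyResults()
  expect_lt(mean(st$detection$mseModel), mean(st$detection$msePersistence))
})
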