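test_that("config validity constraints hold", {
  # widths are coerced to a multiple of the head count
  cfg <- hetConfig(3, dModel = 30, nHeads = 8)
  expect_equal(cfg@dModel %% cfg@nHeads, 0L)
  expect_error(hetConfig(3, dropout = 1), "dropout")
  sc <- hetConfig(3, scale = 0.125)
  expect_equal(sc@dModel, 32L)
})

test_that("positional encoding matches the sinusoidal closed form", {
  pe <- positionalEncoding(5, 8)
  # position 0: even (sin) components 0, odd (cos) components 1
  expect_equal(pe[1, c(1, 3, 5, 7)], rep(0, 4))
  expect_equal(pe[1, c(2, 4, 6, 8)], rep(1, 4))
  # closed form at pos = 3, zero-based dim index 2 (a sin component)
  expect_equal(pe[4, 3], sin(3 / 10000^(2 / 8)))
  expect_equal(pe[4, 4], cos(3 / 10000^(2 / 8)))
})

test_that("embedding is additive in the positional term", {
  cfg <- tinyConfig()
  mod <- initHetModel(cfg)
  ser <- tinyStream(T = 6, M = 2)
  e <- embedSequence(ser, mod)
  expect_equal(dim(e), c(6L, 2L, 8L))
  expect_true(all(is.finite(e)))

  # zero input with a zero projection leaves exactly the positional code
  mod0 <- mod
  mod0@params$Wz[] <- 0
  zser <- sentinet:::newSummarySeries(array(0, c(6, 2, 2)),
                                      featureNames = c("f1", "f2"))
  e0 <- embedSequence(zser, mod0)
  pe <- positionalEncoding(6, 8)
  for (j in 1:2) expect_equal(e0[, j, ], pe)

  badser <- tinyStream(T = 4, M = 2, k = 3)
  expect_error(embedSequence(badser, mod), "feature count")
})

test_that("temporal encoder is causal, normalized and depth-0 transparent", {
  cfg <- tinyConfig(depth = 2)
  mod <- initHetModel(cfg)
  ser <- tinyStream(T = 10, M = 2)
  e0 <- embedSequence(ser, mod)

  cfg0 <- tinyConfig(depth = 0)
  mod0 <- initHetModel(cfg0)
  expect_identical(temporalEncode(e0, mod0), e0)

  out <- temporalEncode(e0, mod, returnAttention = TRUE)
  for (l in seq_along(out$attention)) for (j in 1:2)
    for (A in out$attention[[l]][[j]]) {
      expect_equal(unname(rowSums(A)), rep(1, 10))
      expect_true(all(A[upper.tri(A)] == 0))  # causal mask
    }

  # a single-step sequence puts all attention on itself
  e1 <- embedSequence(tinyStream(T = 1, M = 2), mod)
  o1 <- temporalEncode(e1, mod, returnAttention = TRUE)
  expect_equal(o1$attention[[1]][[1]][[1]], matrix(1, 1, 1))

  # causality: perturbing the future never changes past encodings
  ser2 <- ser
  v <- seriesValues(ser)
  v[8:10, , ] <- v[8:10, , ] + 5
  ser2 <- sentinet:::newSummarySeries(v, featureNames = featureNames(ser))
  eA <- temporalEncode(embedSequence(ser, mod), mod)
  eB <- temporalEncode(embedSequence(ser2, mod), mod)
  expect_equal(eA[1:7, , ], eB[1:7, , ])
  expect_error(temporalEncode(e0 * NA, mod), "non-finite")
})

test_that("single-head attention reproduces softmax(QK'/sqrt(dk))V by hand", {
  lay <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2), Wo = diag(2),
              W1 = matrix(0, 2, 2), b1 = numeric(2),
              W2 = matrix(0, 2, 2), b2 = numeric(2))
  E <- rbind(c(1, 0.5), c(-0.3, 2))
  got <- sentinet:::mhsaForward(E, lay, nHeads = 1L)$out
  # hand computation with the causal mask
  s21 <- sum(E[2, ] * E[1, ]) / sqrt(2)
  s22 <- sum(E[2, ] * E[2, ]) / sqrt(2)
  w <- exp(c(s21, s22)); w <- w / sum(w)
  expect_equal(got[1, ], E[1, ])                    # only itself visible
  expect_equal(got[2, ], w[1] * E[1, ] + w[2] * E[2, ])
})

test_that("graph attention normalizes, respects symmetry and the gate", {
  cfg <- tinyConfig()
  mod <- initHetModel(cfg)

  # isolated region: the self-loop takes all the attention
  g1 <- tinyGraph(1, seed = 3)
  ser1 <- tinyStream(T = 4, M = 1)
  pol1 <- tinyPolicy(T = 4, M = 1)
  e1 <- temporalEncode(embedSequence(ser1, mod), mod)
  o1 <- spatialPolicyFuse(e1, g1, pol1, mod, returnAttention = TRUE)
  expect_equal(o1$attention[[1]], matrix(1, 1, 1), ignore_attr = TRUE)

  # two connected regions with identical features split attention evenly
  g2 <- makeRegionGraph(2, edgeDensity = 1, seed = 2)
  g2@coords <- rbind(c(0.5, 0.5), c(0.5, 0.5))  # kernel prior exactly 1
  Zsame <- array(rep(rnorm(4 * 2), each = 1), c(4, 2, 2))
  Zsame[, 2, ] <- Zsame[, 1, ]
  sersame <- sentinet:::newSummarySeries(Zsame, featureNames = c("f1", "f2"))
  polsame <- tinyPolicy(T = 4, M = 2)
  esame <- temporalEncode(embedSequence(sersame, mod), mod)
  osame <- spatialPolicyFuse(esame, g2, polsame, mod, returnAttention = TRUE)
  for (t in 1:4)
    expect_equal(osame$attention[[t]], matrix(0.5, 2, 2),
                 ignore_attr = TRUE)
  # attention rows always sum to one
  g3 <- tinyGraph(3, seed = 4)
  ser3 <- tinyStream(T = 5, M = 3)
  pol3 <- tinyPolicy(T = 5, M = 3)
  o3 <- spatialPolicyFuse(temporalEncode(embedSequence(ser3, mod), mod),
                          g3, pol3, mod, returnAttention = TRUE)
  for (t in 1:5)
    expect_equal(unname(rowSums(o3$attention[[t]])), rep(1, 3))

  # a saturated gate returns the spatial branch exactly
  modg <- mod
  modg@params$Wl[] <- 0
  modg@params$bl[] <- 30
  og <- spatialPolicyFuse(temporalEncode(embedSequence(ser3, modg), modg),
                          g3, pol3, modg, returnAttention = TRUE)
  expect_equal(og$latent, og$spatial, tolerance = 1e-12)
  expect_true(all(og$gate > 0 & og$gate < 1))

  # masked policy cells are refused
  polm <- maskPolicySeries(pol3, 0.5, seed = 1)
  expect_error(spatialPolicyFuse(temporalEncode(embedSequence(ser3, mod),
                                                mod),
                                 g3, polm, mod), "impute")
})

test_that("prediction heads are affine with floored softplus variances", {
  cfg <- tinyConfig()
  mod <- initHetModel(cfg)
  h0 <- array(0, c(3, 2, 5))
  out <- predictHeads(h0, mod)
  for (t in 1:3) for (j in 1:2)
    expect_equal(out$pointForecast[t, j, ], mod@params$bout,
                 ignore_attr = TRUE)

  set.seed(1)
  hr <- array(rnorm(10000 * 5, sd = 5), c(10000, 1, 5))
  vr <- forecastVariance(predictHeads(hr, mod)$dist)
  expect_true(all(vr >= cfg@varianceFloor))

  # Gaussian log-density agrees with the closed diagonal form
  z <- matrix(c(0.3, -1.2), 1); mu <- matrix(c(0.1, 0.2), 1)
  va <- matrix(c(0.5, 2), 1)
  nll <- compositeLoss(z, mu, va, z, alpha = 0, beta = 1)
  expect_equal(nll, -sum(dnorm(z, mu, sqrt(va), log = TRUE)))
})

test_that("the fused training pass matches the modular inference path", {
  cfg <- tinyConfig(depth = 2)
  mod <- initHetModel(cfg)
  g <- tinyGraph(3, seed = 2)
  ser <- tinyStream(T = 7, M = 3)
  pol <- tinyPolicy(T = 7, M = 3)
  h <- spatialPolicyFuse(temporalEncode(embedSequence(ser, mod), mod),
                         g, pol, mod)
  heads <- predictHeads(h, mod)
  lossModular <- compositeLoss(
    heads$pointForecast[1:6, , ], forecastMean(heads$dist)[1:6, , ],
    forecastVariance(heads$dist)[1:6, , ], seriesValues(ser)[2:7, , ],
    alpha = 1, beta = 0.5)
  fused <- sentinet:::hetLossGrad(
    mod@params, cfg, seriesValues(ser), seriesValues(pol),
    sentinet:::adjacencyWithSelf(g), log(kernelInfluenceMatrix(g)),
    alpha = 1, beta = 0.5, wantGrad = FALSE)
  expect_equal(fused$loss, lossModular)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tinyConfig(depth = 1)
  mod <- initHetModel(cfg)
  g <- tinyGraph(3, seed = 2)
  set.seed(31)
  W <- 5L; M <- 3L
  Z <- array(rnorm(W * M * 2), c(W, M, 2))
  Ip <- array(runif(W * M * 4), c(W, M, 4))
  adj <- sentinet:::adjacencyWithSelf(g)
  lp <- log(kernelInfluenceMatrix(g))
  out <- sentinet:::hetLossGrad(mod@params, cfg, Z, Ip, adj, lp, 1, 0.5)
  flat <- sentinet:::flattenParams(mod@params)
  gflat <- sentinet:::flattenParams(out$grads)
  idx <- sort(sample(length(flat), 150))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    f1 <- flat; f1[i] <- f1[i] + eps
    f2 <- flat; f2[i] <- f2[i] - eps
    l1 <- sentinet:::hetLossGrad(utils::relist(f1, mod@params), cfg, Z, Ip,
                                 adj, lp, 1, 0.5, wantGrad = FALSE)$loss
    l2 <- sentinet:::hetLossGrad(utils::relist(f2, mod@params), cfg, Z, Ip,
                                 adj, lp, 1, 0.5, wantGrad = FALSE)$loss
    (l1 - l2) / (2 * eps)
  }, numeric(1))
  relErr <- abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx]))
  expect_lt(max(relErr), 1e-4)
})

test_that("evaluation is deterministic and shape preserving", {
  cfg <- tinyConfig(depth = 2)
  mod <- initHetModel(cfg)
  g <- tinyGraph(2, seed = 6)
  ser <- tinyStream(T = 12, M = 2)
  pol <- tinyPolicy(T = 12, M = 2)
  f1 <- hetForecast(mod, ser, pol, g, blockLen = 5L)
  f2 <- hetForecast(mod, ser, pol, g, blockLen = 5L)
  expect_identical(f1$pointForecast, f2$pointForecast)
  expect_identical(forecastMean(f1$dist), forecastMean(f2$dist))
  expect_equal(dim(f1$latent), c(12L, 2L, 5L))
  expect_equal(dim(f1$pointForecast), c(12L, 2L, 2L))
})
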