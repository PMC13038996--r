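test_that("region graph construction covers degenerate and complete cases", {
  g1 <- makeRegionGraph(1, edgeDensity = 0, seed = 7)
  expect_equal(nRegions(g1), 1L)
  expect_equal(nrow(regionEdges(g1)), 0L)

  g5 <- makeRegionGraph(5, edgeDensity = 1, seed = 1)
  expect_equal(nrow(regionEdges(g5)), 10L)

  expect_error(makeRegionGraph(0), "M must be")
})

test_that("region graphs are reproducible and always connected", {
  ga <- makeRegionGraph(25, edgeDensity = 0.2, seed = 3)
  gb <- makeRegionGraph(25, edgeDensity = 0.2, seed = 3)
  expect_identical(regionEdges(ga), regionEdges(gb))
  expect_identical(regionCoords(ga), regionCoords(gb))
  expect_identical(demographics(ga), demographics(gb))

  # spanning-tree repair keeps near-empty graphs connected
  for (s in 1:5) {
    g <- makeRegionGraph(12, edgeDensity = 0.02, seed = s)
    ig <- igraph::graph_from_edgelist(regionEdges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 12 - igraph::vcount(ig)))
    expect_equal(igraph::components(ig)$no, 1L)
  }
})

test_that("policy process respects templates and dwell-time geometry", {
  g <- tinyGraph(2, seed = 4)
  one <- list(list(name = "strict", stringencyRange = c(70, 70),
                   maskProb = 1, meanDwell = Inf))
  pol <- simulatePolicySeries(g, 30, templates = one, seed = 2)
  P <- seriesValues(pol)
  expect_true(all(P[, , 1] == 0.70))
  expect_true(all(P[, , 2] == 1))
  expect_true(all(P[, , 3] == 0) && all(P[, , 4] == 0))

  zero <- list(list(name = "none", stringencyRange = c(0, 0),
                    maskProb = 0, meanDwell = 5))
  polz <- simulatePolicySeries(g, 50, templates = zero, seed = 3)
  expect_true(all(seriesValues(polz)[, , 1] == 0))

  expect_error(simulatePolicySeries(g, 10, templates = list(), seed = 1),
               "nonempty")

  # geometric dwell oracle: count observed regime sojourns directly
  g20 <- makeRegionGraph(20, edgeDensity = 0.2, seed = 9)
  pol <- simulatePolicySeries(g20, 2000, defaultPolicyTemplates(50), seed = 11)
  P <- seriesValues(pol)
  durs <- unlist(lapply(seq_len(20), function(j) {
    runs <- rle(apply(P[, j, ], 1L, paste, collapse = ","))$lengths
    runs[-length(runs)]  # final sojourn is truncated by the horizon
  }))
  expect_gt(length(durs), 200)
  expect_lt(abs(mean(durs) - 50) / 50, 0.10)
})

test_that("surveillance dynamics honour degenerate parameters and stability", {
  g <- tinyGraph(3, seed = 6)
  dp <- defaultDynParams()
  dp$A <- matrix(0, 3, 3); dp$coupling <- 0
  dp$processSd <- 0; dp$emissionSd <- 0
  dp$B <- dp$B * 0
  sim <- simulateSurveillance(g, NULL, T = 10, dynParams = dp, seed = 1)
  Z <- seriesValues(sim$series)
  for (f in 1:3) expect_true(all(Z[, , f] == dp$bias[f]))

  bad <- defaultDynParams(damping = 0.95, coupling = 0.2)
  expect_error(simulateSurveillance(g, NULL, 10, dynParams = bad),
               "unstable")

  s1 <- simulateSurveillance(g, NULL, 50, seed = 8)
  s2 <- simulateSurveillance(g, NULL, 50, seed = 8)
  expect_identical(seriesValues(s1$series), seriesValues(s2$series))
  expect_identical(s1$latent@values, s2$latent@values)
})

test_that("null-run variance matches the linear-Gaussian Lyapunov solution", {
  g <- makeRegionGraph(4, edgeDensity = 0.5, seed = 3)
  dp <- defaultDynParams()
  dp$saturationScale <- NULL   # exactly linear
  sim <- simulateSurveillance(g, NULL, T = 5000, dynParams = dp, seed = 7)
  Z <- seriesValues(sim$series)
  # independent oracle: discrete Lyapunov equation for H' = H A^T + c Wn H
  W <- kernelInfluenceMatrix(g)
  Wn <- W - diag(diag(W)); rs <- rowSums(Wn)
  Wn[rs > 0, ] <- Wn[rs > 0, , drop = FALSE] / rs[rs > 0]
  m <- nrow(dp$A); M <- 4L
  G <- kronecker(dp$A, diag(1, M)) + dp$coupling * kronecker(diag(1, m), Wn)
  Q <- diag(dp$processSd^2, M * m)
  P <- matrix(solve(diag((M * m)^2) - kronecker(G, G), as.vector(Q)), M * m)
  for (j in 1:M) {
    sel <- j + (seq_len(m) - 1L) * M     # vec(H) stacks regions fastest
    Vz <- dp$C %*% P[sel, sel] %*% t(dp$C) + diag(dp$emissionSd^2, nrow(dp$C))
    emp <- apply(Z[, j, ], 2L, var)
    expect_true(all(abs(emp / diag(Vz) - 1) < 0.15))
  }
})

test_that("null-regime series show no drift in windowed means", {
  g <- tinyGraph(3, seed = 13)
  sim <- simulateSurveillance(g, NULL, T = 4000, seed = 17)
  Z <- seriesValues(sim$series)
  win <- rep(1:8, each = 500)
  for (f in 1:3) {
    means <- tapply(as.vector(Z[, 1, f]), win, mean)
    fit <- summary(lm(means ~ seq_along(means)))
    expect_lt(abs(fit$coefficients[2, 3]), 3)  # |t| of the trend slope
  }
})

test_that("anomaly injection controls labelled fraction and conserves values", {
  g <- tinyGraph(2, seed = 5)
  sim <- simulateSurveillance(g, NULL, T = 30, seed = 2)

  # tiny series, ratio small enough that the expected episode count is zero
  out0 <- injectAnomalies(sim$series, ratio = 0.01, seed = 4)
  expect_true(all(anomalyLabels(out0) == 0L))
  expect_identical(seriesValues(out0), seriesValues(sim$series))

  outm0 <- injectAnomalies(sim$series, ratio = 0.4, magnitude = 0, seed = 4)
  expect_gt(sum(anomalyLabels(outm0)), 0)
  expect_identical(seriesValues(outm0), seriesValues(sim$series))

  expect_error(injectAnomalies(sim$series, ratio = 1), "ratio")

  big <- simulateSurveillance(makeRegionGraph(10, 0.3, seed = 3),
                              NULL, T = 10000, seed = 31)
  inj <- injectAnomalies(big$series, ratio = 0.068, seed = 5)
  frac <- mean(anomalyLabels(inj))
  expect_gte(frac, 0.058)
  expect_lte(frac, 0.078)

  # label conservation: values change only where labels are set
  changed <- apply(seriesValues(inj) != seriesValues(big$series), c(1, 2), any)
  expect_true(all(anomalyLabels(inj)[changed] == 1L))

  # episodes respect the minimum duration
  for (j in 1:10) {
    r <- rle(anomalyLabels(inj)[, j])
    expect_true(all(r$lengths[r$values == 1L] >= 3L))
  }
})

test_that("detection tables follow the Poisson count model", {
  g <- tinyGraph(2, seed = 8)
  empty <- simulateDetections(g, 5, densityParams = list(lambda = 0), seed = 1)
  expect_equal(nrow(empty), 0L)

  expect_error(simulateDetections(g, 5, densityParams = list(lambda = -1)),
               "nonnegative")

  # a single-individual frame carries the full attribute vector
  one <- NULL
  for (s in 1:50) {
    cand <- simulateDetections(tinyGraph(1, seed = 2), 1,
                               densityParams = list(lambda = 1), seed = s)
    if (nrow(cand) == 1L) { one <- cand; break }
  }
  expect_false(is.null(one))
  expect_true(all(c("velocity", "compliance", "activity") %in% names(one)))

  g1 <- tinyGraph(1, seed = 3)
  det <- simulateDetections(g1, 1000, densityParams = list(lambda = 5),
                            seed = 6)
  counts <- tabulate(det$time, nbins = 1000)
  expect_gte(mean(counts), 4.7)
  expect_lte(mean(counts), 5.3)

  d1 <- simulateDetections(g, 20, seed = 9)
  d2 <- simulateDetections(g, 20, seed = 9)
  expect_identical(d1, d2)
})
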