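# Small shared fixtures, built in code.

tinyGraph <- function(M = 3L, seed = 11L, density = 0.6) {
  makeRegionGraph(M, edgeDensity = density, seed = seed)
}

tinyConfig <- function(k = 2L, r = 4L, depth = 1L, dModel = 8L, nHeads = 2L,
                       seed = 5L, dropout = 0) {
  hetConfig(nFeatures = k, policyDim = r, depth = depth, dModel = dModel,
            nHeads = nHeads, dFf = 12L, latentDim = 5L, intHidden = 4L,
            dropout = dropout, seed = seed)
}

tinyStream <- function(T = 40L, M = 3L, k = 2L, seed = 21L) {
  set.seed(seed)
  Z <- array(rnorm(T * M * k), dim = c(T, M, k))
  sentinet:::newSummarySeries(Z, featureNames = paste0("f", seq_len(k)))
}

tinyPolicy <- function(T = 40L, M = 3L, seed = 22L) {
  set.seed(seed)
  vals <- array(runif(T * M * 4), dim = c(T, M, 4))
  new("PolicySeries", values = vals, missingMask = matrix(FALSE, T, M),
      scheme = defaultPolicyScheme())
}
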