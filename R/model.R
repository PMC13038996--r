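#' Construct a forecaster configuration
#'
#' Reference-scale defaults are a depth-4 stack, model width 256, eight
#' attention heads and dropout 0.1. The single `scale` factor shrinks every
#' width proportionally (keeping `dModel` a multiple of `nHeads`) for
#' desk-scale runs; depth and dropout are untouched.
#'
#' @param nFeatures number of summary features k.
#' @param policyDim policy-vector dimension r.
#' @param depth temporal transformer depth L.
#' @param dModel model width.
#' @param nHeads attention heads (head width is `dModel / nHeads`).
#' @param dFf feed-forward width.
#' @param latentDim graph-attention / latent width m.
#' @param intHidden intervention-encoder hidden width.
#' @param dropout dropout rate in \[0, 1), applied during training only.
#' @param useKernelPrior multiply graph-attention scores by the spatial
#'   kernel prior.
#' @param varianceFloor floor of the predictive variances.
#' @param seed parameter-initialization seed.
#' @param scale width scale factor for desk-scale runs.
#' @return A [HetConfig-class].
#' @export
hetConfig <- function(nFeatures, policyDim = 4L, depth = 4L, dModel = 256L,
                      nHeads = 8L, dFf = NULL, latentDim = NULL,
                      intHidden = NULL, dropout = 0.1, useKernelPrior = TRUE,
                      varianceFloor = 1e-4, seed = 1L, scale = 1) {
  dModel <- max(nHeads, as.integer(round(dModel * scale / nHeads)) * nHeads)
  if (is.null(dFf)) dFf <- 2L * dModel
  else dFf <- max(1L, as.integer(round(dFf * scale)))
  if (is.null(latentDim)) latentDim <- max(1L, dModel %/% 2L)
  else latentDim <- max(1L, as.integer(round(latentDim * scale)))
  if (is.null(intHidden)) intHidden <- max(4L, dModel %/% 4L)
  cfg <- new("HetConfig",
      nFeatures = as.integer(nFeatures), policyDim = as.integer(policyDim),
      depth = as.integer(depth), dModel = as.integer(dModel),
      nHeads = as.integer(nHeads), dFf = as.integer(dFf),
      latentDim = as.integer(latentDim), intHidden = as.integer(intHidden),
      dropout = dropout, useKernelPrior = useKernelPrior,
      varianceFloor = varianceFloor, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# scaled-normal init, sd = 1/sqrt(fan-in)
rmat <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
}

#' Initialize model parameters
#'
#' Projections use scaled-normal initialization (sd `1/sqrt(fan-in)`),
#' biases start at zero, the Gaussian-variance head bias starts at
#' `softplus^-1(1)` so initial predictive variances are about one, and the
#' policy-conditioning correction network is zero-initialized so the
#' corrected forecast reduces exactly to the base head before training.
#'
#' @param config a [HetConfig-class].
#' @return An unfitted [HetModel-class].
#' @export
initHetModel <- function(config) {
  d <- config@dModel; k <- config@nFeatures; m <- config@latentDim
  r <- config@policyDim; ih <- config@intHidden; ff <- config@dFf
  withSeed(config@seed, {
    layers <- lapply(seq_len(config@depth), function(l) {
      list(Wq = rmat(d, d), Wk = rmat(d, d), Wv = rmat(d, d), Wo = rmat(d, d),
           W1 = rmat(d, ff), b1 = numeric(ff),
           W2 = rmat(ff, d), b2 = numeric(d))
    })
    params <- list(
      Wz = rmat(k, d), bz = numeric(d),
      layers = layers,
      Wg = rmat(d, m), aSelf = rnorm(m, sd = 1 / sqrt(m)),
      aNei = rnorm(m, sd = 1 / sqrt(m)),
      Wi1 = rmat(r, ih), bi1 = numeric(ih),
      Wi2 = rmat(ih, m), bi2 = numeric(m),
      Wl = rmat(2L * m, m), bl = numeric(m),
      Wout = rmat(m, k), bout = numeric(k),
      Wmu = rmat(m, k), bmu = numeric(k),
      Wsig = rmat(m, k), bsig = rep(log(exp(1) - 1), k),
      Wp1 = rmat(r + 1L, ih), bp1 = numeric(ih),
      Wp2 = matrix(0, ih, m), bp2 = numeric(m)
    )
    new("HetModel", config = config, params = params, fitted = FALSE)
  })
}

#' Sinusoidal positional encoding
#'
#' Standard sinusoidal table: even columns `sin(pos / 10000^(2i/d))`, odd
#' columns `cos` at the same frequency; positions are zero-based.
#'
#' @param T number of positions.
#' @param d encoding width.
#' @return T x d matrix.
#' @export
positionalEncoding <- function(T, d) {
  pos <- seq_len(T) - 1
  pe <- matrix(0, T, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

# row-wise layer normalization (no learnable affine); returns value + cache
lnForward <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  list(y = xhat, xhat = xhat, inv = inv)
}

lnBackward <- function(dY, cache) {
  xhat <- cache$xhat
  (dY - rowMeans(dY) - xhat * rowMeans(dY * xhat)) * cache$inv
}

# adjacency with self-loops as a logical matrix
adjacencyWithSelf <- function(graph) {
  M <- nRegions(graph)
  A <- diag(TRUE, M)
  e <- regionEdges(graph)
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

asValueArray <- function(z) {
  if (is(z, "SummarySeries")) seriesValues(z) else z
}

#' Embed a summary series into model space
#'
#' Input embedding `e0 = PE(t) + LayerNorm(Wz z + bz)`: a learned affine
#' projection of each region-time summary, layer-normalized, plus the
#' sinusoidal positional encoding of the (window-relative) time position.
#'
#' @param z a [SummarySeries-class] or T x M x k array.
#' @param model a [HetModel-class].
#' @return T x M x dModel numeric array.
#' @export
embedSequence <- function(z, model) {
  Z <- asValueArray(z)
  cfg <- model@config
  d <- dim(Z)
  stopIfNot(d[3L] == cfg@nFeatures,
            "feature count does not match the fitted projection")
  T <- d[1L]; M <- d[2L]
  X0 <- matrix(Z, T * M, d[3L]) %*% model@params$Wz +
    matrix(model@params$bz, T * M, cfg@dModel, byrow = TRUE)
  ln <- lnForward(X0)
  pe <- positionalEncoding(T, cfg@dModel)
  E0 <- ln$y + pe[rep(seq_len(T), times = M), , drop = FALSE]
  array(E0, dim = c(T, M, cfg@dModel))
}

# multi-head causal self-attention for one region's (T x d) sequence;
# returns output and caches (weights per head) for backprop / inspection
mhsaForward <- function(E, lay, nHeads, causal = TRUE) {
  T <- nrow(E); d <- ncol(E); dk <- d %/% nHeads
  Q <- E %*% lay$Wq; K <- E %*% lay$Wk; V <- E %*% lay$Wv
  O <- matrix(0, T, d)
  attn <- vector("list", nHeads)
  maskIdx <- if (causal && T > 1L) which(
    matrix(rep(seq_len(T), T), T, T, byrow = TRUE) > seq_len(T)) else integer()
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    if (length(maskIdx)) S[maskIdx] <- -Inf
    S <- S - apply(S, 1L, max)
    A <- exp(S)
    A <- A / rowSums(A)
    attn[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  list(out = O %*% lay$Wo, Q = Q, K = K, V = V, attn = attn, Ocat = O)
}

#' Temporal transformer encoding
#'
#' Applies `depth` stacked layers of causal multi-head self-attention plus
#' a position-wise feed-forward block, each with residual connection and
#' layer normalization, independently per region along the time axis.
#' Causal masking restricts every query to positions at or before it, so
#' forecasts depend only on the past. With `depth = 0` the input is
#' returned unchanged.
#'
#' @param e0 T x M x dModel array from [embedSequence()].
#' @param model a [HetModel-class].
#' @param returnAttention also return per-layer, per-region attention
#'   weight matrices.
#' @return T x M x dModel array, or a list `(encoded, attention)` when
#'   `returnAttention = TRUE`.
#' @export
temporalEncode <- function(e0, model, returnAttention = FALSE) {
  cfg <- model@config
  stopIfNot(all(is.finite(e0)), "non-finite input to temporal encoder")
  d <- dim(e0)
  T <- d[1L]; M <- d[2L]
  E <- matrix(e0, T * M, d[3L])
  attnAll <- list()
  for (l in seq_len(cfg@depth)) {
    lay <- model@params$layers[[l]]
    attnAll[[l]] <- vector("list", M)
    for (j in seq_len(M)) {
      idx <- ((j - 1L) * T + 1L):(j * T)
      Ej <- E[idx, , drop = FALSE]
      mh <- mhsaForward(Ej, lay, cfg@nHeads)
      n1 <- lnForward(Ej + mh$out)
      F1 <- pmax(n1$y %*% lay$W1 +
                   matrix(lay$b1, T, cfg@dFf, byrow = TRUE), 0)
      F2 <- F1 %*% lay$W2 + matrix(lay$b2, T, d[3L], byrow = TRUE)
      E[idx, ] <- lnForward(n1$y + F2)$y
      attnAll[[l]][[j]] <- mh$attn
    }
  }
  out <- array(E, dim = d)
  if (returnAttention) list(encoded = out, attention = attnAll) else out
}

# graph attention + policy gating for one time slice; X is M x d.
gatSlice <- function(X, params, adj, logPrior) {
  G <- X %*% params$Wg
  sSelf <- drop(G %*% params$aSelf)
  sNei <- drop(G %*% params$aNei)
  raw <- outer(sSelf, sNei, "+")
  S <- leakyRelu(raw)
  if (!is.null(logPrior)) S <- S + logPrior
  S[!adj] <- -Inf
  S <- S - apply(S, 1L, max)
  A <- exp(S)
  A <- A / rowSums(A)
  pre <- A %*% G
  list(h = elu(pre), alpha = A, G = G, raw = raw, pre = pre)
}

#' Spatial aggregation and policy-aware gating
#'
#' For every time step, regions exchange information through graph
#' attention over their neighbourhood (self-loops included): scores are
#' LeakyReLU attention logits, optionally multiplied by the spatial kernel
#' prior, normalized by softmax over neighbours, and aggregated through an
#' ELU nonlinearity. Encoded intervention vectors `eta = MLP(I)` are then
#' fused by a learned sigmoid gate:
#' `h = lambda * hSpatial + (1 - lambda) * eta` with
#' `lambda = sigmoid(Wl [hSpatial; eta] + bl)`.
#'
#' @param eL T x M x dModel array from [temporalEncode()].
#' @param graph a [RegionGraph-class].
#' @param policy a [PolicySeries-class]; masked cells must already be
#'   imputed (an error otherwise).
#' @param model a [HetModel-class].
#' @param returnAttention also return the T-list of M x M attention
#'   matrices and the gate values.
#' @return T x M x latentDim array of fused latents (or a list when
#'   `returnAttention = TRUE`).
#' @export
spatialPolicyFuse <- function(eL, graph, policy, model,
                              returnAttention = FALSE) {
  cfg <- model@config
  p <- model@params
  d <- dim(eL)
  T <- d[1L]; M <- d[2L]
  stopIfNot(nRegions(graph) == M, "region count mismatch between graph and series")
  Ipol <- seriesValues(policy)
  stopIfNot(dim(Ipol)[1L] >= T && dim(Ipol)[2L] == M,
            "policy series does not align with the encoded series")
  if (any(missingMask(policy)[seq_len(T), , drop = FALSE]))
    stop("policy series still contains masked cells; impute first",
         call. = FALSE)
  adj <- adjacencyWithSelf(graph)
  logPrior <- if (cfg@useKernelPrior)
    log(kernelInfluenceMatrix(graph)) else NULL
  m <- cfg@latentDim
  Htil <- matrix(0, T * M, m)
  alphas <- if (returnAttention) vector("list", T) else NULL
  for (t in seq_len(T)) {
    X <- matrix(eL[t, , ], M, d[3L])
    gs <- gatSlice(X, p, adj, logPrior)
    Htil[t + (seq_len(M) - 1L) * T, ] <- gs$h
    if (returnAttention) alphas[[t]] <- gs$alpha
  }
  Imat <- matrix(Ipol[seq_len(T), , , drop = FALSE], T * M, cfg@policyDim)
  H1 <- tanh(Imat %*% p$Wi1 + matrix(p$bi1, T * M, cfg@intHidden, byrow = TRUE))
  Eta <- H1 %*% p$Wi2 + matrix(p$bi2, T * M, m, byrow = TRUE)
  Lam <- sigmoid(cbind(Htil, Eta) %*% p$Wl +
                   matrix(p$bl, T * M, m, byrow = TRUE))
  H <- Lam * Htil + (1 - Lam) * Eta
  out <- array(H, dim = c(T, M, m))
  if (returnAttention)
    list(latent = out, attention = alphas,
         gate = array(Lam, dim = c(T, M, m)),
         spatial = array(Htil, dim = c(T, M, m)),
         eta = array(Eta, dim = c(T, M, m)))
  else out
}

#' Prediction heads: point forecast and Gaussian uncertainty
#'
#' The point head is affine, `zhat = Wout h + bout`; the distribution head
#' produces a diagonal Gaussian with mean `mu = Wmu h + bmu` and variance
#' `softplus(Wsig h + bsig)` floored at the configured variance floor. The
#' two heads are parameterized separately. The forecast at position `t` is
#' for the summary at `t + 1`.
#'
#' @param h T x M x latentDim array from [spatialPolicyFuse()].
#' @param model a [HetModel-class].
#' @return list with `pointForecast` (T x M x k array) and `dist`
#'   (a [GaussianForecast-class]).
#' @export
predictHeads <- function(h, model) {
  cfg <- model@config
  p <- model@params
  stopIfNot(all(is.finite(h)), "non-finite latent input")
  d <- dim(h)
  T <- d[1L]; M <- d[2L]; k <- cfg@nFeatures
  H <- matrix(h, T * M, d[3L])
  Zhat <- H %*% p$Wout + matrix(p$bout, T * M, k, byrow = TRUE)
  Mu <- H %*% p$Wmu + matrix(p$bmu, T * M, k, byrow = TRUE)
  Var <- softplus(H %*% p$Wsig + matrix(p$bsig, T * M, k, byrow = TRUE)) +
    cfg@varianceFloor
  list(
    pointForecast = array(Zhat, dim = c(T, M, k)),
    dist = new("GaussianForecast",
               mean = array(Mu, dim = c(T, M, k)),
               variance = array(Var, dim = c(T, M, k)),
               varianceFloor = cfg@varianceFloor)
  )
}

#' Run the full forecaster over a stream in causal blocks
#'
#' Processes the stream in consecutive non-overlapping blocks of
#' `blockLen` steps (matching the training window length); within each
#' block causal attention guarantees the forecast at position `t` uses only
#' observations up to `t`. Returns latents, point forecasts and the
#' Gaussian forecast grid, all aligned so index `t` holds the prediction
#' *made at* `t` (for `t + 1`).
#'
#' @param model a fitted [HetModel-class].
#' @param series a [SummarySeries-class].
#' @param policy an imputed [PolicySeries-class].
#' @param graph a [RegionGraph-class].
#' @param blockLen processing block length.
#' @return list with `latent` (T x M x m), `pointForecast` (T x M x k),
#'   `dist` ([GaussianForecast-class]).
#' @export
hetForecast <- function(model, series, policy, graph, blockLen = 64L) {
  Z <- seriesValues(series)
  T <- dim(Z)[1L]; M <- dim(Z)[2L]
  m <- model@config@latentDim; k <- model@config@nFeatures
  lat <- array(0, dim = c(T, M, m))
  pf <- array(0, dim = c(T, M, k))
  mu <- array(0, dim = c(T, M, k))
  va <- array(0, dim = c(T, M, k))
  starts <- seq(1L, T, by = blockLen)
  for (s in starts) {
    e <- min(T, s + blockLen - 1L)
    zb <- Z[s:e, , , drop = FALSE]
    pb <- new("PolicySeries",
              values = seriesValues(policy)[s:e, , , drop = FALSE],
              missingMask = missingMask(policy)[s:e, , drop = FALSE],
              scheme = policyScheme(policy))
    sb <- newSummarySeries(zb, featureNames = featureNames(series))
    h <- spatialPolicyFuse(temporalEncode(embedSequence(sb, model), model),
                           graph, pb, model)
    heads <- predictHeads(h, model)
    lat[s:e, , ] <- h
    pf[s:e, , ] <- heads$pointForecast
    mu[s:e, , ] <- forecastMean(heads$dist)
    va[s:e, , ] <- forecastVariance(heads$dist)
  }
  list(latent = lat, pointForecast = pf,
       dist = new("GaussianForecast", mean = mu, variance = va,
                  varianceFloor = model@config@varianceFloor))
}
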