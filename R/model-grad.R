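# Fused forward + analytic backward pass over one training window.
#
# Training needs cached intermediates, so this file implements a single
# cached pass mirroring the modular inference path in model.R (a unit test
# asserts the two paths agree). Gradients are hand-derived for every stage:
# embedding projection + LayerNorm, causal multi-head self-attention,
# position-wise feed-forward, graph attention with optional kernel prior,
# the intervention MLP, the policy gate, and the three prediction heads.
# Correctness is pinned by a finite-difference gradient check in the tests.

reluGrad <- function(x) (x > 0) + 0
eluGrad <- function(pre) ifelse(pre > 0, 1, exp(pmin(pre, 0)))

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

# Composite loss over a window's predictions:
#   alpha * MSE (mean over features) + beta * Gaussian NLL (sum over
#   features), averaged over the (W-1) * M predicted region-time cells.
# Returns loss plus gradients wrt Zhat, Mu, Spre at the predicting rows.
windowLossParts <- function(Zhat, Mu, Var, Spre, Tgt, alpha, beta, k) {
  nCells <- nrow(Tgt)
  resP <- Zhat - Tgt
  resM <- Tgt - Mu
  mse <- mean(rowMeans(resP^2))
  nll <- mean(rowSums(0.5 * (log(2 * pi * Var) + resM^2 / Var)))
  loss <- alpha * mse + beta * nll
  dZhat <- alpha * 2 * resP / (nCells * k)
  dMu <- beta * (-resM / Var) / nCells
  dVar <- beta * 0.5 * (1 / Var - resM^2 / Var^2) / nCells
  dSpre <- dVar * sigmoid(Spre)   # softplus'
  list(loss = loss, mse = mse, nll = nll,
       dZhat = dZhat, dMu = dMu, dSpre = dSpre)
}

# One window: Zw (W x M x k), Iw (W x M x r). Returns loss and a gradient
# list shaped like `params`. With wantGrad = FALSE only the loss is
# computed (used for validation batches).
hetLossGrad <- function(params, cfg, Zw, Iw, adj, logPrior,
                        alpha, beta, training = FALSE, wantGrad = TRUE) {
  d <- cfg@dModel; k <- cfg@nFeatures; m <- cfg@latentDim
  H <- cfg@nHeads; dk <- d %/% H; ff <- cfg@dFf; ih <- cfg@intHidden
  W <- dim(Zw)[1L]; M <- dim(Zw)[2L]
  WM <- W * M
  pdrop <- if (training) cfg@dropout else 0

  ## ---- forward ----
  Zmat <- matrix(Zw, WM, k)
  X0 <- Zmat %*% params$Wz + matrix(params$bz, WM, d, byrow = TRUE)
  ln0 <- lnForward(X0)
  pe <- positionalEncoding(W, d)
  E <- ln0$y + pe[rep(seq_len(W), times = M), , drop = FALSE]

  maskIdx <- if (W > 1L) which(
    matrix(rep(seq_len(W), W), W, W, byrow = TRUE) > seq_len(W)) else integer()
  layerCache <- vector("list", cfg@depth)
  for (l in seq_len(cfg@depth)) {
    lay <- params$layers[[l]]
    layerCache[[l]] <- vector("list", M)
    for (j in seq_len(M)) {
      idx <- ((j - 1L) * W + 1L):(j * W)
      Ein <- E[idx, , drop = FALSE]
      Q <- Ein %*% lay$Wq; K <- Ein %*% lay$Wk; V <- Ein %*% lay$Wv
      Ocat <- matrix(0, W, d)
      attn <- vector("list", H)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        S <- tcrossprod(Q[, cols, drop = FALSE],
                        K[, cols, drop = FALSE]) / sqrt(dk)
        if (length(maskIdx)) S[maskIdx] <- -Inf
        S <- S - apply(S, 1L, max)
        A <- exp(S); A <- A / rowSums(A)
        attn[[h]] <- A
        Ocat[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      O <- Ocat %*% lay$Wo
      drop1 <- if (pdrop > 0)
        matrix((runif(W * d) >= pdrop) / (1 - pdrop), W, d) else NULL
      if (!is.null(drop1)) O <- O * drop1
      ln1 <- lnForward(Ein + O)
      N1 <- ln1$y
      F1pre <- N1 %*% lay$W1 + matrix(lay$b1, W, ff, byrow = TRUE)
      F1 <- pmax(F1pre, 0)
      F2 <- F1 %*% lay$W2 + matrix(lay$b2, W, d, byrow = TRUE)
      drop2 <- if (pdrop > 0)
        matrix((runif(W * d) >= pdrop) / (1 - pdrop), W, d) else NULL
      if (!is.null(drop2)) F2 <- F2 * drop2
      ln2 <- lnForward(N1 + F2)
      E[idx, ] <- ln2$y
      layerCache[[l]][[j]] <- list(Ein = Ein, Q = Q, K = K, V = V,
                                   attn = attn, Ocat = Ocat, drop1 = drop1,
                                   ln1 = ln1, N1 = N1, F1 = F1,
                                   drop2 = drop2, ln2 = ln2)
    }
  }

  gatCache <- vector("list", W)
  Htil <- matrix(0, WM, m)
  for (t in seq_len(W)) {
    rows <- t + (seq_len(M) - 1L) * W
    gs <- gatSlice(E[rows, , drop = FALSE], params, adj, logPrior)
    Htil[rows, ] <- gs$h
    gatCache[[t]] <- gs
  }
  Imat <- matrix(Iw, WM, cfg@policyDim)
  A1 <- Imat %*% params$Wi1 + matrix(params$bi1, WM, ih, byrow = TRUE)
  H1 <- tanh(A1)
  Eta <- H1 %*% params$Wi2 + matrix(params$bi2, WM, m, byrow = TRUE)
  Cat <- cbind(Htil, Eta)
  LamPre <- Cat %*% params$Wl + matrix(params$bl, WM, m, byrow = TRUE)
  Lam <- sigmoid(LamPre)
  Hout <- Lam * Htil + (1 - Lam) * Eta

  Zhat <- Hout %*% params$Wout + matrix(params$bout, WM, k, byrow = TRUE)
  Mu <- Hout %*% params$Wmu + matrix(params$bmu, WM, k, byrow = TRUE)
  Spre <- Hout %*% params$Wsig + matrix(params$bsig, WM, k, byrow = TRUE)
  Var <- softplus(Spre) + cfg@varianceFloor

  predIdx <- as.vector(vapply(seq_len(M), function(j)
    ((j - 1L) * W + 1L):((j - 1L) * W + W - 1L), integer(W - 1L)))
  tgtIdx <- predIdx + 1L
  lp <- windowLossParts(Zhat[predIdx, , drop = FALSE],
                        Mu[predIdx, , drop = FALSE],
                        Var[predIdx, , drop = FALSE],
                        Spre[predIdx, , drop = FALSE],
                        Zmat[tgtIdx, , drop = FALSE], alpha, beta, k)
  if (!wantGrad)
    return(list(loss = lp$loss, mse = lp$mse, nll = lp$nll))

  ## ---- backward ----
  g <- zeroLike(params)
  dZhat <- matrix(0, WM, k); dZhat[predIdx, ] <- lp$dZhat
  dMu <- matrix(0, WM, k); dMu[predIdx, ] <- lp$dMu
  dSpre <- matrix(0, WM, k); dSpre[predIdx, ] <- lp$dSpre

  g$Wout <- crossprod(Hout, dZhat); g$bout <- colSums(dZhat)
  g$Wmu <- crossprod(Hout, dMu); g$bmu <- colSums(dMu)
  g$Wsig <- crossprod(Hout, dSpre); g$bsig <- colSums(dSpre)
  dHout <- dZhat %*% t(params$Wout) + dMu %*% t(params$Wmu) +
    dSpre %*% t(params$Wsig)

  dLam <- dHout * (Htil - Eta)
  dHtil <- dHout * Lam
  dEta <- dHout * (1 - Lam)
  dLamPre <- dLam * Lam * (1 - Lam)
  g$Wl <- crossprod(Cat, dLamPre); g$bl <- colSums(dLamPre)
  dCat <- dLamPre %*% t(params$Wl)
  dHtil <- dHtil + dCat[, seq_len(m), drop = FALSE]
  dEta <- dEta + dCat[, m + seq_len(m), drop = FALSE]

  g$Wi2 <- crossprod(H1, dEta); g$bi2 <- colSums(dEta)
  dH1 <- dEta %*% t(params$Wi2)
  dA1 <- dH1 * (1 - H1^2)
  g$Wi1 <- crossprod(Imat, dA1); g$bi1 <- colSums(dA1)

  dE <- matrix(0, WM, d)
  for (t in seq_len(W)) {
    rows <- t + (seq_len(M) - 1L) * W
    gs <- gatCache[[t]]
    dh <- dHtil[rows, , drop = FALSE]
    dpre <- dh * eluGrad(gs$pre)
    dalpha <- tcrossprod(dpre, gs$G)
    dG <- crossprod(gs$alpha, dpre)
    dS <- gs$alpha * (dalpha - rowSums(dalpha * gs$alpha))
    dRaw <- dS * ifelse(gs$raw > 0, 1, 0.2)
    dsSelf <- rowSums(dRaw)
    dsNei <- colSums(dRaw)
    g$aSelf <- g$aSelf + drop(crossprod(gs$G, dsSelf))
    g$aNei <- g$aNei + drop(crossprod(gs$G, dsNei))
    dG <- dG + outer(dsSelf, params$aSelf) + outer(dsNei, params$aNei)
    X <- E[rows, , drop = FALSE]
    g$Wg <- g$Wg + crossprod(X, dG)
    dE[rows, ] <- dE[rows, ] + dG %*% t(params$Wg)
  }

  for (l in rev(seq_len(cfg@depth))) {
    lay <- params$layers[[l]]
    gl <- g$layers[[l]]
    for (j in seq_len(M)) {
      idx <- ((j - 1L) * W + 1L):(j * W)
      cc <- layerCache[[l]][[j]]
      dOut <- dE[idx, , drop = FALSE]
      dR2 <- lnBackward(dOut, cc$ln2)
      dN1 <- dR2
      dF2 <- if (is.null(cc$drop2)) dR2 else dR2 * cc$drop2
      gl$W2 <- gl$W2 + crossprod(cc$F1, dF2)
      gl$b2 <- gl$b2 + colSums(dF2)
      dF1 <- (dF2 %*% t(lay$W2)) * reluGrad(cc$F1)
      gl$W1 <- gl$W1 + crossprod(cc$N1, dF1)
      gl$b1 <- gl$b1 + colSums(dF1)
      dN1 <- dN1 + dF1 %*% t(lay$W1)
      dR1 <- lnBackward(dN1, cc$ln1)
      dEin <- dR1
      dO <- if (is.null(cc$drop1)) dR1 else dR1 * cc$drop1
      gl$Wo <- gl$Wo + crossprod(cc$Ocat, dO)
      dOcat <- dO %*% t(lay$Wo)
      dQ <- matrix(0, W, d); dK <- matrix(0, W, d); dV <- matrix(0, W, d)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$attn[[h]]
        dOh <- dOcat[, cols, drop = FALSE]
        Vh <- cc$V[, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dk)
        dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dk)
      }
      gl$Wq <- gl$Wq + crossprod(cc$Ein, dQ)
      gl$Wk <- gl$Wk + crossprod(cc$Ein, dK)
      gl$Wv <- gl$Wv + crossprod(cc$Ein, dV)
      dEin <- dEin + dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv)
      dE[idx, ] <- dEin
    }
    g$layers[[l]] <- gl
  }

  dX0 <- lnBackward(dE, ln0)
  g$Wz <- crossprod(Zmat, dX0)
  g$bz <- colSums(dX0)

  list(loss = lp$loss, mse = lp$mse, nll = lp$nll, grads = g)
}

# flatten / restore parameter lists (Adam state bookkeeping)
flattenParams <- function(p) {
  unlist(p, use.names = FALSE)
}

relistParams <- function(flat, skeleton) {
  relist(flat, skeleton)
}
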