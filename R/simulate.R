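#' LatentTrajectory: generative latent states behind a simulated stream
#'
#' @slot values numeric T x M x m array of latent states.
#' @slot dynParams list of transition parameters used for generation.
#' @exportClass LatentTrajectory
setClass("LatentTrajectory",
  representation(values = "array", dynParams = "list")
)

setValidity("LatentTrajectory", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be T x M x m")
  if (any(!is.finite(object@values))) return("latent states must be finite")
  TRUE
})

setMethod("show", "LatentTrajectory", function(object) {
  d <- dim(object@values)
  cat(sprintf("LatentTrajectory: T=%d, M=%d, m=%d\n", d[1L], d[2L], d[3L]))
})

#' Construct a random connected region graph
#'
#' Samples `M` regions with coordinates uniform in the unit square, draws
#' each of the `M(M-1)/2` candidate edges independently with probability
#' `edgeDensity`, and — when the draw leaves the graph disconnected — adds a
#' random spanning tree over the components so the returned graph is always
#' connected (by design, not an error). Demographic subgroup labels (age
#' band, income band, urbanicity) are assigned uniformly at random.
#'
#' @param M number of regions (>= 1).
#' @param edgeDensity edge inclusion probability in \[0, 1\].
#' @param seed integer seed; identical inputs give bitwise-identical graphs.
#' @param kernelBandwidth bandwidth sigma of the spatial influence kernel.
#' @return A [RegionGraph-class].
#' @examples
#' g <- makeRegionGraph(6, edgeDensity = 0.3, seed = 1)
#' nRegions(g)
#' @export
makeRegionGraph <- function(M, edgeDensity = 0.3, seed = 1L,
                            kernelBandwidth = 0.5) {
  stopIfNot(is.numeric(M) && length(M) == 1L && M >= 1, "M must be >= 1")
  M <- as.integer(M)
  stopIfNot(edgeDensity >= 0 && edgeDensity <= 1,
            "edgeDensity must lie in [0, 1]")
  withSeed(seed, {
    coords <- cbind(runif(M), runif(M))
    edges <- matrix(integer(), 0L, 2L)
    if (M > 1L) {
      pairs <- t(combn(M, 2L))
      keep <- runif(nrow(pairs)) < edgeDensity
      edges <- pairs[keep, , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        as.data.frame(edges), directed = FALSE,
        vertices = data.frame(name = seq_len(M)))
      comp <- igraph::components(g)
      if (comp$no > 1L) {
        # connect components with a random tree over component representatives
        reps <- vapply(seq_len(comp$no),
                       function(cc) which(comp$membership == cc)[sample.int(comp$csize[cc], 1L)],
                       1L)
        ord <- sample(comp$no)
        extra <- cbind(reps[ord[-length(ord)]], reps[ord[-1L]])
        edges <- rbind(edges, extra)
      }
    }
    storage.mode(edges) <- "integer"
    demo <- data.frame(
      ageBand = sample(c("youth", "mixed", "elderly"), M, replace = TRUE),
      incomeBand = sample(c("low", "high"), M, replace = TRUE),
      urbanicity = sample(c("urban", "rural"), M, replace = TRUE),
      stringsAsFactors = FALSE
    )
    new("RegionGraph",
        regionIds = sprintf("R%02d", seq_len(M)),
        edges = edges, coords = coords, demographics = demo,
        kernelBandwidth = kernelBandwidth)
  })
}

#' Default intervention regime templates
#'
#' Three regimes mirroring the default policy encoding categories: a strict
#' lockdown (high stringency, mask mandates likely), a moderate regime, and
#' a no-lockdown regime. Stringency ranges are on the 0-100 index scale;
#' `meanDwell` is the mean sojourn time (in steps) of the geometric regime
#' dwell process.
#'
#' @param meanDwell mean regime dwell time in steps (may be `Inf`).
#' @return list of regime templates.
#' @export
defaultPolicyTemplates <- function(meanDwell = 50) {
  list(
    list(name = "strict", stringencyRange = c(60, 90), maskProb = 0.9,
         meanDwell = meanDwell),
    list(name = "moderate", stringencyRange = c(30, 60), maskProb = 0.5,
         meanDwell = meanDwell),
    list(name = "none", stringencyRange = c(0, 20), maskProb = 0.1,
         meanDwell = meanDwell)
  )
}

#' Simulate a piecewise-constant policy process
#'
#' Each region follows an independent regime-switching process: a regime is
#' drawn uniformly from the templates, held for a geometric dwell time with
#' the template's mean, then replaced by a different template drawn
#' uniformly. Within a regime sojourn the stringency index is sampled once
#' from the template's range and the mask mandate once from its probability,
#' so the emitted encoded vector is constant within a sojourn. Vectors
#' follow the default 4-component encoding
#' (stringency/100, mask flag, one-hot regime category).
#'
#' @param graph a [RegionGraph-class].
#' @param T number of time steps (>= 1).
#' @param templates list of regime templates; see [defaultPolicyTemplates()].
#' @param seed integer seed.
#' @return A [PolicySeries-class] with nothing masked.
#' @export
simulatePolicySeries <- function(graph, T, templates = defaultPolicyTemplates(),
                                 seed = 1L) {
  stopIfNot(length(templates) >= 1L, "template set must be nonempty")
  stopIfNot(T >= 1, "T must be >= 1")
  T <- as.integer(T)
  M <- nRegions(graph)
  scheme <- defaultPolicyScheme()
  r <- scheme$r
  for (tp in templates) {
    stopIfNot(tp$name %in% scheme$categories,
              "template name must be a policy category of the scheme")
  }
  withSeed(seed, {
    values <- array(0, dim = c(T, M, r))
    for (j in seq_len(M)) {
      t <- 1L
      regime <- sample.int(length(templates), 1L)
      while (t <= T) {
        tp <- templates[[regime]]
        dwell <- if (is.infinite(tp$meanDwell)) T else
          rgeom(1L, prob = 1 / tp$meanDwell) + 1L
        idx <- runif(1L, tp$stringencyRange[1L], tp$stringencyRange[2L])
        mask <- rbinom(1L, 1L, tp$maskProb)
        vec <- encodePolicyRecord(
          policyRecord(idx, mask, tp$name), scheme)
        span <- t:min(T, t + dwell - 1L)
        values[span, j, ] <- matrix(vec, length(span), r, byrow = TRUE)
        t <- t + as.integer(dwell)
        if (length(templates) > 1L) {
          regime <- sample(setdiff(seq_along(templates), regime), 1L)
        }
      }
    }
    new("PolicySeries", values = values,
        missingMask = matrix(FALSE, T, M), scheme = scheme)
  })
}

#' Default transition/emission parameters for the surveillance simulator
#'
#' The latent dynamics are a damped linear-Gaussian transition with an
#' optional tanh saturation, spatial coupling through the row-normalized
#' kernel influence matrix, and an additive policy effect. Emission is a
#' linear-Gaussian decoder onto `k = 3` summary features
#' (density, activity, compliance).
#'
#' @param m latent dimension per region.
#' @param k number of emitted summary features.
#' @param r policy-vector dimension.
#' @param damping latent AR gain (spectral contribution of the local block).
#' @param coupling weight of the row-normalized spatial kernel term. The
#'   process is stationary only when `damping + coupling < 1`.
#' @param processSd latent innovation standard deviation.
#' @param emissionSd observation noise standard deviation.
#' @param saturationScale scale `s` of the soft saturation `s * tanh(x/s)`;
#'   `NULL` for exactly linear dynamics.
#' @return list of dynamic parameters accepted by [simulateSurveillance()].
#' @export
defaultDynParams <- function(m = 3L, k = 3L, r = 4L, damping = 0.8,
                             coupling = 0.15, processSd = 0.3,
                             emissionSd = 0.2, saturationScale = 3) {
  A <- diag(damping, m)
  if (m >= 2L) { A[1L, 2L] <- 0.05; A[2L, 1L] <- -0.05 }
  # stringency suppresses the activity latent; mask mandates raise compliance
  B <- matrix(0, m, r)
  B[min(2L, m), 1L] <- -0.05
  B[min(3L, m), 2L] <- 0.02
  Cm <- matrix(0, k, m)
  for (i in seq_len(k)) Cm[i, ((i - 1L) %% m) + 1L] <- 0.8
  if (k >= 2L && m >= 2L) { Cm[1L, 2L] <- 0.2; Cm[2L, 1L] <- 0.3 }
  if (k >= 3L && m >= 2L) Cm[3L, 2L] <- 0.2
  list(A = A, B = B, C = Cm, bias = c(1.0, 0.5, 0.7)[seq_len(k)],
       coupling = coupling, processSd = processSd, emissionSd = emissionSd,
       saturationScale = saturationScale,
       featureNames = c("density", "activity", "compliance")[seq_len(k)])
}

#' Simulate latent dynamics and observed region summaries
#'
#' Runs the coupled latent state-space process
#' `h[j,t] = sat(A h[j,t-1] + coupling * sum_k Wn[j,k] h[k,t-1] +
#' B I[j,t] + process noise)` where `Wn` is the row-normalized off-diagonal
#' spatial kernel matrix, `sat` an optional tanh saturation, and draws
#' observations from the linear-Gaussian decoder
#' `z[j,t] = C h[j,t] + bias + emission noise`. The linear map must be
#' stable (spectral radius < 1), otherwise the call is refused.
#'
#' @param graph a [RegionGraph-class].
#' @param policy a [PolicySeries-class] covering at least `T` steps, or
#'   `NULL` for a null (policy-free) run.
#' @param T number of steps.
#' @param dynParams list from [defaultDynParams()] (possibly modified).
#' @param seed integer seed.
#' @return list with elements `latent` ([LatentTrajectory-class]) and
#'   `series` ([SummarySeries-class]).
#' @export
simulateSurveillance <- function(graph, policy = NULL, T = 500L,
                                 dynParams = defaultDynParams(), seed = 1L) {
  M <- nRegions(graph)
  T <- as.integer(T)
  p <- dynParams
  m <- nrow(p$A)
  k <- nrow(p$C)
  W <- kernelInfluenceMatrix(graph)
  Wn <- W - diag(diag(W))
  rs <- rowSums(Wn)
  Wn[rs > 0, ] <- Wn[rs > 0, , drop = FALSE] / rs[rs > 0]
  G <- kronecker(diag(1, M), p$A) + p$coupling * kronecker(Wn, diag(1, m))
  sr <- max(Mod(eigen(G, only.values = TRUE)$values))
  if (sr >= 1)
    stop(sprintf(
      "unstable transition: spectral radius %.3f >= 1; reduce damping/coupling",
      sr), call. = FALSE)
  Ipol <- if (is.null(policy)) NULL else seriesValues(policy)
  if (!is.null(Ipol)) {
    stopIfNot(dim(Ipol)[1L] >= T && dim(Ipol)[2L] == M,
              "policy series must cover T steps for every region")
  }
  sat <- function(x) {
    s <- p$saturationScale
    if (is.null(s) || !is.finite(s)) x else s * tanh(x / s)
  }
  withSeed(seed, {
    H <- array(0, dim = c(T, M, m))
    Z <- array(0, dim = c(T, M, k))
    hPrev <- matrix(0, M, m)
    for (t in seq_len(T)) {
      drive <- hPrev %*% t(p$A) + p$coupling * (Wn %*% hPrev)
      if (!is.null(Ipol))
        drive <- drive + matrix(Ipol[t, , ], M) %*% t(p$B)
      noise <- matrix(rnorm(M * m, sd = p$processSd), M, m)
      hCur <- sat(drive + noise)
      H[t, , ] <- hCur
      eps <- matrix(rnorm(M * k, sd = p$emissionSd), M, k)
      Z[t, , ] <- hCur %*% t(p$C) +
        matrix(p$bias, M, k, byrow = TRUE) + eps
      hPrev <- hCur
    }
    list(
      latent = new("LatentTrajectory", values = H, dynParams = p),
      series = newSummarySeries(Z, featureNames = p$featureNames)
    )
  })
}

#' Inject contiguous anomaly episodes into a summary series
#'
#' Places contiguous per-region anomaly episodes uniformly at random until
#' the expected labelled fraction matches `ratio`. Each episode perturbs one
#' randomly chosen feature over its span: with probability 0.7 a mean shift
#' of `magnitude` within-feature standard deviations (random sign), and
#' otherwise a variance inflation adding noise with that standard deviation.
#' Episode lengths are `minDuration` plus a geometric excess with mean
#' `meanLength - minDuration`. Labels are set exactly on perturbed cells.
#'
#' @param series a [SummarySeries-class].
#' @param ratio target anomalous cell fraction in (0, 1).
#' @param magnitude effect size in within-feature standard deviations (>= 0).
#' @param minDuration minimum episode length in steps.
#' @param meanLength mean episode length in steps (>= minDuration).
#' @param seed integer seed.
#' @return A [SummarySeries-class] with `anomalyLabels` set.
#' @export
injectAnomalies <- function(series, ratio = 0.068, magnitude = 2.5,
                            minDuration = 3L, meanLength = 6, seed = 1L) {
  stopIfNot(ratio > 0 && ratio < 1, "ratio must lie in (0, 1)")
  stopIfNot(magnitude >= 0, "magnitude must be >= 0")
  stopIfNot(meanLength >= minDuration, "meanLength must be >= minDuration")
  Z <- seriesValues(series)
  d <- dim(Z)
  T <- d[1L]; M <- d[2L]; k <- d[3L]
  labels <- matrix(0L, T, M)
  sds <- apply(Z, 3L, sd)
  sds[sds == 0] <- 1
  nEpisodes <- round(ratio * T * M / meanLength)
  pExtra <- 1 / (meanLength - minDuration + 1)
  withSeed(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < nEpisodes && tries < nEpisodes * 60L) {
      tries <- tries + 1L
      len <- minDuration + rgeom(1L, pExtra)
      if (len > T) len <- T
      j <- sample.int(M, 1L)
      t0 <- sample.int(T - len + 1L, 1L)
      span <- t0:(t0 + len - 1L)
      if (any(labels[span, j] == 1L)) next
      f <- sample.int(k, 1L)
      if (runif(1L) < 0.7) {
        shift <- sample(c(-1, 1), 1L) * magnitude * sds[f]
        Z[span, j, f] <- Z[span, j, f] + shift
      } else {
        Z[span, j, f] <- Z[span, j, f] +
          rnorm(len, sd = magnitude * sds[f])
      }
      labels[span, j] <- 1L
      placed <- placed + 1L
    }
    out <- series
    out@values <- Z
    out@anomalyLabels <- labels
    validObject(out)
    out
  })
}

#' Simulate an individual-level detection table
#'
#' A synthetic stand-in for per-frame individual detections: the number of
#' individuals in region `j` at step `t` is Poisson with the region's
#' expected count, centroids are jittered around the region coordinate but
#' constrained to fall inside the region's nearest-neighbour cell, and each
#' individual carries a `d = 3` attribute vector
#' (velocity, compliance flag, activity score).
#'
#' @param graph a [RegionGraph-class].
#' @param T number of frames.
#' @param densityParams list with `lambda` (scalar or per-region expected
#'   count, >= 0) and `complianceProb` (Bernoulli rate of the compliance
#'   flag).
#' @param seed integer seed.
#' @return data.frame with columns `time`, `id`, `x`, `y`, `velocity`,
#'   `compliance`, `activity` (a detection table).
#' @export
simulateDetections <- function(graph, T,
                               densityParams = list(lambda = 5,
                                                    complianceProb = 0.7),
                               seed = 1L) {
  M <- nRegions(graph)
  T <- as.integer(T)
  lambda <- rep_len(densityParams$lambda, M)
  stopIfNot(all(lambda >= 0), "expected counts must be nonnegative")
  cp <- densityParams$complianceProb %||% 0.7
  coords <- regionCoords(graph)
  withSeed(seed, {
    rows <- vector("list", T)
    nextId <- 1L
    for (t in seq_len(T)) {
      counts <- rpois(M, lambda)
      n <- sum(counts)
      if (n == 0L) next
      j <- rep(seq_len(M), counts)
      pos <- coords[j, , drop = FALSE] +
        matrix(rnorm(2L * n, sd = 0.06), n, 2L)
      # keep centroids inside their region's nearest-neighbour cell
      for (it in 1:6) {
        d2 <- outer(pos[, 1L], coords[, 1L], "-")^2 +
          outer(pos[, 2L], coords[, 2L], "-")^2
        bad <- max.col(-d2, ties.method = "first") != j
        if (!any(bad)) break
        pos[bad, ] <- (pos[bad, , drop = FALSE] +
                         coords[j[bad], , drop = FALSE]) / 2
      }
      pos[] <- pmin(pmax(pos, 0), 1)
      rows[[t]] <- data.frame(
        time = t,
        id = seq.int(nextId, length.out = n),
        x = pos[, 1L], y = pos[, 2L],
        velocity = abs(rnorm(n, 1.2, 0.5)),
        compliance = rbinom(n, 1L, cp),
        activity = rgamma(n, shape = 2, scale = 0.5)
      )
      nextId <- nextId + n
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out))
      out <- data.frame(time = integer(), id = integer(), x = numeric(),
                        y = numeric(), velocity = numeric(),
                        compliance = integer(), activity = numeric())
    rownames(out) <- NULL
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
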