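#' Default policy encoding scheme
#'
#' The default fixed-length intervention encoding: component 1 is the
#' lockdown stringency index divided by its 0-100 scale, component 2 the
#' binary mask-mandate flag, and components 3-4 a one-hot over the regime
#' categories `moderate` and `none` with `strict` as the dropped reference
#' level (a strict record therefore encodes trailing zeros).
#'
#' @return list with elements `indexScale`, `categories`, `reference`, `r`
#'   and component `layout`.
#' @export
defaultPolicyScheme <- function() {
  list(indexScale = 100,
       categories = c("strict", "moderate", "none"),
       reference = "strict",
       r = 4L,
       layout = c("stringency", "mask_mandate", "cat_moderate", "cat_none"))
}

#' Construct a policy record
#'
#' @param lockdownIndex stringency index on the 0-100 scale.
#' @param maskMandate binary mask-mandate flag.
#' @param regime regime category, one of `strict`, `moderate`, `none`.
#' @return list of class `policyRecord`.
#' @export
policyRecord <- function(lockdownIndex, maskMandate, regime) {
  structure(list(lockdownIndex = lockdownIndex,
                 maskMandate = maskMandate,
                 regime = regime),
            class = "policyRecord")
}

#' Encode a policy record as a fixed-length vector
#'
#' Normalizes the stringency index by the scheme scale and appends the mask
#' flag and the regime one-hot (reference level dropped). Under the default
#' scheme the result has `r = 4` components; e.g. a strict lockdown at
#' index 75 with a mask mandate encodes to `c(0.75, 1, 0, 0)`.
#'
#' @param record a [policyRecord()].
#' @param scheme encoding scheme; see [defaultPolicyScheme()].
#' @return named numeric vector of length `scheme$r`.
#' @export
encodePolicyRecord <- function(record, scheme = defaultPolicyScheme()) {
  stopIfNot(record$regime %in% scheme$categories,
            paste0("unknown regime category: ", record$regime))
  idx <- record$lockdownIndex
  stopIfNot(is.numeric(idx) && idx >= 0 && idx <= scheme$indexScale,
            "lockdownIndex outside the scheme scale")
  stopIfNot(record$maskMandate %in% c(0, 1), "maskMandate must be binary")
  oneHot <- as.numeric(
    setdiff(scheme$categories, scheme$reference) == record$regime)
  setNames(c(idx / scheme$indexScale, as.numeric(record$maskMandate), oneHot),
           scheme$layout)
}

#' Mask policy cells at random
#'
#' Masks each region-time cell (the whole r-vector) independently with the
#' given probability, recording the mask; masked values are retained
#' internally for audit but must be treated as unobserved.
#'
#' @param series a [PolicySeries-class].
#' @param rate masking probability in \[0, 1\].
#' @param seed integer seed.
#' @return A [PolicySeries-class] with an updated missingness mask.
#' @export
maskPolicySeries <- function(series, rate, seed = 1L) {
  stopIfNot(is.numeric(rate) && rate >= 0 && rate <= 1,
            "rate must lie in [0, 1]")
  d <- dim(seriesValues(series))
  withSeed(seed, {
    drop <- matrix(runif(d[1L] * d[2L]) < rate, d[1L], d[2L])
    out <- series
    out@missingMask <- series@missingMask | drop
    out
  })
}

#' Fit the auxiliary policy encoder for learned imputation
#'
#' A linear auxiliary encoder that reconstructs the encoded policy vector of
#' a region-time cell from the region identity and the concurrent and
#' previous region summaries, fitted by ridge regression on the observed
#' cells of a training split. Because policy regimes move the summary
#' stream, the summaries carry enough signal to recover masked vectors
#' better than zero substitution.
#'
#' @param policy training [PolicySeries-class].
#' @param summary training [SummarySeries-class] aligned with `policy`.
#' @param lambda ridge penalty.
#' @return object of class `policyEncoder`.
#' @export
fitPolicyEncoder <- function(policy, summary, lambda = 1e-3) {
  P <- seriesValues(policy)
  Z <- seriesValues(summary)
  d <- dim(P)
  stopIfNot(all(dim(Z)[1:2] == d[1:2]),
            "policy and summary series must align")
  X <- encoderFeatures(Z, d[2L])
  obs <- which(!policy@missingMask)
  stopIfNot(length(obs) > 0L, "no observed policy cells to fit on")
  Xo <- X[obs, , drop = FALSE]
  Yo <- matrix(P, d[1L] * d[2L], d[3L])[obs, , drop = FALSE]
  XtX <- crossprod(Xo) + lambda * diag(ncol(Xo))
  W <- solve(XtX, crossprod(Xo, Yo))
  structure(list(W = W, r = d[3L], M = d[2L]), class = "policyEncoder")
}

# feature matrix for the auxiliary encoder: intercept, region one-hot,
# current and previous summaries, cell index (T*M) x p
encoderFeatures <- function(Z, M) {
  d <- dim(Z)
  T <- d[1L]
  Zprev <- Z[c(1L, seq_len(T - 1L)), , , drop = FALSE]
  reg <- matrix(0, T * M, M)
  cellRegion <- rep(seq_len(M), each = T)
  reg[cbind(seq_len(T * M), cellRegion)] <- 1
  cbind(1, reg,
        matrix(Z, T * M, d[3L]),
        matrix(Zprev, T * M, d[3L]))
}

#' Impute masked policy cells
#'
#' Fills every masked cell according to the chosen strategy and returns the
#' series with its mask retained for audit. Observed cells are never
#' modified.
#'
#' * `zero`: masked vectors replaced by zero vectors.
#' * `mean`: per-component means of the observed cells of a reference
#'   (training) series.
#' * `carry_forward`: last observed vector of the same region, zero before
#'   the first observation.
#' * `learned`: predictions of a fitted auxiliary encoder
#'   ([fitPolicyEncoder()]); requires the aligned summary series.
#'
#' @param series a [PolicySeries-class].
#' @param strategy one of `zero`, `mean`, `carry_forward`, `learned`.
#' @param reference training [PolicySeries-class] (for `mean`).
#' @param encoder fitted `policyEncoder` (for `learned`).
#' @param summary aligned [SummarySeries-class] (for `learned`).
#' @return A [PolicySeries-class] with masked cells filled.
#' @export
imputePolicySeries <- function(series,
                               strategy = c("zero", "mean", "carry_forward",
                                            "learned"),
                               reference = NULL, encoder = NULL,
                               summary = NULL) {
  strategy <- match.arg(strategy)
  P <- seriesValues(series)
  mask <- missingMask(series)
  d <- dim(P)
  out <- series
  if (!any(mask)) return(out)
  fill <- switch(strategy,
    zero = function(t, j) rep(0, d[3L]),
    mean = {
      stopIfNot(!is.null(reference),
                "mean imputation needs a reference training series")
      Pref <- seriesValues(reference)
      obsRef <- which(!missingMask(reference))
      mu <- vapply(seq_len(d[3L]), function(cc)
        mean(matrix(Pref[, , cc], ncol = 1L)[obsRef]), numeric(1L))
      function(t, j) mu
    },
    carry_forward = NULL,
    learned = {
      if (is.null(encoder) || !inherits(encoder, "policyEncoder"))
        stop("learned imputation needs a fitted auxiliary encoder",
             call. = FALSE)
      stopIfNot(!is.null(summary),
                "learned imputation needs the aligned summary series")
      X <- encoderFeatures(seriesValues(summary), d[2L])
      pred <- X %*% encoder$W
      pred[, 1L] <- pmin(pmax(pred[, 1L], 0), 1)  # stringency in [0,1]
      pred[, -1L] <- pmin(pmax(pred[, -1L], 0), 1)
      function(t, j) pred[(j - 1L) * d[1L] + t, ]
    })
  if (strategy == "carry_forward") {
    for (j in seq_len(d[2L])) {
      last <- rep(0, d[3L])
      for (t in seq_len(d[1L])) {
        if (mask[t, j]) P[t, j, ] <- last else last <- P[t, j, ]
      }
    }
  } else {
    idx <- which(mask, arr.ind = TRUE)
    for (rr in seq_len(nrow(idx))) {
      P[idx[rr, 1L], idx[rr, 2L], ] <- fill(idx[rr, 1L], idx[rr, 2L])
    }
  }
  out@values <- P
  out
}
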