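#' Burst-suppression ratio of a segment
#'
#' BSR is the fraction of segment time occupied by burst signal: the total
#' burst duration from [detectBursts()] divided by the total envelope
#' duration. Note the convention used here: higher BSR = more burst activity
#' = better recovery (many clinical papers define the inverse).
#'
#' @param seg an unflagged [EEGSegment-class] (or an [EnvelopeTrace-class]).
#' @param thresholdUv burst threshold, uV.
#' @return BSR in \[0, 1\]; `NA` for artifact-flagged segments.
#' @export
computeBSR <- function(seg, thresholdUv = 10) {
  if (is(seg, "EEGSegment")) {
    if (seg@artifactFlag) return(NA_real_)
    env <- computeEnvelope(seg)
  } else env <- seg
  bursts <- detectBursts(env, thresholdUv = thresholdUv)
  tot <- length(env@values) * env@hopS
  if (!nrow(bursts)) return(0)
  min(sum(bursts$endS - bursts$startS) / tot, 1)
}

#' Weighted-permutation entropy
#'
#' Embeds the series with dimension `m` and delay `tau`; each embedded vector
#' contributes its ordinal pattern (rank tuple, ties broken by index order)
#' weighted by the vector's variance (population form, i.e. mean squared
#' deviation). The entropy of the weighted pattern distribution is normalized
#' by `log(m!)`, so the result lies in \[0, 1\]: 0 for a monotone ramp
#' (single pattern), 1 in the white-noise limit. A constant series (all
#' weights zero) is defined as 0. The statistic is invariant under global
#' positive scaling of the series.
#'
#' @param series numeric vector (length should be much larger than `m!`).
#' @param m embedding dimension (>= 2).
#' @param tau embedding delay in samples (>= 1).
#' @return Normalized WPE in \[0, 1\].
#' @export
computeWPE <- function(series, m = 5, tau = 1) {
  stopifnot(m >= 2, tau >= 1)
  n <- length(series) - (m - 1) * tau
  if (n < 1) stop("series too short for the requested embedding")
  emb <- vapply(seq_len(m), function(j) series[(j - 1) * tau + seq_len(n)],
                numeric(n))
  # rank of column i within each row, ties broken by column (index) order
  ranks <- matrix(0L, n, m)
  for (i in seq_len(m)) {
    ri <- integer(n)
    for (j in seq_len(m)) {
      if (j == i) next
      ri <- ri + (emb[, j] < emb[, i]) + (emb[, j] == emb[, i] & j < i)
    }
    ranks[, i] <- ri
  }
  key <- as.vector(ranks %*% m^(seq_len(m) - 1))
  mu <- rowMeans(emb)
  w <- rowMeans((emb - mu)^2)     # population variance weight
  tw <- sum(w)
  if (tw <= 0) return(0)
  pw <- rowsum(w, key)
  pw <- pw[pw > 0] / tw
  -sum(pw * log(pw)) / log(factorial(m))
}

#' Per-segment WPE (channel mean)
#'
#' @param seg an [EEGSegment-class].
#' @param m,tau embedding parameters, see [computeWPE()].
#' @return Mean of the two channels' WPE; `NA` for flagged segments.
#' @export
computeSegmentWPE <- function(seg, m = 5, tau = 1) {
  if (seg@artifactFlag) return(NA_real_)
  mean(apply(seg@samples, 2, computeWPE, m = m, tau = tau))
}

#' Time-weighted average of a feature trajectory
#'
#' Trapezoidal integral of the feature over the post-ROSC schedule divided by
#' the spanned duration (last minus first timepoint) — the epidemiological
#' time-weighted-exposure form. Flagged/missing values are dropped before
#' integration. With equally spaced timepoints this reduces to the mean of
#' the interior points plus half-weighted endpoints.
#'
#' @param timepointsMin schedule timepoints, minutes.
#' @param values feature values (NA = flagged/missing).
#' @return The TWA, or `NA` (with a warning) when fewer than two valid
#'   points remain.
#' @export
computeTWA <- function(timepointsMin, values) {
  ok <- is.finite(values) & is.finite(timepointsMin)
  t <- timepointsMin[ok]; v <- values[ok]
  o <- order(t); t <- t[o]; v <- v[o]
  if (length(t) < 2) {
    warning("fewer than two valid points; TWA undefined")
    return(NA_real_)
  }
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2) / (t[length(t)] - t[1])
}

#' Per-segment feature table for one animal
#'
#' Computes BSR and WPE for each scheduled segment plus the optional baseline
#' segment, and the time-weighted averages over the post-ROSC schedule
#' (the baseline is excluded from TWA).
#'
#' @param segments list of [EEGSegment-class] from [extractSegments()].
#' @param baseline optional baseline [EEGSegment-class].
#' @param m,tau WPE embedding parameters.
#' @param animalId identifier recorded in the table.
#' @return A list with `features` (data.frame: `animalId`, `timepointMin`
#'   (`NA` = baseline), `bsr`, `wpe`, `artifactFlag`), `twaBsr`, `twaWpe`,
#'   `nSegmentsUsed`.
#' @export
segmentFeatures <- function(segments, baseline = NULL, m = 5, tau = 1,
                            animalId = NA_character_) {
  all <- c(if (!is.null(baseline)) list(baseline), segments)
  feat <- data.frame(
    animalId = animalId,
    timepointMin = vapply(all, timepointMin, numeric(1)),
    bsr = vapply(all, computeBSR, numeric(1)),
    wpe = vapply(all, computeSegmentWPE, numeric(1), m = m, tau = tau),
    artifactFlag = vapply(all, artifactFlag, logical(1))
  )
  post <- !is.na(feat$timepointMin)
  twaBsr <- computeTWA(feat$timepointMin[post], feat$bsr[post])
  twaWpe <- computeTWA(feat$timepointMin[post], feat$wpe[post])
  list(features = feat, twaBsr = twaBsr, twaWpe = twaWpe,
       nSegmentsUsed = sum(post & !feat$artifactFlag))
}
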