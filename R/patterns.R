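#' Amplitude envelope of a recording or segment
#'
#' Computes the half peak-to-peak amplitude per short window for each channel
#' and combines channels by the per-window minimum, so that "amplitude above
#' x uV in both channels" annotation rules become single comparisons against
#' the combined trace. The window is two hops long; with the default nominal
#' 0.5 s window / 0.25 s hop the hop is `floor(fs / 4)` samples, so durations
#' are exact in sample units at any rate.
#'
#' @param x an [EEGRecording-class], [EEGSegment-class], or numeric matrix.
#' @param fs sampling rate (matrix input only).
#' @param windowS nominal window length, seconds.
#' @return An [EnvelopeTrace-class] with
#'   `floor((nSamples - window) / hop) + 1` windows.
#' @export
computeEnvelope <- function(x, fs = NULL, windowS = 0.5) {
  m <- if (is(x, "EEGRecording") || is(x, "EEGSegment")) x@samples else x
  if (is.null(fs))
    fs <- if (is(x, "EEGRecording") || is(x, "EEGSegment")) x@fs else
      stop("fs required for matrix input")
  hop <- floor(windowS * fs / 2)
  win <- 2L * hop
  n <- nrow(m)
  if (n < win) stop("signal shorter than one envelope window")
  nb <- floor(n / hop)
  perCh <- vapply(seq_len(ncol(m)), function(ch) {
    b <- matrix(m[seq_len(nb * hop), ch], nrow = hop)
    bmax <- apply(b, 2, max)
    bmin <- apply(b, 2, min)
    wmax <- pmax(bmax[-nb], bmax[-1L])
    wmin <- pmin(bmin[-nb], bmin[-1L])
    (wmax - wmin) / 2
  }, numeric(nb - 1L))
  keep <- seq_len(floor((n - win) / hop) + 1L)
  perCh <- perCh[keep, , drop = FALSE]
  new("EnvelopeTrace", values = as.numeric(do.call(pmin, asplit(perCh, 2))),
      perChannel = perCh, hopS = hop / fs, windowS = win / fs, fs = fs)
}

#' Detect burst events on an envelope trace
#'
#' A burst is a maximal run of combined-envelope windows above
#' `thresholdUv` lasting at least `minBurstS`; suppression gaps shorter than
#' `minGapS` (the minimum inter-burst suppression duration) are merged into
#' the surrounding burst. Each envelope window contributes one hop of
#' duration, so a k-window run lasts `k * hop` seconds.
#'
#' @param env an [EnvelopeTrace-class].
#' @param thresholdUv burst amplitude threshold, uV.
#' @param minBurstS minimum burst duration, s.
#' @param minGapS minimum suppression duration between distinct bursts, s.
#' @return data.frame with columns `startS`, `endS` (sorted, non-overlapping).
#' @export
detectBursts <- function(env, thresholdUv = 10, minBurstS = 0.1,
                         minGapS = 0.5) {
  hop <- env@hopS
  high <- env@values > thresholdUv
  if (!any(high))
    return(data.frame(startS = numeric(0), endS = numeric(0)))
  r <- rle(high)
  # merge interior low runs shorter than minGapS into the surrounding burst
  if (length(r$lengths) > 2L) {
    interior <- seq_along(r$values)[-c(1L, length(r$values))]
    shortGap <- !r$values[interior] & r$lengths[interior] * hop < minGapS
    if (any(shortGap)) {
      high2 <- inverse.rle(r)
      idx <- cumsum(r$lengths)
      for (i in interior[shortGap])
        high2[(idx[i - 1L] + 1L):idx[i]] <- TRUE
      r <- rle(high2)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * hop >= minBurstS
  data.frame(startS = (starts[keep] - 1L) * hop,
             endS = (starts[keep] - 1L + r$lengths[keep]) * hop)
}

# run table of envelope windows below `thr`, as (startS, endS) using the
# one-hop-per-window duration convention
.lowRuns <- function(values, hop, thr) {
  low <- values < thr
  if (!any(low)) return(data.frame(startS = numeric(0), endS = numeric(0)))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(startS = (starts[r$values] - 1L) * hop,
             endS = ends[r$values] * hop)
}

#' Classify the three-pattern recovery timeline
#'
#' Rolls a 60-second window (10-second hop) over the combined envelope and
#' labels each window: `continuous` when the window maximum exceeds
#' `burstThresholdUv` while the 5th-percentile envelope exceeds
#' `contFloorUv`; `isoelectric` when the envelope stays below `isoThresholdUv`
#' for at least 30 consecutive seconds within the window and the window
#' contains no burst; otherwise `burst_suppression` when at least one burst
#' overlaps the window. Windows matching none of the rules (sustained 5-10 uV
#' activity without bursts) fall back to the isoelectric/suppression label.
#' Adjacent same-label windows are merged.
#'
#' Because a 60-second window straddling a transition already contains
#' evidence of the next pattern, raw window labels place onsets up to one
#' window early; with `refine = TRUE` (default) the isoelectric-to-burst-
#' suppression boundary is snapped to the first detected burst onset near the
#' coarse boundary, and the boundary into `continuous` is snapped to the end
#' of the last sub-`burstThresholdUv` envelope excursion within +/- 70 s.
#'
#' Envelope windows above `artifactMaskUv` (injected artifacts) are replaced
#' by interpolation between their neighbours before classification.
#'
#' @param env an [EnvelopeTrace-class] spanning at least 60 s.
#' @param isoThresholdUv "no visible activity" threshold, uV.
#' @param burstThresholdUv burst threshold, uV.
#' @param contFloorUv continuous-background amplitude floor, uV.
#' @param windowS,hopS classification window and hop, seconds.
#' @param refine logical; apply sub-window boundary refinement.
#' @param artifactMaskUv envelope mask threshold, uV.
#' @param animalId identifier stored in the timeline.
#' @return A [PatternTimeline-class] partitioning `[0, duration]`.
#' @export
classifyTimeline <- function(env, isoThresholdUv = 5, burstThresholdUv = 10,
                             contFloorUv = 5, windowS = 60, hopS = 10,
                             refine = TRUE, artifactMaskUv = 500,
                             animalId = NA_character_) {
  hop <- env@hopS
  v <- env@values
  totS <- length(v) * hop
  if (totS < windowS) stop("envelope must span at least one 60 s window")

  # mask artifact excursions by linear interpolation
  bad <- v > artifactMaskUv
  if (all(bad)) {
    warning("all-artifact envelope; returning empty timeline")
    return(new("PatternTimeline",
               intervals = data.frame(label = character(),
                                      startMin = numeric(),
                                      endMin = numeric()),
               durationMin = totS / 60, animalId = as.character(animalId)))
  }
  if (any(bad)) {
    # dilate the mask so partially-overlapping edge windows are covered too
    pad <- ceiling(env@windowS / hop)
    bi <- which(bad)
    bad[unique(pmin(pmax(rep(bi, each = 2 * pad + 1) +
                           (-pad):pad, 1L), length(v)))] <- TRUE
    idx <- seq_along(v)
    v[bad] <- approx(idx[!bad], v[!bad], xout = idx[bad], rule = 2)$y
  }

  envM <- EnvelopeTrace(v, hopS = hop, windowS = env@windowS, fs = env@fs)
  bursts <- detectBursts(envM, thresholdUv = burstThresholdUv)
  isoRuns <- .lowRuns(v, hop, isoThresholdUv)

  wStarts <- seq(0, totS - windowS, by = hopS)
  labs <- vapply(wStarts, function(t0) {
    t1 <- t0 + windowS
    i0 <- floor(t0 / hop) + 1L
    i1 <- min(length(v), ceiling(t1 / hop))
    w <- v[i0:i1]
    hasBurst <- nrow(bursts) > 0 &&
      any(bursts$startS < t1 & bursts$endS > t0)
    if (max(w) > burstThresholdUv &&
        quantile(w, 0.05, names = FALSE) > contFloorUv)
      return("continuous")
    isoOverlap <- nrow(isoRuns) > 0 &&
      any(pmin(isoRuns$endS, t1) - pmax(isoRuns$startS, t0) >= 30)
    if (isoOverlap && !hasBurst) return("isoelectric")
    if (hasBurst) return("burst_suppression")
    "isoelectric"
  }, character(1))

  # merge adjacent same-label windows into intervals over [0, totS]
  r <- rle(labs)
  k <- length(r$lengths)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  startS <- wStarts[startIdx]
  endS <- c(wStarts[startIdx[-1L]], totS)
  lab <- r$values

  if (refine && k > 1L) {
    for (i in 2:k) {
      b <- startS[i]
      lo <- max(startS[i - 1L], b - 70)
      hi <- min(endS[i], b + 70)
      newB <- b
      if (lab[i] == "burst_suppression" && nrow(bursts)) {
        cand <- bursts$startS[bursts$startS >= lo & bursts$startS <= hi]
        if (length(cand)) newB <- cand[1L]
      } else if (lab[i] == "continuous") {
        i0 <- max(1L, floor(lo / hop) + 1L)
        i1 <- min(length(v), ceiling(hi / hop))
        sub <- which(v[i0:i1] <= burstThresholdUv)
        if (length(sub)) newB <- (i0 - 1L + max(sub)) * hop
      }
      startS[i] <- min(max(newB, startS[i - 1L] + hop), endS[i] - hop)
      endS[i - 1L] <- startS[i]
    }
  }

  # drop zero-length intervals and re-merge identical neighbours
  keep <- endS - startS > 1e-9
  lab <- lab[keep]; startS <- startS[keep]; endS <- endS[keep]
  if (length(lab) > 1L) {
    j <- 1L
    for (i in 2:length(lab)) {
      if (lab[i] == lab[j]) {
        endS[j] <- endS[i]
      } else {
        j <- j + 1L
        lab[j] <- lab[i]; startS[j] <- startS[i]; endS[j] <- endS[i]
      }
    }
    lab <- lab[1:j]; startS <- startS[1:j]; endS <- endS[1:j]
  }
  PatternTimeline(lab, startS / 60, endS / 60, animalId = animalId)
}

#' Onset time of burst (OTOB) and time to normal trace (TTNT)
#'
#' OTOB is the time from ROSC to the first burst-suppression interval (or to
#' the first continuous interval when the recording jumps straight from
#' isoelectric to continuous); TTNT is the time from ROSC to the first
#' continuous interval. Recordings that never reach the continuous pattern
#' are censored at the recording duration.
#'
#' @param tl a [PatternTimeline-class] starting at ROSC (t = 0).
#' @param durationMin recording duration (defaults to the timeline's span).
#' @return A list with `otobMin`, `ttntMin`, `ttntCensored`.
#' @export
computeOtobTtnt <- function(tl, durationMin = NULL) {
  iv <- tl@intervals
  if (!nrow(iv)) stop("timeline has no intervals")
  if (is.null(durationMin)) durationMin <- tl@durationMin
  firstBs <- match("burst_suppression", iv$label)
  firstCont <- match("continuous", iv$label)
  if (is.na(firstCont)) {
    ttnt <- durationMin; cens <- TRUE
  } else {
    ttnt <- iv$startMin[firstCont]; cens <- FALSE
  }
  otob <- if (!is.na(firstBs) && (is.na(firstCont) || firstBs < firstCont))
    iv$startMin[firstBs] else ttnt
  list(otobMin = otob, ttntMin = ttnt, ttntCensored = cens)
}

#' Write a timeline as BED-like tab-separated intervals
#'
#' Columns: animal_id, start_s, end_s, label.
#'
#' @param tl a [PatternTimeline-class].
#' @param path output file; use `append = TRUE` to accumulate a cohort file.
#' @param append logical.
#' @return The path, invisibly.
#' @export
writeTimelineBed <- function(tl, path, append = FALSE) {
  iv <- tl@intervals
  df <- data.frame(animal_id = tl@animalId,
                   start_s = iv$startMin * 60,
                   end_s = iv$endMin * 60,
                   label = iv$label)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = !append, quote = FALSE, append = append)
  invisible(path)
}
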