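#' Preprocessing filter parameters
#'
#' Band-pass plus mains-notch filtering parameters. Defaults follow the
#' standard quantitative-EEG preprocessing for this model: 0.3-100 Hz
#' band-pass to remove offset and high-frequency noise, and a 50 Hz notch
#' against power-line interference. The band-pass is a 4th-order Butterworth
#' applied forward-backward (zero phase); the notch is a second-order IIR of
#' quality 30, also applied forward-backward.
#'
#' @param bandpassLo,bandpassHi band edges, Hz.
#' @param notchFreq notch centre frequency, Hz.
#' @param filterOrder Butterworth order of the band-pass.
#' @param notchQuality notch quality factor (centre frequency / -3 dB width).
#' @return A list of class `qeegFilterParams`.
#' @export
filterParams <- function(bandpassLo = 0.3, bandpassHi = 100,
                         notchFreq = 50, filterOrder = 4,
                         notchQuality = 30) {
  stopifnot(bandpassLo > 0, bandpassLo < bandpassHi, notchQuality > 0)
  p <- list(bandpassLo = bandpassLo, bandpassHi = bandpassHi,
            notchFreq = notchFreq, filterOrder = filterOrder,
            notchQuality = notchQuality)
  class(p) <- "qeegFilterParams"
  p
}

# Second-order IIR notch (biquad) coefficients.
.notchCoef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

.filterMatrix <- function(m, fs, p) {
  if (p$bandpassHi >= fs / 2)
    stop("bandpassHi must be below the Nyquist frequency fs/2")
  if (p$notchFreq >= fs / 2)
    stop("notchFreq must be below the Nyquist frequency fs/2")
  bp <- signal::butter(p$filterOrder,
                       c(p$bandpassLo, p$bandpassHi) / (fs / 2), "pass")
  nc <- .notchCoef(p$notchFreq, fs, p$notchQuality)
  apply(m, 2, function(x) {
    y <- signal::filtfilt(bp, x)
    signal::filtfilt(nc$b, nc$a, y)
  })
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies the band-pass then the notch to each channel, forward-backward
#' (zero phase). Output length equals input length; the DC component is
#' removed by the band-pass high-pass edge.
#'
#' @param x an [EEGRecording-class] or [EEGSegment-class].
#' @param p a [filterParams()].
#' @return An object of the same class with filtered samples.
#' @export
setGeneric("filterRecording", function(x, p = filterParams())
  standardGeneric("filterRecording"))

#' @rdname filterRecording
#' @export
setMethod("filterRecording", "EEGRecording", function(x, p = filterParams()) {
  EEGRecording(.filterMatrix(x@samples, x@fs, p), fs = x@fs,
               t0Min = x@t0Min, animalId = x@animalId)
})

#' @rdname filterRecording
#' @export
setMethod("filterRecording", "EEGSegment", function(x, p = filterParams()) {
  EEGSegment(.filterMatrix(x@samples, x@fs, p), fs = x@fs,
             timepointMin = x@timepointMin, artifactFlag = x@artifactFlag)
})

#' Artifact screen for a one-minute segment
#'
#' Flags a segment as artifact-contaminated if any sample exceeds
#' `ampThresholdUv` in magnitude (amplifier-range / movement artifact) or if
#' a channel is exactly constant for at least `flatlineS` seconds
#' (clipping / lead-off flatline proxy).
#'
#' @param seg an [EEGSegment-class] or a numeric sample matrix.
#' @param fs sampling rate (needed only when `seg` is a matrix).
#' @param ampThresholdUv amplitude threshold, uV.
#' @param flatlineS minimum duration of an exactly-constant run, seconds.
#' @return Logical scalar.
#' @export
detectArtifact <- function(seg, fs = NULL, ampThresholdUv = 1000,
                           flatlineS = 1) {
  m <- if (is(seg, "EEGSegment")) seg@samples else seg
  if (is.null(fs)) fs <- if (is(seg, "EEGSegment")) seg@fs else
    stop("fs required for matrix input")
  if (any(abs(m) > ampThresholdUv)) return(TRUE)
  nFlat <- round(flatlineS * fs)
  for (ch in seq_len(ncol(m))) {
    d <- diff(m[, ch]) == 0
    if (any(d)) {
      r <- rle(d)
      if (any(r$lengths[r$values] >= nFlat - 1L)) return(TRUE)
    }
  }
  FALSE
}

#' Extract the scheduled one-minute analysis segments
#'
#' Extracts one 60-second, two-channel segment per schedule point
#' (`[t, t + 60 s]`; the last point of a recording that ends exactly at a
#' schedule point uses the final recording minute). Segments overlapping
#' artifacts may slide by up to `slideS` seconds (in 5-second steps,
#' preferring the smallest shift) to find an artifact-free minute; if none is
#' found the segment at the nominal position is returned flagged.
#'
#' @param rec a filtered [EEGRecording-class] with ROSC-relative clock.
#' @param scheduleMin schedule points, minutes post-ROSC (default 5, 30, 60,
#'   ..., up to the recording duration).
#' @param slideS maximum slide when searching for an artifact-free minute, s.
#' @param ampThresholdUv,flatlineS forwarded to [detectArtifact()].
#' @return A list of [EEGSegment-class] (empty, with a warning, if the
#'   recording is shorter than the first schedule point plus one minute).
#' @export
extractSegments <- function(rec, scheduleMin = NULL, slideS = 60,
                            ampThresholdUv = 1000, flatlineS = 1) {
  fs <- rec@fs
  durMin <- durationMin(rec) + rec@t0Min
  if (is.null(scheduleMin)) scheduleMin <- defaultScheduleMin(durMin)
  scheduleMin <- scheduleMin[scheduleMin <= durMin]
  feasible <- scheduleMin[pmin(scheduleMin + 1, durMin) * 60 - 60 >=
                            rec@t0Min * 60 - 1e-9]
  if (!length(feasible)) {
    warning("recording shorter than the first schedule point; no segments")
    return(list())
  }
  n <- nrow(rec@samples)
  segAt <- function(startS) {
    i0 <- round((startS - rec@t0Min * 60) * fs) + 1L
    i1 <- i0 + round(60 * fs) - 1L
    if (i0 < 1L || i1 > n) return(NULL)
    rec@samples[i0:i1, , drop = FALSE]
  }
  lapply(feasible, function(tp) {
    nominal <- min(tp * 60, durMin * 60 - 60)
    offsets <- c(0, as.vector(rbind(seq(5, slideS, 5), -seq(5, slideS, 5))))
    for (off in offsets) {
      m <- segAt(nominal + off)
      if (is.null(m)) next
      if (!detectArtifact(m, fs, ampThresholdUv, flatlineS))
        return(EEGSegment(m, fs = fs, timepointMin = tp, artifactFlag = FALSE))
    }
    EEGSegment(segAt(nominal), fs = fs, timepointMin = tp, artifactFlag = TRUE)
  })
}
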