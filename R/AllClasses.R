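#' Two-channel EEG recording
#'
#' Container for a two-channel post-ROSC EEG recording. Samples are stored as
#' an n-by-2 numeric matrix in microvolts (columns `EEG-L`, `EEG-R`), together
#' with the sampling rate and the recording start time on the ROSC-relative
#' clock (`t0 = 0` means the recording starts at restoration of spontaneous
#' circulation).
#'
#' @slot samples numeric matrix, one column per channel, amplitudes in uV.
#' @slot fs sampling rate in Hz.
#' @slot t0Min recording start, minutes post-ROSC.
#' @slot animalId character scalar identifier.
#'
#' @export
setClass("EEGRecording",
  representation(
    samples  = "matrix",
    fs       = "numeric",
    t0Min    = "numeric",
    animalId = "character"
  ),
  prototype(t0Min = 0, animalId = NA_character_)
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (ncol(object@samples) != 2L)
    msg <- c(msg, "samples must have exactly two channels (columns)")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' One-minute analysis segment
#'
#' A scheduled one-minute, two-channel segment of filtered EEG extracted at a
#' ROSC-relative timepoint, carrying an artifact flag. The `timepointMin` slot
#' is `NA` for the designated pre-arrest baseline segment.
#'
#' @slot samples numeric matrix (60 * fs rows, 2 columns), uV.
#' @slot fs sampling rate in Hz.
#' @slot timepointMin scheduled timepoint in minutes post-ROSC (NA = baseline).
#' @slot artifactFlag logical; TRUE if no artifact-free minute was found.
#'
#' @export
setClass("EEGSegment",
  representation(
    samples      = "matrix",
    fs           = "numeric",
    timepointMin = "numeric",
    artifactFlag = "logical"
  ),
  prototype(artifactFlag = FALSE, timepointMin = NA_real_)
)

setValidity("EEGSegment", function(object) {
  msg <- character()
  if (ncol(object@samples) != 2L)
    msg <- c(msg, "segment must have exactly two channels")
  if (nrow(object@samples) != round(60 * object@fs))
    msg <- c(msg, "segment must contain exactly 60 * fs samples per channel")
  if (length(msg)) msg else TRUE
})

#' Amplitude envelope trace
#'
#' Half peak-to-peak amplitude per short analysis window, per channel, plus
#' the combined trace (per-window minimum across channels, so that
#' "amplitude > x uV in both channels" rules become single comparisons).
#' Window length is two hops; window k covers samples starting at k * hop.
#'
#' @slot values combined (cross-channel minimum) envelope, uV.
#' @slot perChannel matrix of per-channel envelopes (windows x channels), uV.
#' @slot hopS hop between window starts, seconds.
#' @slot windowS window length, seconds.
#' @slot fs sampling rate of the underlying signal, Hz.
#'
#' @export
setClass("EnvelopeTrace",
  representation(
    values     = "numeric",
    perChannel = "matrix",
    hopS       = "numeric",
    windowS    = "numeric",
    fs         = "numeric"
  )
)

setValidity("EnvelopeTrace", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "envelope values must be non-negative")
  if (object@hopS <= 0 || object@windowS <= 0)
    msg <- c(msg, "hop and window must be positive")
  if (length(msg)) msg else TRUE
})

#' Pattern timeline
#'
#' Ordered, non-overlapping labelled intervals partitioning a recording into
#' the three post-resuscitation EEG recovery patterns: `isoelectric`,
#' `burst_suppression` and `continuous`. Times are minutes post-ROSC.
#'
#' @slot intervals data.frame with columns `label`, `startMin`, `endMin`.
#' @slot durationMin total spanned duration in minutes.
#' @slot animalId character scalar identifier.
#'
#' @export
setClass("PatternTimeline",
  representation(
    intervals   = "data.frame",
    durationMin = "numeric",
    animalId    = "character"
  ),
  prototype(animalId = NA_character_)
)

.patternLabels <- c("isoelectric", "burst_suppression", "continuous")

setValidity("PatternTimeline", function(object) {
  iv <- object@intervals
  msg <- character()
  need <- c("label", "startMin", "endMin")
  if (!all(need %in% names(iv)))
    return("intervals must have columns label, startMin, endMin")
  if (nrow(iv)) {
    if (!all(iv$label %in% .patternLabels))
      msg <- c(msg, "unknown pattern label")
    if (any(iv$endMin <= iv$startMin))
      msg <- c(msg, "intervals must have positive length")
    if (nrow(iv) > 1L) {
      if (any(abs(iv$startMin[-1L] - iv$endMin[-nrow(iv)]) > 1e-9))
        msg <- c(msg, "intervals must tile the recording without gaps/overlaps")
      if (any(iv$label[-1L] == iv$label[-nrow(iv)]))
        msg <- c(msg, "adjacent intervals must not share a label")
    }
    if (abs(iv$startMin[1L]) > 1e-9 ||
        abs(iv$endMin[nrow(iv)] - object@durationMin) > 1e-9)
      msg <- c(msg, "intervals must span [0, durationMin]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s': 2 x %d samples @ %g Hz (%.1f min, t0 = %g min post-ROSC)\n",
    object@animalId, nrow(object@samples), object@fs,
    nrow(object@samples) / object@fs / 60, object@t0Min
  ))
})

setMethod("show", "EEGSegment", function(object) {
  tp <- if (is.na(object@timepointMin)) "baseline" else
    sprintf("%g min", object@timepointMin)
  cat(sprintf(
    "EEGSegment at %s: 2 x %d samples @ %g Hz%s\n",
    tp, nrow(object@samples), object@fs,
    if (object@artifactFlag) " [ARTIFACT]" else ""
  ))
})

setMethod("show", "EnvelopeTrace", function(object) {
  cat(sprintf(
    "EnvelopeTrace: %d windows (%.3g s window, %.3g s hop), range %.2f-%.2f uV\n",
    length(object@values), object@windowS, object@hopS,
    min(object@values), max(object@values)
  ))
})

setMethod("show", "PatternTimeline", function(object) {
  cat(sprintf("PatternTimeline '%s' over %g min:\n",
              object@animalId, object@durationMin))
  iv <- object@intervals
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv)))
      cat(sprintf("  [%7.2f - %7.2f] %s\n",
                  iv$startMin[i], iv$endMin[i], iv$label[i]))
  } else cat("  (empty)\n")
})
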