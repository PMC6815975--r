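#' Construct an EEGRecording
#'
#' @param samples numeric matrix (samples x 2 channels), uV.
#' @param fs sampling rate, Hz.
#' @param t0Min recording start in minutes post-ROSC.
#' @param animalId identifier.
#' @return An [EEGRecording-class].
#' @export
EEGRecording <- function(samples, fs, t0Min = 0, animalId = NA_character_) {
  colnames(samples) <- c("EEG-L", "EEG-R")
  new("EEGRecording", samples = samples, fs = fs, t0Min = t0Min,
      animalId = as.character(animalId))
}

#' Construct an EEGSegment
#'
#' @param samples numeric matrix (60 * fs rows, 2 channels), uV.
#' @param fs sampling rate, Hz.
#' @param timepointMin scheduled timepoint (min post-ROSC); NA for baseline.
#' @param artifactFlag logical artifact flag.
#' @return An [EEGSegment-class].
#' @export
EEGSegment <- function(samples, fs, timepointMin = NA_real_,
                       artifactFlag = FALSE) {
  new("EEGSegment", samples = samples, fs = fs,
      timepointMin = timepointMin, artifactFlag = artifactFlag)
}

#' Construct an EnvelopeTrace directly from values
#'
#' Mostly useful for testing burst detection against hand-built envelopes;
#' analysis code normally obtains traces from [computeEnvelope()].
#'
#' @param values combined envelope values, uV.
#' @param hopS hop in seconds.
#' @param windowS window length in seconds (default two hops).
#' @param perChannel optional per-channel matrix; defaults to `values` in both.
#' @param fs underlying sampling rate (informational).
#' @return An [EnvelopeTrace-class].
#' @export
EnvelopeTrace <- function(values, hopS, windowS = 2 * hopS,
                          perChannel = cbind(values, values), fs = NA_real_) {
  new("EnvelopeTrace", values = as.numeric(values), perChannel = perChannel,
      hopS = hopS, windowS = windowS, fs = fs)
}

#' Construct a PatternTimeline
#'
#' @param labels character vector of pattern labels
#'   (`isoelectric`, `burst_suppression`, `continuous`).
#' @param startMin,endMin interval bounds in minutes post-ROSC.
#' @param animalId identifier.
#' @return A [PatternTimeline-class].
#' @export
PatternTimeline <- function(labels, startMin, endMin,
                            animalId = NA_character_) {
  iv <- data.frame(label = as.character(labels), startMin = startMin,
                   endMin = endMin, stringsAsFactors = FALSE)
  dur <- if (nrow(iv)) iv$endMin[nrow(iv)] else 0
  new("PatternTimeline", intervals = iv, durationMin = dur,
      animalId = as.character(animalId))
}

# --- distribution fitting ----------------------------------------------------

#' Fit a three-parameter (shifted, possibly reflected) log-normal to quartiles
#'
#' Matches the first quartile, median and third quartile exactly. Right-skewed
#' quartiles (q3 - m > m - q1) give a shifted log-normal
#' X = shift + LN(meanlog, sdlog); left-skewed quartiles give its reflection
#' X = shift - LN(meanlog, sdlog); symmetric quartiles fall back to a normal
#' with sd = IQR / 1.349.
#'
#' @param q1,m,q3 target quartiles (q1 <= m <= q3, q1 < q3).
#' @return A list with `kind` ("lnorm", "rlnorm" or "norm") and parameters;
#'   the returned `qfun(p)` evaluates the fitted quantile function.
#' @export
fitSkewQuantiles <- function(q1, m, q3) {
  stopifnot(q1 <= m, m <= q3, q3 > q1)
  z75 <- qnorm(0.75)
  sym <- abs((q3 - m) - (m - q1)) < 1e-9 * (q3 - q1)
  if (sym) {
    mu <- m; s <- (q3 - q1) / (2 * z75)
    return(list(kind = "norm", mean = mu, sd = s,
                qfun = function(p) qnorm(p, mu, s)))
  }
  if ((q3 - m) > (m - q1)) {       # right skew: X = delta + LN
    delta <- (m^2 - q1 * q3) / (2 * m - q1 - q3)
    if (delta >= q1) stop("degenerate quartiles for shifted log-normal fit")
    meanlog <- log(m - delta)
    sdlog <- log((q3 - delta) / (m - delta)) / z75
    return(list(kind = "lnorm", shift = delta, meanlog = meanlog, sdlog = sdlog,
                qfun = function(p) delta + exp(meanlog + sdlog * qnorm(p))))
  }
  # left skew: reflect around c, fit the mirror image, reflect back
  cc <- q1 + q3
  r1 <- cc - q3; rm <- cc - m; r3 <- cc - q1
  delta <- (rm^2 - r1 * r3) / (2 * rm - r1 - r3)
  if (delta >= r1) stop("degenerate quartiles for shifted log-normal fit")
  meanlog <- log(rm - delta)
  sdlog <- log((r3 - delta) / (rm - delta)) / z75
  list(kind = "rlnorm", reflect = cc, shift = delta,
       meanlog = meanlog, sdlog = sdlog,
       qfun = function(p) cc - (delta + exp(meanlog + sdlog * qnorm(1 - p))))
}

#' Stratified (jittered systematic) probability points
#'
#' Returns `n` probabilities, one drawn from each stratum
#' ((i - 1)/n, i/n) with a centred jitter of the given relative width, in a
#' seeded random order. Used to plant small cohorts that are representative of
#' a configured distribution: the sample quartiles of `qfun(stratifiedProbs(n))`
#' concentrate tightly around the distribution quartiles even at n = 20.
#'
#' @param n number of points.
#' @param jitter relative jitter width within each stratum (0 = deterministic
#'   mid-points, 1 = full-stratum uniform jitter).
#' @return Numeric vector of probabilities in (0, 1), randomly permuted
#'   (draws from the current RNG stream).
#' @export
stratifiedProbs <- function(n, jitter = 0.6) {
  if (n <= 0) return(numeric())
  u <- runif(n, -0.5, 0.5) * jitter
  p <- (seq_len(n) - 0.5 + u) / n
  p[sample.int(n)]
}

# Truncated sampling from a fitted quantile function via stratified probs:
# probabilities are mapped into (F(lo), F(hi)) before evaluation.
.sampleFitTrunc <- function(fit, n, lo = -Inf, hi = Inf, jitter = 0.6) {
  p <- stratifiedProbs(n, jitter)
  plo <- .fitCdf(fit, lo); phi <- .fitCdf(fit, hi)
  fit$qfun(plo + p * (phi - plo))
}

.fitCdf <- function(fit, x) {
  if (!is.finite(x)) return(if (x > 0) 1 else 0)
  switch(fit$kind,
    norm   = pnorm(x, fit$mean, fit$sd),
    lnorm  = if (x <= fit$shift) 0 else
      pnorm((log(x - fit$shift) - fit$meanlog) / fit$sdlog),
    rlnorm = if (x >= fit$reflect - fit$shift) 1 else
      pnorm(-(log(fit$reflect - x - fit$shift) - fit$meanlog) / fit$sdlog)
  )
}

# --- seeds and hashing -------------------------------------------------------

# Derive k child seeds (< 2^31 - 1) from a master seed, reproducibly.
deriveSeeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Tiny FNV-1a hash of a config object for output file headers.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# Write a data.frame as CSV with a provenance comment header.
writeCsvWithHeader <- function(df, path, seed = NA, cfgHash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qeegr seed=%s config=%s", seed, cfgHash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

readCsvSkipHeader <- function(path) {
  read.csv(path, comment.char = "#")
}
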