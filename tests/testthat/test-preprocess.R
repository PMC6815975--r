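# Filtering, segment extraction, artifact screening.

test_that("filtering attenuates 50 Hz mains and preserves the passband", {
  fs <- 250
  rms <- function(x) sqrt(mean(x^2))
  # oracle: frequency response of the designed cascade at 50 and 10 Hz
  p <- filterParams()
  bp <- signal::butter(p$filterOrder, c(p$bandpassLo, p$bandpassHi) / (fs / 2),
                       "pass")
  resp <- function(fHz) {
    w <- 2 * pi * fHz / fs
    hBp <- abs(sum(bp$b * exp(-1i * w * (seq_along(bp$b) - 1))) /
                 sum(bp$a * exp(-1i * w * (seq_along(bp$a) - 1))))
    w0 <- 2 * pi * p$notchFreq / fs
    al <- sin(w0) / (2 * p$notchQuality)
    b <- c(1, -2 * cos(w0), 1) / (1 + al)
    a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
    hN <- abs(sum(b * exp(-1i * w * 0:2)) / sum(a * exp(-1i * w * 0:2)))
    (hBp * hN)^2        # forward-backward application squares the magnitude
  }
  expect_lt(20 * log10(resp(50)), -20)
  expect_gt(resp(10), 0.95)

  # and the implementation matches the oracle on actual tones
  r50 <- filterRecording(sineRecording(50, 10, fs = fs))
  expect_lt(20 * log10(rms(eegSamples(r50)[, 1]) / rms(10 * sin(2 * pi * 50 *
    seq(0, 60 - 1 / fs, by = 1 / fs)))), -20)

  r10raw <- sineRecording(10, 10, fs = fs)
  r10 <- filterRecording(r10raw)
  mid <- (10 * fs):(50 * fs)   # avoid forward-backward edge effects
  ratio <- rms(eegSamples(r10)[mid, 1]) / rms(eegSamples(r10raw)[mid, 1])
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("filtering is zero-preserving, length-preserving and passband-idempotent", {
  fs <- 250
  zero <- EEGRecording(matrix(0, 60 * fs, 2), fs = fs)
  expect_equal(eegSamples(filterRecording(zero)), eegSamples(zero))

  r10 <- sineRecording(10, 10, fs = fs)
  once <- filterRecording(r10)
  twice <- filterRecording(once)
  expect_equal(nrow(eegSamples(once)), nrow(eegSamples(r10)))
  mid <- (10 * fs):(50 * fs)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(eegSamples(twice)[mid, 1]) /
                  rms(eegSamples(once)[mid, 1]) - 1), 0.01)

  expect_error(filterRecording(sineRecording(10, 10, fs = 150)), "Nyquist")
})

test_that("artifact detection flags spikes and flatlines, passes clean EEG", {
  fs <- 250
  clean <- matrix(rnorm(60 * fs * 2, sd = 10), ncol = 2)
  expect_false(detectArtifact(clean, fs = fs))

  spike <- clean
  spike[1000, 2] <- 2000
  expect_true(detectArtifact(spike, fs = fs))

  flat <- clean
  flat[1:(2 * fs), 1] <- 3.7      # 2 s exactly constant
  expect_true(detectArtifact(flat, fs = fs))
  flatShort <- clean
  flatShort[1:round(0.5 * fs), 1] <- 3.7   # only 0.5 s: below the rule
  expect_false(detectArtifact(flatShort, fs = fs))
})

test_that("segment extraction follows the post-ROSC schedule", {
  fs <- 20   # schedule logic is rate-independent; keep the fixture small
  rec <- EEGRecording(matrix(rnorm(240 * 60 * fs * 2, sd = 8), ncol = 2),
                      fs = fs)
  segs <- extractSegments(rec)
  expect_length(segs, 9)
  expect_equal(vapply(segs, timepointMin, numeric(1)),
               c(5, seq(30, 240, by = 30)))
  expect_true(all(vapply(segs, function(s) nrow(eegSamples(s)), numeric(1))
                  == 60 * fs))
  # non-overlapping post-ROSC windows under the default schedule
  starts <- vapply(segs, timepointMin, numeric(1)) * 60
  expect_true(all(diff(starts) >= 60))

  short <- EEGRecording(matrix(rnorm(4 * 60 * fs * 2), ncol = 2), fs = fs)
  expect_warning(empty <- extractSegments(short), "schedule")
  expect_length(empty, 0)
})

test_that("segments slide away from artifacts, or are flagged when trapped", {
  fs <- 50
  n <- 70 * 60 * fs
  base <- matrix(rnorm(n * 2, sd = 8), ncol = 2)
  # artifact inside the nominal 30-min window only: sliding rescues it
  m1 <- base
  m1[(30 * 60 + 20) * fs, 1] <- 5000
  segs <- extractSegments(EEGRecording(m1, fs = fs), scheduleMin = c(5, 30))
  expect_false(artifactFlag(segs[[2]]))
  # artifacts peppered across the whole +/- 60 s search range: flagged
  m2 <- base
  for (tS in seq(29 * 60 - 10, 32 * 60 + 10, by = 20)) m2[tS * fs, 1] <- 5000
  segs2 <- extractSegments(EEGRecording(m2, fs = fs), scheduleMin = c(5, 30))
  expect_true(artifactFlag(segs2[[2]]))
})
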