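# Envelope, burst detection, timeline classification, OTOB/TTNT.

test_that("envelope is half peak-to-peak, combined by cross-channel minimum", {
  fs <- 250
  rec <- sineRecording(10, 20, fs = fs, seconds = 10)
  env <- computeEnvelope(rec)
  expect_equal(length(env@values),
               floor((10 * fs - 2 * floor(fs / 4)) / floor(fs / 4)) + 1)
  expect_true(all(abs(env@values - 20) < 0.5))

  zero <- EEGRecording(matrix(0, 10 * fs, 2), fs = fs)
  expect_true(all(computeEnvelope(zero)@values == 0))

  both <- sineRecording(10, 20, fs = fs, seconds = 10, peakUv2 = 4)
  envB <- computeEnvelope(both)
  expect_true(all(abs(envB@values - 4) < 0.5))         # minimum rule
  expect_true(all(abs(envB@perChannel[, 1] - 20) < 0.5))

  expect_error(computeEnvelope(matrix(0, 10, 2), fs = fs), "shorter")
})

test_that("burst detection enumerates square-wave envelopes exactly", {
  expect_equal(nrow(detectBursts(EnvelopeTrace(rep(0, 240), hopS = 0.25))), 0)

  sq <- squareEnvelope(reps = 20, highS = 2, lowS = 1)
  b <- detectBursts(sq)
  expect_equal(nrow(b), 20)
  expect_equal(sum(b$endS - b$startS), 40)

  solid <- EnvelopeTrace(rep(20, 240), hopS = 0.25)   # 60 s constant
  b1 <- detectBursts(solid)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$endS - b1$startS, 60)

  # suppression gaps shorter than 0.5 s are merged into the burst
  shortGap <- squareEnvelope(reps = 10, highS = 2, lowS = 0.25)
  expect_equal(nrow(detectBursts(shortGap)), 1)
  # bursts shorter than the minimum duration are dropped
  blip <- EnvelopeTrace(c(rep(0, 100), 20, rep(0, 100)), hopS = 0.05)
  expect_equal(nrow(detectBursts(blip, minBurstS = 0.1)), 0)
})

test_that("timeline classification follows the three amplitude rules", {
  hop <- 0.25
  mkEnv <- function(v) EnvelopeTrace(v, hopS = hop)
  labsOf <- function(tl) intervals(tl)$label

  isoEnv <- mkEnv(rep(2, 480))                         # 2 min below 5 uV
  expect_equal(labsOf(classifyTimeline(isoEnv)), "isoelectric")

  bsEnv <- squareEnvelope(reps = 40, highS = 2, lowS = 1)  # 120 s of bursts
  expect_equal(labsOf(classifyTimeline(bsEnv)), "burst_suppression")

  contEnv <- mkEnv(rep(c(6, 25), 240))                 # min 6, max 25
  expect_equal(labsOf(classifyTimeline(contEnv)), "continuous")

  # sustained 5-10 uV activity without bursts falls back to iso/suppression
  midEnv <- mkEnv(rep(7, 480))
  expect_equal(labsOf(classifyTimeline(midEnv)), "isoelectric")
})

test_that("classification is threshold-based, not scale-free", {
  contEnv <- EnvelopeTrace(rep(c(6, 25), 240), hopS = 0.25)
  expect_equal(intervals(classifyTimeline(contEnv))$label, "continuous")
  # halving the amplitude pushes the floor below 5 uV: label changes
  halfEnv <- EnvelopeTrace(rep(c(3, 12.5), 240), hopS = 0.25)
  expect_false(identical(intervals(classifyTimeline(halfEnv))$label,
                         "continuous"))
  # scaling well above both thresholds leaves the label unchanged
  bigEnv <- EnvelopeTrace(rep(c(12, 50), 240), hopS = 0.25)
  expect_equal(intervals(classifyTimeline(bigEnv))$label, "continuous")
})

test_that("classified timelines partition the recording", {
  # iso -> burst suppression -> continuous, 3 minutes each
  v <- c(rep(2, 720),
         rep(squareEnvelope(1, 2, 1)@values, 60),
         rep(c(15, 25), 360))
  tl <- classifyTimeline(EnvelopeTrace(v, hopS = 0.25))
  iv <- intervals(tl)
  expect_equal(iv$startMin[1], 0)
  expect_equal(iv$endMin[nrow(iv)], durationMin(tl))
  if (nrow(iv) > 1) {
    expect_equal(iv$startMin[-1], iv$endMin[-nrow(iv)])
    expect_true(all(iv$label[-1] != iv$label[-nrow(iv)]))
  }
  expect_equal(iv$label[1], "isoelectric")
  expect_equal(iv$label[nrow(iv)], "continuous")
  ot <- computeOtobTtnt(tl)
  expect_lt(abs(ot$otobMin - 3), 0.25)
  expect_lt(abs(ot$ttntMin - 6), 1)
})

test_that("OTOB/TTNT extraction implements the onset definitions", {
  tl <- PatternTimeline(c("isoelectric", "burst_suppression", "continuous"),
                        c(0, 20, 170), c(20, 170, 240))
  ot <- computeOtobTtnt(tl)
  expect_equal(ot$otobMin, 20)
  expect_equal(ot$ttntMin, 170)
  expect_false(ot$ttntCensored)

  tlCens <- PatternTimeline(c("isoelectric", "burst_suppression"),
                            c(0, 30), c(30, 240))
  otc <- computeOtobTtnt(tlCens)
  expect_equal(otc$ttntMin, 240)
  expect_true(otc$ttntCensored)
  expect_equal(otc$otobMin, 30)

  # isoelectric straight to continuous: OTOB falls through to TTNT
  tlJump <- PatternTimeline(c("isoelectric", "continuous"),
                            c(0, 100), c(100, 240))
  otj <- computeOtobTtnt(tlJump)
  expect_equal(otj$otobMin, 100)
  expect_equal(otj$ttntMin, 100)

  empty <- suppressWarnings(
    classifyTimeline(EnvelopeTrace(rep(1000, 480), hopS = 0.25)))
  expect_error(computeOtobTtnt(empty), "no intervals")
})

test_that("timelines export as BED-like interval tables", {
  tl <- PatternTimeline(c("isoelectric", "burst_suppression"),
                        c(0, 20), c(20, 240), animalId = "A1")
  path <- withr::local_tempfile(fileext = ".bed")
  writeTimelineBed(tl, path)
  bed <- read.delim(path)
  expect_equal(names(bed), c("animal_id", "start_s", "end_s", "label"))
  expect_equal(bed$start_s, c(0, 1200))
  expect_equal(bed$end_s, c(1200, 14400))
})
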