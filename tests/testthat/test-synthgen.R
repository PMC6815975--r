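# Synthetic cohort generator: distribution fits, planted invariants,
# determinism, and envelope-by-construction properties.

test_that("three-quantile fit reproduces the target quartiles exactly", {
  cases <- list(
    c(20.00, 21.85, 23.38),   # left-skewed (reflected fit)
    c(22.48, 25.70, 30.05),   # right-skewed
    c(161.63, 169.83, 208.55),
    c(186.29, 208.39, 248.80),
    c(1, 2, 3)                # symmetric (normal fallback)
  )
  for (q in cases) {
    f <- fitSkewQuantiles(q[1], q[2], q[3])
    expect_equal(f$qfun(c(0.25, 0.5, 0.75)), q, tolerance = 1e-10)
  }
})

test_that("stratified sampling concentrates small-cohort medians", {
  f <- fitSkewQuantiles(186.29, 208.39, 248.80)
  meds <- vapply(1:50, function(s)
    withr::with_seed(s, median(f$qfun(stratifiedProbs(20)))), numeric(1))
  expect_true(all(abs(meds - 208.39) < 3))
})

test_that("cohort generation is deterministic and honours invariants", {
  cfg <- generatorConfig(nPerGroup = 20, fs = 250, seed = 11)
  coh1 <- generateCohort(cfg)
  coh2 <- generateCohort(cfg)
  expect_identical(coh1, coh2)

  expect_equal(nrow(coh1), 40)
  expect_setequal(unique(coh1$group), c("H2", "Ctrl"))
  expect_true(all(coh1$plantedOtobMin < coh1$plantedTtntMin))
  expect_true(all(coh1$plantedOtobMin > 0))
  expect_true(all((coh1$survivalTimeH == 96) == coh1$survived96h))
  expect_true(all(coh1$survivalTimeH > 4 & coh1$survivalTimeH <= 96))
  nds <- as.matrix(coh1[, c("nds24", "nds48", "nds72", "nds96")])
  expect_true(all(nds >= 0 & nds <= 500))
  # non-survivors carry the death score at 96 h
  expect_true(all(coh1$nds96[!coh1$survived96h] == 500))
  # fixed survival margins match the configured rates
  expect_equal(sum(coh1$survived96h[coh1$group == "H2"]), 18)
  expect_equal(sum(coh1$survived96h[coh1$group == "Ctrl"]), 8)
})

test_that("planted cohort medians match the configured quartiles", {
  meds <- t(vapply(1:10, function(s) {
    coh <- generateCohort(generatorConfig(nPerGroup = 20, fs = 250, seed = s))
    h2 <- coh[coh$group == "H2", ]; ct <- coh[coh$group == "Ctrl", ]
    c(median(h2$plantedOtobMin), median(ct$plantedOtobMin),
      median(pmin(h2$plantedTtntMin, 240)),
      median(pmin(ct$plantedTtntMin, 240)))
  }, numeric(4)))
  expect_true(all(abs(meds[, 1] - 21.85) < 1))
  expect_true(all(abs(meds[, 2] - 25.70) < 1))
  expect_true(all(abs(meds[, 3] - 169.83) < 4))
  expect_true(all(abs(meds[, 4] - 208.39) < 4))
})

test_that("empty and invalid configurations are handled", {
  expect_equal(nrow(generateCohort(generatorConfig(nPerGroup = 0))), 0)
  expect_error(generatorConfig(durationMin = -1), "durationMin")
  expect_error(generatorConfig(fs = 80), "Nyquist")
  bad <- generatorConfig()
  bad$groups$H2$otobQ <- c(25, 22, 30)    # q1 > median
  expect_error(validateGeneratorConfig(bad), "q1")
  bad2 <- generatorConfig()
  bad2$amplitude$burstAmpRange <- c(2, 5) # bursts below the 10 uV rule
  expect_error(validateGeneratorConfig(bad2), "burst")
})

test_that("recordings respect the planted amplitude regimes per phase", {
  gen <- tinyGeneratorConfig(seed = 4, durationMin = 40)
  gen$artifactRate <- 0   # phase envelopes, not artifact handling
  coh <- generateCohort(gen)
  prof <- coh[coh$group == "Ctrl", ][1, ]
  rec <- filterRecording(generateRecording(prof, gen))
  env <- computeEnvelope(rec)
  hop <- env@hopS
  tS <- (seq_along(env@values) - 1) * hop
  otS <- prof$plantedOtobMin * 60
  ttS <- prof$plantedTtntMin * 60

  iso <- env@values[tS + 1 < otS - 1]
  expect_true(all(iso < 5))
  if (is.finite(ttS) && ttS < 39 * 60) {
    cont <- env@values[tS > ttS + 1 & tS + 1 < 40 * 60]
    expect_gt(min(cont), 5)
    expect_gt(max(cont), 10)
    # burst-suppression phase reaches above 10 uV (bursts) and below (gaps)
    bs <- env@values[tS > otS + 1 & tS + 1 < ttS - 1]
    expect_gt(max(bs), 10)
    expect_lt(min(bs), 10)
  }
})

test_that("recording regeneration is bit-identical and chunkable", {
  gen <- tinyGeneratorConfig(seed = 9, durationMin = 40)
  prof <- generateCohort(gen)[1, ]
  r1 <- generateRecording(prof, gen)
  r2 <- generateRecording(prof, gen)
  expect_identical(eegSamples(r1), eegSamples(r2))
  chunk <- generateRecording(prof, gen, fromMin = 10, toMin = 25)
  i0 <- 10 * 60 * gen$fs + 1
  expect_identical(eegSamples(chunk),
                   eegSamples(r1)[i0:(i0 + 15 * 60 * gen$fs - 1), ])
})

test_that("measured burst occupancy tracks the planted trajectory", {
  gen <- tinyGeneratorConfig(seed = 21, durationMin = 40)
  gen$artifactRate <- 0
  coh <- generateCohort(gen)
  prof <- coh[1, ]
  rec <- filterRecording(generateRecording(prof, gen))
  env <- computeEnvelope(rec)
  hop <- env@hopS
  # average measured occupancy per 1-min window in the plateau region
  plateauStart <- prof$plantedOtobMin + gen$rampMin
  winStarts <- seq(ceiling(plateauStart),
                   floor(min(prof$plantedTtntMin, 40)) - 1)
  winStarts <- head(winStarts, 5)
  expect_gte(length(winStarts), 2)
  for (w in winStarts) {
    idx <- which((seq_along(env@values) - 1) * hop >= w * 60 &
                   seq_along(env@values) * hop <= (w + 1) * 60)
    sub <- EnvelopeTrace(env@values[idx], hopS = hop)
    bsr <- computeBSR(sub)
    planted <- bsrTrajectory(w + 0.5, prof$plantedOtobMin,
                             prof$plantedTtntMin, prof$bsrPlateau,
                             gen$rampMin)
    expect_lt(abs(bsr - planted), 0.15)
  }
})

test_that("text matrix round-trip preserves the recording", {
  gen <- tinyGeneratorConfig(seed = 2, durationMin = 40)
  prof <- generateCohort(gen)[1, ]
  rec <- generateRecording(prof, gen, fromMin = 0, toMin = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  writeRecordingText(rec, path)
  back <- readRecordingText(path)
  expect_equal(sampleRate(back), sampleRate(rec))
  expect_equal(animalId(back), animalId(rec))
  expect_equal(eegSamples(back), eegSamples(rec), tolerance = 1e-5)
})
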