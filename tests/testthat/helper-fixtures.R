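# Shared fixtures built in code.

# A square combined-envelope trace: `reps` repetitions of (highS seconds at
# highUv, lowS seconds at lowUv), at the given hop. Durations must be
# multiples of the hop.
squareEnvelope <- function(reps, highS, lowS, highUv = 20, lowUv = 2,
                           hopS = 0.25) {
  one <- c(rep(highUv, round(highS / hopS)), rep(lowUv, round(lowS / hopS)))
  EnvelopeTrace(rep(one, reps), hopS = hopS)
}

# Two-channel sinusoid recording (peak amplitude per channel), seconds long.
sineRecording <- function(freqHz, peakUv, fs = 250, seconds = 60,
                          peakUv2 = peakUv) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  EEGRecording(cbind(peakUv * sin(2 * pi * freqHz * t),
                     peakUv2 * sin(2 * pi * freqHz * t)),
               fs = fs, animalId = "sine")
}

# Small, fast generator configuration for plumbing tests: 2 animals per arm,
# short recordings. Onset quartiles are scaled into the short window.
tinyGeneratorConfig <- function(seed = 1, nPerGroup = 2, durationMin = 40) {
  generatorConfig(
    nPerGroup = nPerGroup, fs = 250, durationMin = durationMin,
    groups = list(
      H2 = list(otobQ = c(4, 5, 6.5), ttntQ = c(20, 24, 28),
                twaBsrMean = 0.66, twaBsrSd = 0.09, survivalProb = 0.9,
                wpePlateauMean = 0.6, wpePlateauSd = 0.08),
      Ctrl = list(otobQ = c(6, 7.5, 9.5), ttntQ = c(26, 30, 35),
                  twaBsrMean = 0.52, twaBsrSd = 0.17, survivalProb = 0.4,
                  wpePlateauMean = 0.45, wpePlateauSd = 0.08)
    ),
    rampMin = 6, seed = seed
  )
}
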