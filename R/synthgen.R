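#' Generator configuration for synthetic post-ROSC EEG cohorts
#'
#' Builds the configuration object consumed by [generateCohort()] and
#' [generateRecording()]. Defaults reproduce the two-arm study design: 20
#' animals per arm, 240-minute two-channel recordings, arm-specific onset-time
#' quartiles (OTOB: time from ROSC to the first burst-suppression pattern;
#' TTNT: time to the first continuous-background pattern), arm-specific
#' time-weighted-average burst-suppression-ratio (TWA-BSR) targets, 96-hour
#' survival fractions, and a pooled death-time distribution calibrated so
#' the control arm's pooled survival-time quartiles reproduce
#' 44.00 [22.85-96.00] hours with 8 of 20 animals surviving.
#'
#' Amplitude parameters are standard deviations (uV) of band-limited Gaussian
#' noise per phase; the resulting half peak-to-peak envelope is roughly 1.5-3x
#' the SD, so the defaults respect the annotation thresholds by construction:
#' isoelectric envelope < 5 uV, suppression envelope < 10 uV, burst envelope
#' > 10 uV, and a continuous background whose envelope minimum exceeds 5 uV
#' and maximum exceeds 10 uV.
#'
#' @param nPerGroup animals per arm.
#' @param fs sampling rate in Hz (1000 nominal; 250 is the reduced desk-scale
#'   mode — all thresholds are amplitude-based and rate-independent).
#' @param durationMin recording duration, minutes post-ROSC.
#' @param groups named list of per-arm parameter lists; see Details.
#' @param deathTimeQuartiles pooled survival-time quartiles (h) used to
#'   calibrate the death-time distribution of the arm whose survival fraction
#'   matches `deathCalArm`.
#' @param deathCalArm arm whose group size/survivor count anchors the
#'   death-time calibration (default "Ctrl").
#' @param neverContinuousProb probability that an animal never reaches the
#'   continuous pattern within the recording (TTNT censored; default 3/40).
#' @param amplitude list of per-phase noise SDs (uV): `isoSd`, `suppressionSd`,
#'   `burstAmpRange` (per-burst SD drawn uniformly), `continuousEnvRange`
#'   (slow modulation range of the continuous background SD).
#' @param lineNoiseAmp amplitude (uV) of the 50 Hz mains sinusoid added to
#'   both channels.
#' @param artifactRate expected high-amplitude artifact events per hour.
#' @param artifactAmp artifact oscillation amplitude, uV.
#' @param burstDurRange burst duration range, seconds.
#' @param minGapS minimum inter-burst suppression duration, seconds. Must be
#'   comfortably above the 0.5 s envelope window so planted gaps survive
#'   envelope smoothing and the sub-0.5 s gap-merge rule.
#' @param burstWideningS seconds by which the 0.5 s envelope window widens
#'   each detected burst; the burst/gap scheduler compensates for it so that
#'   *measured* burst occupancy matches the planted trajectory.
#' @param rampMin minutes over which burst occupancy ramps from near zero at
#'   OTOB up to the animal's plateau.
#' @param survivalSampling `"fixed"` (default) fixes the number of survivors
#'   at `round(nPerGroup * survivalProb)`, matching the study's printed rates;
#'   `"bernoulli"` draws survival labels independently.
#' @param seed master seed; every downstream draw derives from it.
#'
#' @details Each element of `groups` is a list with `otobQ` and `ttntQ`
#' (quartile triplets, minutes), `twaBsrMean`/`twaBsrSd` (target TWA-BSR,
#' drawn per animal and solved for the occupancy plateau), `survivalProb`,
#' and `wpePlateauMean`/`wpePlateauSd` (signal-complexity plateau in (0,1),
#' controlling the broadband mixing fraction and hence measured
#' weighted-permutation entropy).
#'
#' @return A validated list of class `qeegGeneratorConfig`.
#' @export
generatorConfig <- function(
  nPerGroup = 20,
  fs = 1000,
  durationMin = 240,
  groups = list(
    H2 = list(
      otobQ = c(20.00, 21.85, 23.38),
      ttntQ = c(161.63, 169.83, 208.55),
      twaBsrMean = 0.66, twaBsrSd = 0.09,
      survivalProb = 0.9,
      wpePlateauMean = 0.60, wpePlateauSd = 0.08
    ),
    Ctrl = list(
      otobQ = c(22.48, 25.70, 30.05),
      ttntQ = c(186.29, 208.39, 248.80),
      twaBsrMean = 0.52, twaBsrSd = 0.17,
      survivalProb = 0.4,
      wpePlateauMean = 0.45, wpePlateauSd = 0.08
    )
  ),
  deathTimeQuartiles = c(22.85, 44.00, 96.00),
  deathCalArm = "Ctrl",
  neverContinuousProb = 3 / 40,
  amplitude = list(
    isoSd = 1.2,
    suppressionSd = 2.0,
    burstAmpRange = c(10, 25),
    continuousEnvRange = c(9, 18)
  ),
  lineNoiseAmp = 2,
  artifactRate = 1,
  artifactAmp = 1500,
  burstDurRange = c(0.5, 3),
  minGapS = 1.25,
  burstWideningS = 0.43,
  rampMin = 30,
  survivalSampling = c("fixed", "bernoulli"),
  seed = 1
) {
  cfg <- list(
    nPerGroup = as.integer(nPerGroup), fs = fs, durationMin = durationMin,
    groups = groups, deathTimeQuartiles = deathTimeQuartiles,
    deathCalArm = deathCalArm,
    neverContinuousProb = neverContinuousProb, amplitude = amplitude,
    lineNoiseAmp = lineNoiseAmp, artifactRate = artifactRate,
    artifactAmp = artifactAmp, burstDurRange = burstDurRange,
    minGapS = minGapS, burstWideningS = burstWideningS, rampMin = rampMin,
    survivalSampling = match.arg(survivalSampling), seed = as.integer(seed)
  )
  validateGeneratorConfig(cfg)
  class(cfg) <- "qeegGeneratorConfig"
  cfg
}

#' @rdname generatorConfig
#' @param cfg a generator configuration list.
#' @export
validateGeneratorConfig <- function(cfg) {
  if (cfg$durationMin <= 0) stop("durationMin must be positive")
  if (cfg$fs <= 100) stop("fs must exceed 100 Hz to represent 50 Hz mains (Nyquist)")
  for (gname in names(cfg$groups)) {
    g <- cfg$groups[[gname]]
    for (qn in c("otobQ", "ttntQ")) {
      q <- g[[qn]]
      if (!(q[1] > 0 && q[1] <= q[2] && q[2] <= q[3]))
        stop(gname, ": ", qn, " must satisfy 0 < q1 <= median <= q3")
    }
    if (any(g$otobQ >= g$ttntQ))
      stop(gname, ": OTOB quartiles must be below TTNT quartiles")
    if (g$survivalProb < 0 || g$survivalProb > 1)
      stop(gname, ": survivalProb must be in [0, 1]")
  }
  amp <- cfg$amplitude
  # thresholds by construction: bursts must clear 10 uV, suppression and
  # isoelectric noise must stay below it (envelope ~ 1.5-3x SD)
  if (min(amp$burstAmpRange) * 1.4 <= 10)
    stop("burstAmpRange too low: burst envelope must exceed 10 uV")
  if (amp$suppressionSd * 3.6 >= 10)
    stop("suppressionSd too high: suppression envelope must stay below 10 uV")
  if (amp$isoSd * 3.6 >= 5)
    stop("isoSd too high: isoelectric envelope must stay below 5 uV")
  if (min(amp$continuousEnvRange) * 1.4 <= 5)
    stop("continuousEnvRange too low: continuous envelope minimum must exceed 5 uV")
  invisible(TRUE)
}

# Schedule used for TWA planting (minutes post-ROSC).
defaultScheduleMin <- function(durationMin = 240) {
  s <- c(5, if (durationMin >= 30) seq(30, durationMin, by = 30))
  s[s <= durationMin]
}

#' Death-time distribution calibrated to pooled survival quartiles
#'
#' Fits a log-normal to non-survivor death times so that a cohort of `n`
#' animals with `nDeath` deaths and the remainder censored at `censorH` hours
#' has pooled sample quartiles matching `pooledQ`, and so that the
#' Kaplan-Meier median (the `ceiling(n/2)`-th death when deaths are sampled
#' by stratified quantiles) is centred on the pooled median. Quartiles at or
#' above the censoring time impose no constraint (they are met automatically
#' by the censored block).
#'
#' @param pooledQ pooled quartiles c(q1, median, q3) in hours.
#' @param n cohort size; `nDeath` number of deaths.
#' @param censorH censoring horizon (h).
#' @param minH earliest possible death (h); deaths cannot occur during the
#'   monitored 4-hour EEG window.
#' @return A fit list as from [fitSkewQuantiles()] (kind "lnorm", shift 0)
#'   whose *truncated-to-(minH, censorH)* quantiles hit the targets.
#' @export
fitDeathTimes <- function(pooledQ, n, nDeath, censorH = 96, minH = 4) {
  if (nDeath < 2) stop("need at least 2 deaths to calibrate death times")
  # order-statistic index of a type-7 pooled quantile, mapped to a death-
  # distribution probability via plotting positions (h - 0.5)/nDeath;
  # for the median use the KM-median death index (centres S(t) = 0.5).
  targets <- list()
  hMed <- ceiling(n / 2)                 # death whose time is the KM median
  if (pooledQ[2] < censorH)
    targets <- c(targets, list(c(p = (hMed - 0.5) / nDeath, q = pooledQ[2])))
  h1 <- 1 + (n - 1) * 0.25
  if (pooledQ[1] < censorH)
    targets <- c(targets, list(c(p = (h1 - 0.5) / nDeath, q = pooledQ[1])))
  h3 <- 1 + (n - 1) * 0.75
  if (pooledQ[3] < censorH)
    targets <- c(targets, list(c(p = (h3 - 0.5) / nDeath, q = pooledQ[3])))
  if (length(targets) < 2)
    stop("pooled quartiles leave the death-time distribution unidentified")
  p0 <- sapply(targets, function(t) t["p"])
  lq <- sapply(targets, function(t) log(t["q"]))
  # solve log q = mu + sigma * qnorm(p'), where p' rescales p into the
  # sampling truncation window (minH, censorH); the window depends on
  # (mu, sigma), so iterate the fit to a fixed point
  mu <- NA; sigma <- NA
  plo <- 0; phi <- 1
  for (it in 1:8) {
    z <- qnorm(plo + p0 * (phi - plo))
    sigma <- if (length(z) == 2) diff(lq) / diff(z) else
      sum((z - mean(z)) * (lq - mean(lq))) / sum((z - mean(z))^2)
    mu <- mean(lq) - sigma * mean(z)
    if (sigma <= 0) break
    plo <- pnorm((log(minH) - mu) / sigma)
    phi <- pnorm((log(censorH) - mu) / sigma)
  }
  if (sigma <= 0) {
    # pooled order-statistic mapping degenerates for very small cohorts;
    # fall back to treating pooledQ as the death-time quartiles themselves
    f <- fitSkewQuantiles(pooledQ[1], pooledQ[2], min(pooledQ[3], censorH))
    return(f)
  }
  list(kind = "lnorm", shift = 0, meanlog = mu, sdlog = sigma,
       qfun = function(p) exp(mu + sigma * qnorm(p)))
}

# Trapezoid weights for points t (non-uniform spacing).
.trapWeights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1] <- (t[2] - t[1]) / 2
  w[n] <- (t[n] - t[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (t[3:n] - t[1:(n - 2)]) / 2
  w
}

#' Planted burst-occupancy trajectory
#'
#' The ground-truth instantaneous burst occupancy of a generated recording:
#' 0 before the planted OTOB, a linear ramp from `r0` to `plateau` over
#' `rampMin` minutes, the plateau until the planted TTNT, and 1 afterwards
#' (a continuous background is all "burst" by the amplitude definition).
#'
#' @param tMin evaluation time(s), minutes post-ROSC.
#' @param otobMin,ttntMin planted phase boundaries, minutes.
#' @param plateau occupancy plateau in (0, 1).
#' @param rampMin ramp duration, minutes.
#' @param r0 occupancy at onset.
#' @return Occupancy value(s) in \[0, 1\].
#' @export
bsrTrajectory <- function(tMin, otobMin, ttntMin, plateau, rampMin, r0 = 0.05) {
  r <- numeric(length(tMin))
  ramp <- tMin >= otobMin & tMin < pmin(otobMin + rampMin, ttntMin)
  r[ramp] <- r0 + (plateau - r0) * (tMin[ramp] - otobMin) / rampMin
  plat <- tMin >= otobMin + rampMin & tMin < ttntMin
  r[plat] <- plateau
  r[tMin >= ttntMin] <- 1
  r
}

# Solve the occupancy plateau so the trapezoidal TWA of the trajectory over
# the measurement schedule (evaluated at segment midpoints) hits twaTarget.
.solvePlateau <- function(twaTarget, otobMin, ttntMin, rampMin,
                          scheduleMin, r0 = 0.05, cap = 0.8) {
  if (length(scheduleMin) < 2)                # degenerate schedule
    return(min(max(twaTarget, 0.02), cap))
  tm <- scheduleMin + 0.5                     # segment midpoints
  w <- .trapWeights(scheduleMin)
  span <- sum(w)
  contrib1 <- sum(w * bsrTrajectory(tm, otobMin, ttntMin, 1, rampMin, r0))
  contrib0 <- sum(w * bsrTrajectory(tm, otobMin, ttntMin, 0, rampMin, 0))
  # TWA(plateau) is linear: TWA = (contrib0 + plateau*(contrib1 - contrib0))/span
  denom <- contrib1 - contrib0
  if (denom <= 1e-9) return(cap)
  pl <- (twaTarget * span - contrib0) / denom
  min(max(pl, 0.02), cap)
}

#' Generate a synthetic cohort of animal profiles
#'
#' Draws one [AnimalProfile][generateCohort] row per animal for each arm:
#' planted OTOB/TTNT (stratified draws from three-parameter log-normal fits
#' to the configured quartiles), the target TWA-BSR and the occupancy plateau
#' that realizes it, the complexity plateau, 96-h survival, survival time
#' (deaths drawn from the calibrated death-time distribution and assigned
#' worst-first along a latent severity score), neurological deficit scores
#' (NDS, 0-500) and serum S100B levels linked to the EEG severity by a
#' Gaussian-copula-style rank construction, and a per-animal stream seed.
#'
#' @param config a [generatorConfig()].
#' @return A `data.frame` with one row per animal (class
#'   `qeegCohort`): columns `animalId`, `group`, `plantedOtobMin`,
#'   `plantedTtntMin` (`Inf` = never continuous), `twaBsrTarget`,
#'   `bsrPlateau`, `wpePlateau`, `survived96h`, `survivalTimeH`,
#'   `nds24`, `nds48`, `nds72`, `nds96`, `s100bBl`, `s100b120`, `s100b240`,
#'   `streamSeed`.
#' @export
generateCohort <- function(config) {
  validateGeneratorConfig(config)
  if (config$nPerGroup <= 0) {
    empty <- .emptyCohort()
    return(empty)
  }
  withr::with_seed(config$seed, .generateCohortInner(config))
}

.emptyCohort <- function() {
  df <- data.frame(
    animalId = character(), group = character(),
    plantedOtobMin = numeric(), plantedTtntMin = numeric(),
    twaBsrTarget = numeric(), bsrPlateau = numeric(), wpePlateau = numeric(),
    survived96h = logical(), survivalTimeH = numeric(),
    nds24 = numeric(), nds48 = numeric(), nds72 = numeric(), nds96 = numeric(),
    s100bBl = numeric(), s100b120 = numeric(), s100b240 = numeric(),
    streamSeed = integer(), stringsAsFactors = FALSE
  )
  class(df) <- c("qeegCohort", "data.frame")
  df
}

.generateCohortInner <- function(config) {
  n <- config$nPerGroup
  sched <- defaultScheduleMin(config$durationMin)
  calArm <- config$groups[[config$deathCalArm]]
  nDeathCal <- n - round(n * calArm$survivalProb)
  deathFit <- fitDeathTimes(config$deathTimeQuartiles, n, max(nDeathCal, 2))

  arms <- lapply(names(config$groups), function(gname) {
    g <- config$groups[[gname]]
    otFit <- do.call(fitSkewQuantiles, as.list(g$otobQ))
    ttFit <- do.call(fitSkewQuantiles, as.list(g$ttntQ))
    otob <- .sampleFitTrunc(otFit, n, lo = 1, hi = config$durationMin - 10)
    ttnt <- ttFit$qfun(stratifiedProbs(n))
    ttnt <- pmax(ttnt, otob + 5)
    # never-continuous animals are the latest recoverers: censoring the top
    # draws leaves the realized cohort median at the configured one
    nCens <- rbinom(1, n, config$neverContinuousProb)
    if (nCens > 0) ttnt[order(ttnt, decreasing = TRUE)[seq_len(nCens)]] <- Inf

    twaFit <- list(kind = "norm", mean = g$twaBsrMean, sd = g$twaBsrSd,
                   qfun = function(p) qnorm(p, g$twaBsrMean, g$twaBsrSd))
    twa <- .sampleFitTrunc(twaFit, n, lo = 0.02, hi = 0.95)
    plateau <- mapply(function(tw, ot, tt)
      .solvePlateau(tw, ot, tt, config$rampMin, sched), twa, otob, ttnt)
    wpePl <- pmin(pmax(
      qnorm(stratifiedProbs(n), g$wpePlateauMean, g$wpePlateauSd), 0.15), 0.9)

    # latent severity: later recovery and lower burst occupancy = worse
    sev <- 0.8 * scale(log(pmin(ttnt, config$durationMin * 2)))[, 1] +
      0.4 * scale(log(otob))[, 1] - 0.9 * scale(twa)[, 1] + rnorm(n, 0, 0.5)

    nSurv <- if (config$survivalSampling == "fixed")
      round(n * g$survivalProb) else sum(runif(n) < g$survivalProb)
    nDeath <- n - nSurv
    survived <- rep(TRUE, n)
    if (nDeath > 0) survived[order(sev, decreasing = TRUE)[seq_len(nDeath)]] <- FALSE

    survTime <- rep(96, n)
    if (nDeath > 0) {
      dt <- sort(.sampleFitTrunc(deathFit, nDeath, lo = 4, hi = 96))
      # worst animals die first
      dead <- which(!survived)
      survTime[dead[order(sev[dead], decreasing = TRUE)]] <- dt
    }

    data.frame(
      animalId = sprintf("%s-%02d", gname, seq_len(n)), group = gname,
      plantedOtobMin = otob, plantedTtntMin = ttnt, twaBsrTarget = twa,
      bsrPlateau = plateau, wpePlateau = wpePl,
      survived96h = survived, survivalTimeH = survTime,
      sev = sev, stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, arms)
  N <- nrow(cohort)

  # outcome variables via a Gaussian-copula-style link on pooled severity rank
  zSev <- qnorm((rank(cohort$sev, ties.method = "first") - 0.5) / N)
  mix <- function(rho) rho * zSev + sqrt(1 - rho^2) * rnorm(N)
  cohort$s100bBl <- rnorm(N, 55, 8)
  cohort$s100b120 <- 70 * exp(0.45 * mix(0.90)) + rnorm(N, 0, 3)
  cohort$s100b240 <- 85 * exp(0.55 * mix(0.93)) + rnorm(N, 0, 3)

  ndsL <- mix(0.85)
  nds96 <- ifelse(cohort$survived96h,
                  pmin(450, pmax(0, round(400 * pnorm(ndsL)^1.7))), 500)
  ndsAt <- function(tH) {
    val <- round(nds96 + (460 - nds96) * exp(-(tH - 24) / 30) + rnorm(N, 0, 15))
    val <- pmin(500, pmax(0, val))
    ifelse(cohort$survivalTimeH <= tH, 500, val)
  }
  cohort$nds24 <- ndsAt(24); cohort$nds48 <- ndsAt(48)
  cohort$nds72 <- ndsAt(72); cohort$nds96 <- ifelse(
    cohort$survivalTimeH <= 96 & !cohort$survived96h, 500, nds96)
  cohort$sev <- NULL
  cohort$streamSeed <- deriveSeeds(config$seed + 1L, N)
  rownames(cohort) <- NULL
  class(cohort) <- c("qeegCohort", "data.frame")
  cohort
}

#' Planted ground-truth pattern timeline of a profile
#'
#' @param profile one row of a [generateCohort()] data.frame.
#' @param durationMin recording duration in minutes.
#' @return A [PatternTimeline-class] with the planted phase boundaries.
#' @export
plantedTimeline <- function(profile, durationMin = 240) {
  ot <- profile$plantedOtobMin; tt <- min(profile$plantedTtntMin, Inf)
  labs <- "isoelectric"; st <- 0; en <- min(ot, durationMin)
  if (ot < durationMin) {
    labs <- c(labs, "burst_suppression")
    st <- c(st, ot); en <- c(en, min(tt, durationMin))
  }
  if (is.finite(tt) && tt < durationMin) {
    labs <- c(labs, "continuous"); st <- c(st, tt); en <- c(en, durationMin)
  }
  PatternTimeline(labs, st, en, animalId = profile$animalId)
}

# Deterministic per-animal synthesis plan: burst events, continuous-phase
# modulation, artifact events, per-block noise seeds.
.recordingPlan <- function(profile, config) {
  fs <- config$fs; durS <- config$durationMin * 60
  otS <- profile$plantedOtobMin * 60
  ttS <- min(profile$plantedTtntMin * 60, durS)
  withr::with_seed(profile$streamSeed, {
    # burst schedule with occupancy compensation for envelope widening
    starts <- ends <- amps <- numeric(0)
    if (otS < ttS) {
      nmax <- ceiling((ttS - otS) / (min(config$burstDurRange) + config$minGapS))
      starts <- ends <- amps <- numeric(nmax)
      k <- 0L; t <- otS
      while (t < ttS) {
        rT <- bsrTrajectory(t / 60, profile$plantedOtobMin,
                            profile$plantedTtntMin, profile$bsrPlateau,
                            config$rampMin)
        rT <- min(max(rT, 0.02), 0.8)
        # high occupancy needs long bursts: with gaps floored at minGapS the
        # achievable occupancy is b/(b + minGap), so bias draws upward
        b <- if (rT > 0.7)
          runif(1, 2.5, config$burstDurRange[2])
        else if (rT > 0.45)
          runif(1, 1.5, config$burstDurRange[2])
        else runif(1, config$burstDurRange[1], config$burstDurRange[2])
        b <- min(b, ttS - t)
        k <- k + 1L
        starts[k] <- t; ends[k] <- t + b
        amps[k] <- runif(1, config$amplitude$burstAmpRange[1],
                         config$amplitude$burstAmpRange[2])
        gap <- (b + config$burstWideningS) / rT - b
        gap <- min(max(gap, config$minGapS), 90)
        t <- t + b + gap
      }
      starts <- starts[seq_len(k)]; ends <- ends[seq_len(k)]
      amps <- amps[seq_len(k)]
    }
    contMod <- list(period = runif(1, 20, 45), phase = runif(1, 0, 2 * pi))
    nArt <- rpois(1, config$artifactRate * config$durationMin / 60)
    artStart <- sort(runif(nArt, 0, durS - 2))
    artDur <- runif(nArt, 0.5, 2)
    nBlocks <- ceiling(config$durationMin / 60)
    blockSeeds <- sample.int(.Machine$integer.max - 1L, nBlocks * 2L)
    list(burst = data.frame(start = starts, end = ends, amp = amps),
         contMod = contMod,
         artifact = data.frame(start = artStart, dur = artDur),
         blockSeeds = matrix(blockSeeds, ncol = 2L),
         otS = otS, ttS = ttS, durS = durS)
  })
}

# Unit-variance band-limited noise of length n (single-pass Butterworth on
# white noise with a warm-up pad to avoid start-up transients).
.bandNoise <- function(n, lo, hi, fs) {
  pad <- round(2 * fs)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), "pass")
  y <- signal::filter(bf, rnorm(n + pad))
  y <- y[-seq_len(pad)]
  y / stats::sd(y)
}

# Synthesize one block [fromS, toS) of one channel pair. Returns n x 2 matrix.
.synthBlock <- function(profile, config, plan, blockIdx, fromS, toS) {
  fs <- config$fs
  n <- round((toS - fromS) * fs)
  tSec <- fromS + (seq_len(n) - 1) / fs
  amp <- config$amplitude

  # per-sample amplitude profile (shared across channels)
  a <- rep(amp$isoSd, n)
  inBS <- tSec >= plan$otS & tSec < plan$ttS
  a[inBS] <- amp$suppressionSd
  if (nrow(plan$burst)) {
    bi <- plan$burst[plan$burst$end > fromS & plan$burst$start < toS, ,
                     drop = FALSE]
    for (j in seq_len(nrow(bi))) {
      i0 <- max(1L, ceiling((bi$start[j] - fromS) * fs) + 1L)
      i1 <- min(n, floor((bi$end[j] - fromS) * fs))
      if (i1 >= i0) a[i0:i1] <- bi$amp[j]
    }
  }
  inCont <- tSec >= plan$ttS
  if (any(inCont)) {
    lo <- amp$continuousEnvRange[1]; hi <- amp$continuousEnvRange[2]
    a[inCont] <- lo + (hi - lo) *
      (0.5 + 0.5 * sin(2 * pi * tSec[inCont] / plan$contMod$period +
                         plan$contMod$phase))
  }

  # complexity mixing fraction (drives weighted-permutation entropy)
  ttEff <- if (is.finite(profile$plantedTtntMin)) plan$ttS else
    plan$otS + 120 * 60
  cmix <- 0.12 + (profile$wpePlateau - 0.12) *
    pmin(pmax((tSec - plan$otS) / max(ttEff - plan$otS, 1), 0), 1)

  out <- matrix(0, n, 2)
  for (ch in 1:2) {
    blockSeed <- plan$blockSeeds[blockIdx, ch]
    x <- withr::with_seed(blockSeed, {
      lown <- .bandNoise(n, 3, 12, fs)
      brdn <- .bandNoise(n, 3, 45, fs)
      u <- ((1 - cmix) * lown + cmix * brdn) / sqrt((1 - cmix)^2 + cmix^2)
      u * a + config$lineNoiseAmp * sin(2 * pi * 50 * tSec + ch)
    })
    out[, ch] <- x
  }

  # high-amplitude artifacts (slow oscillation burst on both channels)
  if (nrow(plan$artifact)) {
    ai <- plan$artifact[plan$artifact$start < toS &
                          plan$artifact$start + plan$artifact$dur > fromS, ,
                        drop = FALSE]
    for (j in seq_len(nrow(ai))) {
      i0 <- max(1L, ceiling((ai$start[j] - fromS) * fs) + 1L)
      i1 <- min(n, floor((ai$start[j] + ai$dur[j] - fromS) * fs))
      if (i1 >= i0) {
        tt <- tSec[i0:i1]
        out[i0:i1, 1] <- out[i0:i1, 1] +
          config$artifactAmp * sin(2 * pi * 8 * tt)
        out[i0:i1, 2] <- out[i0:i1, 2] +
          config$artifactAmp * sin(2 * pi * 8 * tt)
      }
    }
  }
  out
}

#' Generate (a chunk of) a synthetic recording for one animal
#'
#' Synthesizes the two-channel post-ROSC EEG of one cohort animal. The signal
#' follows the planted phase timeline: low-amplitude noise before the planted
#' OTOB (envelope < 5 uV), alternating band-limited bursts (> 10 uV, 0.5-3 s)
#' and suppression gaps with instantaneous occupancy following the planted
#' trajectory until the planted TTNT, then a continuous background whose
#' envelope stays above 5 uV with maxima above 10 uV. A 50 Hz mains sinusoid
#' is added to both channels, and high-amplitude artifacts are injected at
#' the configured rate. Generation is block-wise (60-minute blocks with
#' per-block seeds), so any chunk `[fromMin, toMin)` regenerates
#' bit-identically without synthesizing the rest of the recording.
#'
#' @param profile one row of a [generateCohort()] data.frame.
#' @param config the matching [generatorConfig()].
#' @param fromMin,toMin chunk bounds in minutes post-ROSC (defaults: the full
#'   recording). Must be multiples of 1 minute.
#' @return An [EEGRecording-class] covering `[fromMin, toMin)`.
#' @export
generateRecording <- function(profile, config, fromMin = 0,
                              toMin = config$durationMin) {
  validateGeneratorConfig(config)
  stopifnot(fromMin >= 0, toMin <= config$durationMin, toMin > fromMin)
  plan <- .recordingPlan(profile, config)
  blockMin <- 60
  b0 <- floor(fromMin / blockMin); b1 <- ceiling(toMin / blockMin) - 1
  chunks <- lapply(b0:b1, function(b) {
    # synthesize the whole block, then trim: a chunk is then bit-identical
    # to the same span of a full-recording synthesis
    fS <- b * blockMin * 60
    tS <- min((b + 1) * blockMin, config$durationMin) * 60
    m <- .synthBlock(profile, config, plan, b + 1L, fS, tS)
    i0 <- round((max(b * blockMin, fromMin) * 60 - fS) * config$fs) + 1L
    i1 <- round((min((b + 1) * blockMin, toMin) * 60 - fS) * config$fs)
    m[i0:i1, , drop = FALSE]
  })
  samples <- do.call(rbind, chunks)
  EEGRecording(samples, fs = config$fs, t0Min = fromMin,
               animalId = profile$animalId)
}

#' Generate the designated pre-arrest baseline segment
#'
#' One artifact-free minute of continuous-pattern (awake-baseline style) EEG,
#' used as the `baseline` point of the measurement schedule.
#'
#' @inheritParams generateRecording
#' @return An [EEGSegment-class] with `timepointMin = NA` (baseline).
#' @export
generateBaselineSegment <- function(profile, config) {
  fs <- config$fs; n <- round(60 * fs)
  amp <- config$amplitude
  samples <- withr::with_seed(profile$streamSeed + 7L, {
    tSec <- (seq_len(n) - 1) / fs
    lo <- amp$continuousEnvRange[1]; hi <- amp$continuousEnvRange[2]
    a <- lo + (hi - lo) * (0.5 + 0.5 * sin(2 * pi * tSec / 30))
    vapply(1:2, function(ch) {
      u <- (0.3 * .bandNoise(n, 3, 12, fs) + 0.7 * .bandNoise(n, 3, 45, fs)) /
        sqrt(0.3^2 + 0.7^2)
      u * a + config$lineNoiseAmp * sin(2 * pi * 50 * tSec + ch)
    }, numeric(n))
  })
  EEGSegment(samples, fs = fs, timepointMin = NA_real_)
}

#' Write/read a recording as a plain-text two-column matrix
#'
#' Text interchange format: a one-line header `fs=<Hz>` (plus optional
#' `t0min=` and `id=` fields), then one row per sample with the two channel
#' amplitudes in uV.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @return `writeRecordingText()` returns the path invisibly;
#'   `readRecordingText()` returns an [EEGRecording-class].
#' @export
writeRecordingText <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%g t0min=%g id=%s", rec@fs, rec@t0Min, rec@animalId),
             con)
  utils::write.table(format(rec@samples, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecordingText
#' @export
readRecordingText <- function(path) {
  hdr <- readLines(path, n = 1)
  fields <- strsplit(strsplit(hdr, "\\s+")[[1]], "=")
  kv <- setNames(vapply(fields, `[`, "", 2), vapply(fields, `[`, "", 1))
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  EEGRecording(m, fs = as.numeric(kv[["fs"]]),
               t0Min = if ("t0min" %in% names(kv)) as.numeric(kv[["t0min"]]) else 0,
               animalId = if ("id" %in% names(kv)) kv[["id"]] else NA_character_)
}
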