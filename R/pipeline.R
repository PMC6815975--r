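#' Pipeline configuration
#'
#' Bundles the generator, filter, WPE, schedule and statistics settings for a
#' full simulate-and-analyse run. Defaults reproduce the study settings:
#' 1000 Hz sampling, 0.3-100 Hz band-pass with 50 Hz notch, segments at
#' baseline, 5 min and every 30 min post-ROSC, alpha 0.05.
#'
#' @param generator a [generatorConfig()].
#' @param filter a [filterParams()].
#' @param wpe list with embedding dimension `m` and delay `tau`.
#' @param scheduleMin post-ROSC segment schedule, minutes.
#' @param alpha significance level used by the statistics battery.
#' @param nBootstrap bootstrap resamples for AUC confidence intervals.
#' @param keepRaw write the synthetic recordings as text matrices.
#' @param seed master seed; overrides `generator$seed` so one seed drives
#'   the whole run.
#' @param verbose print stage progress.
#' @return A list of class `qeegPipelineConfig`.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           filter = filterParams(),
                           wpe = list(m = 5, tau = 1),
                           scheduleMin = NULL,
                           alpha = 0.05,
                           nBootstrap = 2000,
                           keepRaw = FALSE,
                           seed = generator$seed,
                           verbose = TRUE) {
  generator$seed <- as.integer(seed)
  validateGeneratorConfig(generator)
  if (is.null(scheduleMin))
    scheduleMin <- defaultScheduleMin(generator$durationMin)
  cfg <- list(generator = generator, filter = filter, wpe = wpe,
              scheduleMin = scheduleMin, alpha = alpha,
              nBootstrap = nBootstrap, keepRaw = keepRaw,
              seed = as.integer(seed), verbose = verbose)
  class(cfg) <- "qeegPipelineConfig"
  cfg
}

#' Analyse one recording through the pattern and feature stages
#'
#' Filters the recording, classifies the pattern timeline (OTOB/TTNT),
#' extracts the scheduled segments with artifact screening, and computes
#' per-segment BSR/WPE plus their time-weighted averages.
#'
#' @param rec an [EEGRecording-class] (raw).
#' @param config a [pipelineConfig()] (its filter/WPE/schedule blocks are
#'   used).
#' @param baseline optional raw baseline [EEGSegment-class].
#' @return A list: `timeline` ([PatternTimeline-class]), `otobMin`,
#'   `ttntMin`, `ttntCensored`, `features` (data.frame), `twaBsr`, `twaWpe`,
#'   `nSegmentsUsed`.
#' @export
analyzeRecording <- function(rec, config = pipelineConfig(),
                             baseline = NULL) {
  frec <- filterRecording(rec, config$filter)
  env <- computeEnvelope(frec)
  tl <- classifyTimeline(env, animalId = rec@animalId)
  ot <- computeOtobTtnt(tl, durationMin(rec))
  segs <- extractSegments(frec, scheduleMin = config$scheduleMin)
  fbase <- if (!is.null(baseline)) filterRecording(baseline, config$filter)
  feats <- segmentFeatures(segs, baseline = fbase,
                           m = config$wpe$m, tau = config$wpe$tau,
                           animalId = rec@animalId)
  c(list(timeline = tl), ot, feats)
}

#' Run the full simulate-preprocess-classify-feature-statistics pipeline
#'
#' Generates the synthetic cohort, synthesizes and analyses every recording,
#' and runs the outcome statistics battery. When `outDir` is given, writes
#' the cohort ground truth (`cohort.csv`), per-animal measurements
#' (`animals.csv`), the tidy feature table (`features.csv`), pattern
#' timelines (`timelines.bed`), the statistics table (`stats.csv`) and a run
#' log; every CSV carries the master seed and a config hash in a comment
#' header, and re-running with the same config is bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory (created if missing).
#' @return A list (invisibly when writing): `cohort`, `animals` (per-animal
#'   measured OTOB/TTNT/TWA table joined with outcomes), `features`,
#'   `timelines`, `stats` (data.frame), `statsDetail` (named list of result
#'   objects), `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  gen <- config$generator
  say <- function(...) if (config$verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] generating cohort (n = %d per arm, seed %d)",
      gen$nPerGroup, gen$seed)
  cohort <- generateCohort(gen)
  if (!nrow(cohort)) {
    warning("empty cohort; nothing to analyse")
    return(invisible(list(cohort = cohort)))
  }

  timelines <- vector("list", nrow(cohort))
  animals <- vector("list", nrow(cohort))
  features <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    say("[analyze] %s (%d/%d)", prof$animalId, i, nrow(cohort))
    rec <- generateRecording(prof, gen)
    if (config$keepRaw && !is.null(outDir))
      writeRecordingText(rec, file.path(outDir,
                                        paste0(prof$animalId, "_eeg.txt")))
    baseline <- generateBaselineSegment(prof, gen)
    res <- analyzeRecording(rec, config, baseline = baseline)
    timelines[[i]] <- res$timeline
    features[[i]] <- res$features
    animals[[i]] <- data.frame(
      animalId = prof$animalId, group = prof$group,
      otobMin = res$otobMin, ttntMin = res$ttntMin,
      ttntCensored = res$ttntCensored,
      twaBsr = res$twaBsr, twaWpe = res$twaWpe,
      nSegmentsUsed = res$nSegmentsUsed,
      survived96h = prof$survived96h, survivalTimeH = prof$survivalTimeH,
      nds96 = prof$nds96, s100b240 = prof$s100b240
    )
    rm(rec); res <- NULL
  }
  animals <- do.call(rbind, animals)
  features <- do.call(rbind, features)

  say("[stats] outcome statistics battery")
  statsDetail <- cohortStats(animals, alpha = config$alpha,
                             nBootstrap = config$nBootstrap,
                             seed = config$seed)
  statsTab <- statsDetail$table

  bundle <- list(cohort = cohort, animals = animals, features = features,
                 timelines = timelines, stats = statsTab,
                 statsDetail = statsDetail$detail, config = config)
  say("[done] %.1f min elapsed",
      as.numeric(difftime(Sys.time(), t0, units = "mins")))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    h <- configHash(unclass(config))
    writeCsvWithHeader(cohort, file.path(outDir, "cohort.csv"),
                       config$seed, h)
    writeCsvWithHeader(animals, file.path(outDir, "animals.csv"),
                       config$seed, h)
    writeCsvWithHeader(features, file.path(outDir, "features.csv"),
                       config$seed, h)
    writeCsvWithHeader(statsTab, file.path(outDir, "stats.csv"),
                       config$seed, h)
    bedPath <- file.path(outDir, "timelines.bed")
    if (file.exists(bedPath)) file.remove(bedPath)
    for (i in seq_along(timelines))
      writeTimelineBed(timelines[[i]], bedPath, append = i > 1)
    logLines <- c(sprintf("qeegr pipeline run, seed=%d config=%s",
                          config$seed, h),
                  sprintf("animals=%d features=%d stats_rows=%d",
                          nrow(animals), nrow(features), nrow(statsTab)),
                  sprintf("fs=%g durationMin=%g nPerGroup=%d",
                          gen$fs, gen$durationMin, gen$nPerGroup))
    writeLines(logLines, file.path(outDir, "run.log"))
    return(invisible(bundle))
  }
  bundle
}

#' Outcome statistics battery on a per-animal table
#'
#' Runs the group comparisons (OTOB, TTNT, TWA-BSR, TWA-WPE), Kaplan-Meier /
#' log-rank survival analysis, Spearman correlations of the EEG features with
#' S100B and NDS, and survival ROC/AUC for every feature, mirroring the
#' study's analysis plan (each feature reported marginally, no
#' multiple-testing adjustment).
#'
#' @param animals per-animal data.frame as produced by [runPipeline()]
#'   (columns `group`, `otobMin`, `ttntMin`, `twaBsr`, `twaWpe`,
#'   `survived96h`, `survivalTimeH`, `nds96`, `s100b240`).
#' @param alpha gate level for [compareGroups()].
#' @param nBootstrap AUC bootstrap resamples.
#' @param seed bootstrap seed.
#' @return A list: `table` (flat data.frame: `analysis`, `estimate`,
#'   `ciLow`, `ciHigh`, `pValue`, `note`) and `detail` (named list of the
#'   underlying result objects).
#' @export
cohortStats <- function(animals, alpha = 0.05, nBootstrap = 2000, seed = 1) {
  g <- split(animals, animals$group)
  if (length(g) != 2) stop("expected exactly two groups")
  gn <- names(g)
  featCols <- c(otob = "otobMin", ttnt = "ttntMin", twa_bsr = "twaBsr",
                twa_wpe = "twaWpe")
  riskDir <- c(otob = "higher", ttnt = "higher", twa_bsr = "lower",
               twa_wpe = "lower")
  detail <- list()
  rows <- list()
  addRow <- function(analysis, estimate, ciLow = NA, ciHigh = NA,
                     pValue = NA, note = "")
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, estimate = estimate, ciLow = ciLow,
      ciHigh = ciHigh, pValue = pValue, note = note)

  for (f in names(featCols)) {
    col <- featCols[[f]]
    cmp <- tryCatch(compareGroups(g[[1]][[col]], g[[2]][[col]],
                                  alpha = alpha),
                    error = function(e) {
                      warning("group comparison for ", f,
                              " skipped (small sample): ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(cmp)) next
    detail[[paste0("compare_", f)]] <- cmp
    addRow(sprintf("compare_%s_%s_vs_%s", f, gn[1], gn[2]),
           estimate = mean(g[[1]][[col]], na.rm = TRUE) -
             mean(g[[2]][[col]], na.rm = TRUE),
           pValue = cmp$pValue, note = paste0("test=", cmp$testUsed))
  }

  km <- kmLogrank(animals$survivalTimeH, !animals$survived96h,
                  animals$group)
  detail$km <- km
  for (gg in names(km$medians))
    addRow(sprintf("km_median_%s", gg), km$medians[[gg]])
  addRow("logrank_chisq", km$chisq, pValue = km$pValue)

  for (f in names(featCols)) {
    col <- featCols[[f]]
    for (outc in c("s100b240", "nds96")) {
      sc <- tryCatch(spearmanCI(animals[[col]], animals[[outc]]),
                     error = function(e) NULL)
      if (is.null(sc)) next
      detail[[paste0("spearman_", f, "_", outc)]] <- sc
      addRow(sprintf("spearman_%s_%s", f, outc), sc$r, sc$ciLow, sc$ciHigh,
             sc$pValue)
    }
    roc <- tryCatch(
      withCallingHandlers(
        rocAucCI(animals[[col]], animals$survived96h,
                 riskDirection = riskDir[[f]], nBoot = nBootstrap,
                 seed = seed),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (!is.null(roc)) {
      detail[[paste0("roc_", f)]] <- roc
      addRow(sprintf("roc_auc_%s", f), roc$auc, roc$ciLow, roc$ciHigh,
             roc$pValue)
    }
    # arm-restricted AUCs (unstable when one class nearly empty)
    for (gg in gn) {
      sub <- g[[gg]]
      rocG <- tryCatch(
        withCallingHandlers(
          rocAucCI(sub[[col]], sub$survived96h,
                   riskDirection = riskDir[[f]], nBoot = nBootstrap,
                   seed = seed),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (!is.null(rocG)) {
        detail[[paste0("roc_", f, "_", gg)]] <- rocG
        addRow(sprintf("roc_auc_%s_%s", f, gg), rocG$auc, rocG$ciLow,
               rocG$ciHigh, rocG$pValue,
               note = if (min(rocG$nDied, rocG$nSurvived) < 5)
                 "small outcome class" else "")
      }
    }
  }
  list(table = do.call(rbind, rows), detail = detail)
}
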