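# Outcome statistics: gated comparison, Spearman CI, ROC/AUC, KM/log-rank.

test_that("identical groups show no difference; gates route the test", {
  x <- withr::with_seed(1, rnorm(20))
  res <- compareGroups(x, x)
  expect_gte(res$pValue, 0.99)

  skewed <- withr::with_seed(2, exp(rnorm(30, 0, 1.5)))
  normalish <- withr::with_seed(3, rnorm(30))
  res2 <- compareGroups(skewed, normalish)
  expect_equal(res2$testUsed, "rank-sum")

  a <- withr::with_seed(4, rnorm(30))
  b <- withr::with_seed(5, rnorm(30, 0.2))
  res3 <- compareGroups(a, b)
  expect_equal(res3$testUsed, "t")

  expect_error(compareGroups(1:2, 1:10), "at least 3")
})

test_that("group comparison has power at the planted TWA-BSR separation", {
  # Monte-Carlo power at the two arms' printed mean/SD, n = 20 each
  rejections <- withr::with_seed(42, vapply(seq_len(500), function(i) {
    a <- rnorm(20, 0.66, 0.09)
    b <- rnorm(20, 0.52, 0.17)
    compareGroups(a, b)$pValue < 0.05
  }, logical(1)))
  expect_gte(mean(rejections), 0.8)
})

test_that("Spearman matches the rank-formula oracle with a Fisher-z CI", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  # oracle: 1 - 6*sum(d^2)/(n(n^2-1)), d = (1,-1,1,-1,0), sum d^2 = 4
  res <- spearmanCI(x, y)
  expect_equal(res$r, 1 - 6 * 4 / (5 * 24))
  expect_equal(res$r, 0.8)
  expect_lte(res$ciLow, res$r)
  expect_gte(res$ciHigh, res$r)

  expect_equal(spearmanCI(1:10, exp(1:10))$r, 1)
  expect_equal(spearmanCI(1:10, -(1:10))$r, -1)
  expect_error(spearmanCI(rep(1, 10), 1:10), "constant")

  # CI agrees with the closed-form Fisher transform
  n <- 30
  xy <- withr::with_seed(7, cbind(rnorm(n), rnorm(n)))
  res2 <- spearmanCI(xy[, 1], xy[, 1] + xy[, 2])
  z <- atanh(res2$r)
  expect_equal(res2$ciLow, tanh(z - qnorm(0.975) / sqrt(n - 3)))
  expect_equal(res2$ciHigh, tanh(z + qnorm(0.975) / sqrt(n - 3)))
})

test_that("AUC handles ties by half credit and is rank-invariant", {
  # survivors (1,2,3) vs non-survivors (2,3,4): 9 pairs, 6 concordant + 2
  # ties -> AUC = (6 + 2*0.5)/9 = 7/9
  scores <- c(1, 2, 3, 2, 3, 4)
  survived <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- suppressWarnings(rocAucCI(scores, survived, "higher", nBoot = 200))
  expect_equal(res$auc, 7 / 9)

  # invariance under a strictly monotone transform
  res2 <- suppressWarnings(rocAucCI(exp(scores), survived, "higher",
                                    nBoot = 200))
  expect_equal(res2$auc, res$auc)

  # perfect separation
  resP <- suppressWarnings(rocAucCI(c(1, 2, 3, 7, 8, 9), survived, "higher",
                                    nBoot = 200))
  expect_equal(resP$auc, 1)
  # risk direction flips orientation
  resL <- suppressWarnings(rocAucCI(-c(1, 2, 3, 7, 8, 9), survived, "lower",
                                    nBoot = 200))
  expect_equal(resL$auc, 1)

  expect_error(rocAucCI(1:5, rep(TRUE, 5), "higher"), "both outcome classes")

  # shuffled labels at large n: null AUC near 0.5, and the implementation
  # agrees with an independent ROC library
  sc <- withr::with_seed(11, rnorm(400))
  lab <- withr::with_seed(12, sample(rep(c(TRUE, FALSE), 200)))
  res3 <- rocAucCI(sc, lab, "higher", nBoot = 200)
  expect_lt(abs(res3$auc - 0.5), 0.08)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = !lab, predictor = sc, direction = "<", quiet = TRUE)))
  expect_equal(res3$auc, ref, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmLogrank(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("A", 4))
  f <- km$fit
  expect_equal(f$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$medians[["A"]], 2)

  # no deaths: survival stays 1, median undefined
  km0 <- kmLogrank(rep(96, 6), rep(0, 6), rep("A", 6))
  expect_true(all(km0$fit$surv == 1))
  expect_true(is.na(km0$medians[["A"]]))

  # without censoring the KM estimate is the empirical survival function
  tt <- withr::with_seed(3, round(rexp(25, 1 / 40), 1) + 1)
  km1 <- kmLogrank(tt, rep(1, 25), rep("A", 25))
  ecdfS <- vapply(km1$fit$time, function(t0) mean(tt > t0), numeric(1))
  expect_equal(km1$fit$surv, ecdfS)

  # identical groups: log-rank statistic near zero
  km2 <- kmLogrank(rep(tt, 2), rep(1, 50), rep(c("A", "B"), each = 25))
  expect_lt(km2$chisq, 1e-10)
  expect_error(kmLogrank(c(1, 2), c(1, 1), factor(c("A", "A"),
                                                  levels = c("A", "B"))),
               "empty group")
})

test_that("log-rank p-values are uniform under label permutation", {
  tt <- withr::with_seed(10, rexp(30, 1 / 50) + 1)
  ev <- rep(1, 30)
  ps <- withr::with_seed(13, vapply(seq_len(200), function(i) {
    g <- sample(rep(c("A", "B"), 15))
    kmLogrank(tt, ev, g)$pValue
  }, numeric(1)))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the statistics battery assembles a flat results table", {
  n <- 20
  animals <- withr::with_seed(21, {
    sev <- c(rnorm(n, 0), rnorm(n, 1))
    data.frame(
      group = rep(c("H2", "Ctrl"), each = n),
      otobMin = 20 + 3 * sev + rnorm(2 * n),
      ttntMin = 170 + 30 * sev + rnorm(2 * n, 0, 10),
      twaBsr = pmin(pmax(0.66 - 0.1 * sev + rnorm(2 * n, 0, 0.05), 0), 1),
      twaWpe = pmin(pmax(0.47 - 0.1 * sev + rnorm(2 * n, 0, 0.05), 0), 1),
      survived96h = sev < 0.8,
      survivalTimeH = ifelse(sev < 0.8, 96, pmax(5, 96 - 30 * sev)),
      nds96 = pmin(500, pmax(0, round(100 + 150 * sev))),
      s100b240 = 80 * exp(0.5 * sev)
    )
  })
  res <- cohortStats(animals, nBootstrap = 100, seed = 5)
  tab <- res$table
  expect_true(all(c("analysis", "estimate", "ciLow", "ciHigh", "pValue",
                    "note") %in% names(tab)))
  expect_true(any(grepl("^compare_", tab$analysis)))
  expect_true(any(grepl("^km_median_", tab$analysis)))
  expect_true(any(grepl("^spearman_", tab$analysis)))
  expect_true(any(grepl("^roc_auc_", tab$analysis)))
  # planted directions: later recovery correlates with worse outcome
  expect_gt(tab$estimate[tab$analysis == "spearman_ttnt_s100b240"], 0)
  expect_lt(tab$estimate[tab$analysis == "spearman_twa_bsr_s100b240"], 0)
  auc <- tab$estimate[tab$analysis == "roc_auc_ttnt"]
  expect_gt(auc, 0.6)
})
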