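#' Normality-gated two-group comparison
#'
#' Reproduces the study's testing rule: each group is screened for normality
#' with a Kolmogorov-Smirnov test against a normal with the sample mean and
#' SD; when both groups pass (p > alpha) and the variances are homogeneous
#' (F-ratio test, p > alpha), a two-tailed Student's t test with pooled
#' variance is used, otherwise the Wilcoxon rank-sum test. Summaries are
#' mean +/- SD for normal data and median \[Q1-Q3\] otherwise.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param alpha gate level for the normality and variance screens.
#' @return A list of class `qeegGroupCompare`: `testUsed` ("t" or
#'   "rank-sum"), `statistic`, `pValue`, `summaryA`, `summaryB`, `normal`,
#'   `homogeneous`.
#' @export
compareGroups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("each group must have at least 3 finite values")
  ksP <- function(x) {
    if (sd(x) == 0) return(0)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }
  normal <- ksP(a) > alpha && ksP(b) > alpha
  homogeneous <- if (sd(a) == 0 || sd(b) == 0) FALSE else
    var.test(a, b)$p.value > alpha
  fmtN <- function(x) sprintf("%.3g +/- %.3g", mean(x), sd(x))
  fmtM <- function(x) sprintf("%.3g [%.3g-%.3g]", median(x),
                              quantile(x, 0.25, names = FALSE),
                              quantile(x, 0.75, names = FALSE))
  if (normal && homogeneous) {
    tt <- t.test(a, b, var.equal = TRUE)
    res <- list(testUsed = "t", statistic = unname(tt$statistic),
                pValue = tt$p.value, summaryA = fmtN(a), summaryB = fmtN(b))
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    res <- list(testUsed = "rank-sum", statistic = unname(wt$statistic),
                pValue = wt$p.value, summaryA = fmtM(a), summaryB = fmtM(b))
  }
  res$normal <- normal
  res$homogeneous <- homogeneous
  class(res) <- "qeegGroupCompare"
  res
}

#' @export
print.qeegGroupCompare <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n  A: %s\n  B: %s\n",
              x$testUsed, x$statistic, x$pValue, x$summaryA, x$summaryB))
  invisible(x)
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Spearman's rho on average ranks, with a 95 percent (by default) confidence
#' interval from the Fisher z transform with standard error
#' `1 / sqrt(n - 3)`, and the large-sample t approximation p-value.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param conf confidence level.
#' @return A list of class `qeegCorr`: `r`, `ciLow`, `ciHigh`, `pValue`, `n`.
#' @export
spearmanCI <- function(x, y, conf = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input vector")
  r <- cor(rank(x), rank(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - conf) / 2)
  res <- list(r = r, ciLow = tanh(z - q * se), ciHigh = tanh(z + q * se),
              pValue = ct$p.value, n = n)
  class(res) <- "qeegCorr"
  res
}

#' @export
print.qeegCorr <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f, %d%% CI [%.3f, %.3f], p = %.4g (n = %d)\n",
              x$r, 95, x$ciLow, x$ciHigh, x$pValue, x$n))
  invisible(x)
}

# Mann-Whitney AUC (half credit for ties): P(risk score of a non-survivor
# exceeds that of a survivor).
.aucMW <- function(riskScores, died) {
  nd <- sum(died); ns <- sum(!died)
  r <- rank(riskScores)
  (sum(r[died]) - nd * (nd + 1) / 2) / (nd * ns)
}

#' ROC AUC for survival prediction, with bootstrap confidence interval
#'
#' Discrimination of 96-h survival by a single quantitative-EEG feature.
#' Scores are oriented so that higher = higher death risk (onset times
#' as-is, `riskDirection = "higher"`; time-weighted-average features negated,
#' `riskDirection = "lower"`), and the AUC is the Mann-Whitney pair statistic
#' with half credit for ties. The confidence interval is a stratified
#' (class-preserving) percentile bootstrap; the p-value is the normal
#' approximation to the null Mann-Whitney statistic.
#'
#' @param scores feature values.
#' @param survived logical (TRUE = survived to 96 h); both classes required.
#' @param riskDirection `"higher"` if larger scores mean higher death risk,
#'   `"lower"` if smaller scores do.
#' @param nBoot bootstrap resamples.
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return A list of class `qeegROC`: `auc`, `ciLow`, `ciHigh`, `pValue`,
#'   `orientation`, `nDied`, `nSurvived`.
#' @export
rocAucCI <- function(scores, survived, riskDirection = c("higher", "lower"),
                     nBoot = 2000, conf = 0.95, seed = 1) {
  riskDirection <- match.arg(riskDirection)
  ok <- is.finite(scores) & !is.na(survived)
  scores <- scores[ok]; survived <- as.logical(survived[ok])
  died <- !survived
  if (!any(died) || !any(survived))
    stop("both outcome classes must be present")
  risk <- if (riskDirection == "higher") scores else -scores
  auc <- .aucMW(risk, died)
  nd <- sum(died); ns <- sum(survived)
  if (min(nd, ns) < 5)
    warning("fewer than 5 animals in one outcome class; AUC is unstable")
  # normal approximation for H0: AUC = 0.5
  sigma0 <- sqrt((nd + ns + 1) / (12 * nd * ns))
  pValue <- 2 * pnorm(-abs(auc - 0.5) / sigma0)
  bootAuc <- withr::with_seed(seed, {
    di <- which(died); si <- which(survived)
    vapply(seq_len(nBoot), function(i) {
      bd <- sample(di, nd, replace = TRUE)
      bs <- sample(si, ns, replace = TRUE)
      .aucMW(c(risk[bd], risk[bs]), c(rep(TRUE, nd), rep(FALSE, ns)))
    }, numeric(1))
  })
  qs <- quantile(bootAuc, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE)
  res <- list(auc = auc, ciLow = max(0, qs[1]), ciHigh = min(1, qs[2]),
              pValue = pValue, orientation = riskDirection,
              nDied = nd, nSurvived = ns)
  class(res) <- "qeegROC"
  res
}

#' @export
print.qeegROC <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f, CI [%.3f, %.3f], p = %.4g (%d died / %d survived; risk: %s)\n",
    x$auc, x$ciLow, x$ciHigh, x$pValue, x$nDied, x$nSurvived, x$orientation))
  invisible(x)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs over all score thresholds, for plotting or
#' CSV export.
#'
#' @inheritParams rocAucCI
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, survived, riskDirection = c("higher", "lower")) {
  riskDirection <- match.arg(riskDirection)
  risk <- if (riskDirection == "higher") scores else -scores
  died <- !as.logical(survived)
  th <- sort(unique(risk))
  pts <- t(vapply(th, function(t0) c(
    fpr = mean(risk[!died] >= t0),
    tpr = mean(risk[died] >= t0)), numeric(2)))
  data.frame(threshold = c(-Inf, th),
             fpr = c(1, pts[, "fpr"]),
             tpr = c(1, pts[, "tpr"]))
}

#' Kaplan-Meier estimate and two-group log-rank test
#'
#' Product-limit survival estimate per group (survivors censored at 96 h),
#' group medians defined as the earliest time at which the survival function
#' drops to 0.5 or below (undefined when it stays above 0.5), and the
#' two-group log-rank chi-square with 1 df.
#'
#' @param timesH survival times, hours (> 0).
#' @param eventFlags logical/0-1; TRUE = death observed, FALSE = censored.
#' @param groups group labels (exactly two non-empty groups for the log-rank
#'   test; a single group yields estimate-only output).
#' @return A list of class `qeegKM`: `fit` (a [survival::survfit] object),
#'   `medians` (named vector, NA = undefined), `chisq`, `pValue`.
#' @export
kmLogrank <- function(timesH, eventFlags, groups) {
  stopifnot(all(timesH > 0))
  if (is.factor(groups) && any(table(groups) == 0)) stop("empty group")
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  event <- as.integer(eventFlags)
  fit <- survival::survfit(survival::Surv(timesH, event) ~ groups)
  medians <- vapply(levels(groups), function(g) {
    idx <- groups == g
    f1 <- survival::survfit(survival::Surv(timesH[idx], event[idx]) ~ 1)
    below <- which(f1$surv <= 0.5 + 1e-12)
    if (length(below)) f1$time[min(below)] else NA_real_
  }, numeric(1))
  if (nlevels(groups) >= 2) {
    sd0 <- survival::survdiff(survival::Surv(timesH, event) ~ groups)
    chisq <- sd0$chisq
    pValue <- pchisq(chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; pValue <- NA_real_
  }
  res <- list(fit = fit, medians = medians, chisq = chisq, pValue = pValue)
  class(res) <- "qeegKM"
  res
}

#' @export
print.qeegKM <- function(x, ...) {
  cat("Kaplan-Meier medians (h):\n")
  print(round(x$medians, 2))
  if (is.finite(x$chisq))
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g\n", x$chisq, x$pValue))
  invisible(x)
}
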