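#' @include AllClasses.R
NULL

## Anderson-Darling-gated paired test on a vector of differences.
##
## `frac` is the subsampling fraction of the resampling scheme that produced
## the differences. Resampled paired values are not independent replicates:
## every subset is drawn from the same dataset, so the per-subset
## differences centre on the dataset-level difference and the naive paired
## test is strongly anti-conservative against the population null. Both
## branches therefore use the subsampling variance correction of Nadeau &
## Bengio (2003): the t branch inflates the squared standard error to
## s^2 * (1/n + f/(1-f)) instead of s^2/n; the Wilcoxon branch applies the
## signed-rank test to variance-inflated differences
## mean(d) + (d - mean(d)) * sqrt(n * (1/n + f/(1-f))), whose spread
## reflects dataset-level uncertainty while preserving the observed effect
## size (a rank statistic on the raw differences saturates and cannot weigh
## magnitude). `frac = 0` recovers the uncorrected tests for genuinely
## independent differences.
##
## Conventions:
##  - all differences exactly zero: the signed-rank statistic is undefined;
##    report p = 1 ("no evidence of difference").
##  - zero-variance non-zero differences: normality is untestable and
##    clearly violated; fall through to the signed-rank branch.
##  - fewer than 8 differences: below the AD test's minimum n; treat as
##    non-normal and use the signed-rank branch.
.adGatedTest <- function(diffs, frac = 0) {
  stopifnot(is.numeric(diffs), length(diffs) >= 2L, frac >= 0, frac < 1)
  if (all(diffs == 0))
    return(list(normalityP = NA_real_, chosenTest = "wilcoxon_signed_rank",
                pValue = 1))
  n <- length(diffs)
  infl <- (1 / n + frac / (1 - frac)) * n  # variance inflation vs naive
  adP <- NA_real_
  if (stats::sd(diffs) > 0 && n >= 8L)
    adP <- nortest::ad.test(diffs)$p.value
  if (!is.na(adP) && adP >= 0.05) {
    se <- stats::sd(diffs) * sqrt(1 / n + frac / (1 - frac))
    tstat <- mean(diffs) / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
    return(list(normalityP = adP, chosenTest = "t_test", pValue = p))
  }
  d <- if (frac > 0) mean(diffs) + (diffs - mean(diffs)) * sqrt(infl)
       else diffs
  p <- .signedRankP(d)
  list(normalityP = adP, chosenTest = "wilcoxon_signed_rank", pValue = p)
}

## Two-sided Wilcoxon signed-rank p-value via the tie-corrected normal
## approximation (zero differences dropped, midranks for ties).
.signedRankP <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  if (sig2 <= 0) return(1)
  z <- (V - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

## Shared resampling engine. statFn(records_subset) must return a length-2
## numeric (statistic for A, statistic for B) or NA values to signal a
## degenerate subset, which is redrawn up to retryCap times.
.pairedResampleTest <- function(recs, statFn, frac, nReps, seed,
                                metric, contrast, retryCap = 25L) {
  n <- length(recs)
  k <- max(1L, floor(frac * n))
  a <- numeric(nReps)
  b <- numeric(nReps)
  withr::with_seed(seed, {
    for (r in seq_len(nReps)) {
      val <- c(NA_real_, NA_real_)
      for (try in seq_len(retryCap)) {
        idx <- sample.int(n, k)
        val <- statFn(recs[idx])
        if (!anyNA(val)) break
      }
      if (anyNA(val))
        stop("resample ", r, " degenerate after ", retryCap, " retries")
      a[r] <- val[1]
      b[r] <- val[2]
    }
  })
  res <- .adGatedTest(a - b, frac = frac)
  new("SignificanceResult", metric = metric, contrast = contrast,
      frac = frac, nReps = as.integer(nReps), valuesA = a, valuesB = b,
      normalityP = res$normalityP, chosenTest = res$chosenTest,
      pValue = res$pValue, significant = res$pValue < 0.05)
}
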