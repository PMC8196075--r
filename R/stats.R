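#' Pearson correlation of AUC against bout duration
#'
#' The central association test of the pipeline: is the size of the
#' bout-locked sensor transient (post-onset AUC) related to how long the
#' animal struggled? Returns the Pearson coefficient with its two-sided
#' t-distribution p-value (`t = r * sqrt((n-2)/(1-r^2))` on n-2 df), and
#' the OLS slope of AUC on duration with its t-based 95% confidence
#' interval.
#'
#' @param metrics a [bout_metrics()] data frame (or any data frame with
#'   `duration_s` and the response column).
#' @param response column name of the response (default `"auc_post"`).
#' @return list of class `correlation_result`: `r`, `n`, `df`, `p`,
#'   `slope`, `intercept`, `slope_ci` (95%), `significant`.
#' @export
correlate_auc_duration <- function(metrics, response = "auc_post") {
  d <- metrics[!is.na(metrics[[response]]) & !is.na(metrics$duration_s), ]
  x <- d$duration_s
  y <- d[[response]]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete bouts")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in duration or response",
          class = "strugglescope_degenerate_input")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(
    list(r = r, n = n, df = n - 2L, p = p,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         slope_ci = c(lower = ci[1L], upper = ci[2L]),
         significant = p < 0.05),
    class = "correlation_result"
  )
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list of class `group_comparison`: `statistic`, `df`, `p`,
#'   `means`, `sems`, `method`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  if (stats::var(a) + stats::var(b) == 0)
    stopf("zero combined variance", class = "strugglescope_degenerate_input")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         means = c(a = mean(a), b = mean(b)),
         sems = c(a = stats::sd(a) / sqrt(length(a)),
                  b = stats::sd(b) / sqrt(length(b))),
         method = "Welch two-sample t test"),
    class = "group_comparison"
  )
}

#' Paired t test
#'
#' One-sample t on the within-pair differences, two-sided.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return a `group_comparison` list as in [welch_t()].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("paired vectors must have equal length")
  if (length(x) < 2L) stopf("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stopf("zero variance of differences", class = "strugglescope_degenerate_input")
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         means = c(x = mean(x), y = mean(y)),
         sems = c(x = stats::sd(x) / sqrt(length(x)),
                  y = stats::sd(y) / sqrt(length(y))),
         method = "Paired t test"),
    class = "group_comparison"
  )
}

#' Exact binomial test for the proportion of positive-transient bouts
#'
#' Tests whether bouts with a positive post-onset response (AUC > 0, or
#' any logical indicator supplied) outnumber those without, against the
#' symmetric null of 0.5, using the exact two-sided binomial test
#' (minimum-likelihood definition: the p-value sums the probabilities of
#' all outcomes no more likely than the observed one).
#'
#' @param metrics a [bout_metrics()] data frame, or a logical vector of
#'   positivity indicators.
#' @param column indicator column when `metrics` is a data frame
#'   (default `"auc_positive"`).
#' @return list: `n_positive`, `n`, `proportion`, `p`.
#' @export
positive_auc_proportion <- function(metrics, column = "auc_positive") {
  flags <- if (is.data.frame(metrics)) metrics[[column]] else metrics
  flags <- flags[!is.na(flags)]
  n <- length(flags)
  if (n < 1L) stopf("need at least one bout")
  k <- sum(flags)
  p <- stats::binom.test(k, n, p = 0.5)$p.value
  list(n_positive = k, n = n, proportion = k / n, p = p)
}

# Benjamini-Hochberg step-up rejection flags at level q
.bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  crit <- q * seq_len(m) / m
  below <- p[o] <= crit
  k <- if (any(below)) max(which(below)) else 0L
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

#' Benjamini-Krieger-Yekutieli two-stage step-up FDR
#'
#' The adaptive two-stage linear step-up procedure controlling the false
#' discovery rate at level `q`: stage 1 runs Benjamini-Hochberg at
#' `q' = q / (1 + q)` giving `r1` rejections and the estimate
#' `m0 = m - r1` of true nulls; if `r1 = 0` nothing is rejected, if
#' `m0 = 0` everything is; otherwise stage 2 reruns BH at `q' * m / m0`
#' and its rejections are returned.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q desired FDR (default 0.01, i.e. a 1% false-discovery rate).
#' @return list: `reject` (logical), `r1`, `m0`, `stage2_level`, `q`.
#' @export
bky_two_stage_fdr <- function(pvals, q = 0.01) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals)))
    stopf("p-values must lie in [0, 1]", class = "strugglescope_domain_error")
  m <- length(pvals)
  qp <- q / (1 + q)
  stage1 <- .bh_reject(pvals, qp)
  r1 <- sum(stage1)
  m0 <- m - r1
  if (r1 == 0L)
    return(list(reject = rep(FALSE, m), r1 = 0L, m0 = m,
                stage2_level = NA_real_, q = q))
  if (m0 == 0L)
    return(list(reject = rep(TRUE, m), r1 = r1, m0 = 0L,
                stage2_level = NA_real_, q = q))
  lvl <- qp * m / m0
  list(reject = .bh_reject(pvals, lvl), r1 = r1, m0 = m0,
       stage2_level = lvl, q = q)
}

#' Normalize per-day transient frequencies to day 1
#'
#' Expresses each subject's daily transient frequency as a percent of that
#' subject's day-1 frequency (day 1 = 100%). Subjects with a zero day-1
#' frequency cannot be normalized and are excluded with a warning.
#'
#' @param freqs data frame with columns `subject`, `day`, `freq_hz`.
#' @param day1 the reference day label (default the minimum day present).
#' @return data frame `subject`, `day`, `freq_hz`, `pct_of_day1`.
#' @export
normalize_frequency_by_day <- function(freqs, day1 = min(freqs$day)) {
  out <- list()
  for (subj in unique(freqs$subject)) {
    sub <- freqs[freqs$subject == subj, , drop = FALSE]
    f1 <- sub$freq_hz[sub$day == day1]
    if (length(f1) != 1L || f1 == 0) {
      warning(sprintf("subject %s has no usable day-%s frequency; excluded",
                      subj, as.character(day1)))
      next
    }
    sub$pct_of_day1 <- 100 * sub$freq_hz / f1
    out[[length(out) + 1L]] <- sub
  }
  if (!length(out))
    return(data.frame(subject = character(), day = integer(),
                      freq_hz = numeric(), pct_of_day1 = numeric()))
  do.call(rbind, out)
}
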