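# Independent brute-force / closed-form oracles used across the suite.
# These deliberately avoid the package's own code paths.

# type-7 linear-interpolation quantile, written out explicitly
oracle_quantile7 <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# mobility threshold: mean + k * sd over the sub-quantile subset
oracle_threshold <- function(speeds, q, k) {
  qv <- oracle_quantile7(speeds, q)
  S <- speeds[speeds <= qv]
  m <- sum(S) / length(S)
  s <- if (length(S) >= 2) sqrt(sum((S - m)^2) / (length(S) - 1)) else 0
  m + k * s
}

# sample-by-sample transient scanner
oracle_scan_transients <- function(z, time, thr, min_samples = 1) {
  runs <- list()
  i <- 1
  n <- length(z)
  while (i <= n) {
    if (z[i] >= thr) {
      j <- i
      while (j < n && z[j + 1] >= thr) j <- j + 1
      if (j - i + 1 >= min_samples) {
        area <- 0
        if (j > i) for (k in i:(j - 1))
          area <- area + (time[k + 1] - time[k]) * (z[k] + z[k + 1]) / 2
        runs[[length(runs) + 1]] <- c(start_s = time[i], end_s = time[j],
                                      max_peak_z = max(z[i:j]), area = area,
                                      n_samples = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      max_peak_z = numeric(), area = numeric(),
                      n_samples = integer()))
  as.data.frame(do.call(rbind, runs))
}

# textbook Welch t
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# one-sample t on differences
oracle_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Pearson r, t-distribution p, OLS slope with t-based 95% CI
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  tc <- qt(0.975, n - 2)
  list(r = r, p = 2 * pt(-abs(t), n - 2), slope = slope,
       ci = c(slope - tc * se, slope + tc * se))
}

# exact two-sided binomial p by enumeration (minimum-likelihood rule)
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# literal step-by-step two-stage step-up procedure
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in 1:m) if (p[o[i]] <= q * i / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[1:k]] <- TRUE
  rej
}

oracle_bky <- function(p, q) {
  m <- length(p)
  qp <- q / (1 + q)
  s1 <- oracle_bh(p, qp)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  oracle_bh(p, qp * m / m0)
}

# unit-peak double-exponential kernel (test-side injection apparatus)
oracle_kernel <- function(t, rise = 0.1, decay = 1.5) {
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  pk <- exp(-tp / decay) - exp(-tp / rise)
  (exp(-t / decay) - exp(-t / rise)) / pk
}
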