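#' Adaptive iteratively reweighted penalized least-squares baseline
#'
#' Estimates slowly varying baseline drift (e.g. photobleaching) under a
#' signal containing positive peaks, by iterating a weighted Whittaker
#' smoother: solve `(W + lambda * t(D) %*% D) z = W y` for the baseline
#' `z`, where `W` is a diagonal weight matrix (initialized to 1) and `D`
#' the `diff_order`-th order difference matrix. After each solve the
#' residual `r = y - z` is formed and `s = sum(|r_i|)` over the negative
#' residuals; iteration stops when `s < conv * sum(|y|)` or after
#' `max_iter` iterations. Otherwise weights are updated to 0 where
#' `y_i >= z_i` (candidate peak region, excluded from the fit) and to
#' `exp(iter * |r_i| / s)` where `y_i < z_i`, so points below the current
#' baseline pull progressively harder. Larger `lambda` gives a stiffer
#' baseline; the default 5e4 suits photometry drift at tens of Hz.
#'
#' @param y numeric series, length >= 10.
#' @param lambda smoothness penalty (> 0), default 5e4.
#' @param diff_order difference order, 1 or 2 (default 1).
#' @param max_iter maximum iterations (default 50).
#' @param conv convergence ratio (default 0.001).
#' @return numeric baseline of the same length as `y`.
#' @export
airpls_baseline <- function(y, lambda = 5e4, diff_order = 1L, max_iter = 50L,
                            conv = 0.001) {
  n <- length(y)
  if (n < 10L) stopf("need at least 10 samples")
  if (!is.numeric(lambda) || lambda <= 0) stopf("`lambda` must be > 0")
  if (!diff_order %in% c(1L, 2L)) stopf("`diff_order` must be 1 or 2")
  if (max_iter < 1L) stopf("`max_iter` must be >= 1")
  D <- if (diff_order == 1L) {
    Matrix::bandSparse(n - 1L, n, k = 0:1,
                       diagonals = list(rep(-1, n - 1L), rep(1, n - 1L)))
  } else {
    Matrix::bandSparse(n - 2L, n, k = 0:2,
                       diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                        rep(1, n - 2L)))
  }
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  abs_y <- sum(abs(y))
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- tryCatch(
      as.numeric(Matrix::solve(W + P, w * y)),
      error = function(e) stopf("airPLS linear system is singular: %s",
                                conditionMessage(e),
                                class = "strugglescope_numerical_error")
    )
    r <- y - z
    neg <- r < 0
    s <- sum(abs(r[neg]))
    if (s < conv * abs_y || !any(neg)) break
    w[!neg] <- 0
    # cap the exponent so late iterations cannot overflow the weights
    w[neg] <- exp(pmin(it * abs(r[neg]) / s, 50))
  }
  z
}
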