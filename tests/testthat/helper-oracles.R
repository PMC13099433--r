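# Independent oracle implementations used to validate the package's
# numerics.  Each is written from the defining formula, by a different
# route than the implementation (double loops, normal equations, direct
# windowed DFT), and must stay independent of the code under test.

# Direct time-domain Stockwell transform: Gaussian window of sigma = 1/f
# (periodized over the circular signal), windowed DFT, one voice per
# frequency.  O(N^2 F) double loop.
oracle_stockwell <- function(x, fs, freqs) {
  n <- length(x)
  out <- matrix(0 + 0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    nb <- round(freqs[j] * n / fs)
    f <- nb / n                       # cycles per sample
    for (tau in 0:(n - 1)) {
      acc <- 0 + 0i
      for (k in 0:(n - 1)) {
        g <- sum((f / sqrt(2 * pi)) *
                   exp(-((tau - k + (-3:3) * n)^2) * f^2 / 2))
        acc <- acc + x[k + 1] * g * exp(-2i * pi * nb * k / n)
      }
      out[tau + 1, j] <- acc
    }
  }
  out
}

# Simple-regression OLS via explicit normal equations.
oracle_ols <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  coef <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% coef
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  list(beta = coef[2], t = coef[2] / se)
}

# One-sample t statistic from the defining formula.
oracle_t_one_sample <- function(x) {
  n <- length(x)
  tt <- mean(x) / (sd(x) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1))
}

# Pearson r from the defining sums, p via the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# Benjamini-Hochberg step-up by direct enumeration: largest k with
# p_(k) <= k q / m rejects p_(1..k).
oracle_bh_reject <- function(p, q_level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q_level / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k)) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Sliding-window mean correlation by a plain double loop over windows.
oracle_sliding_mean_r <- function(x, y, w, step = 1) {
  starts <- seq(1, length(x) - w + 1, by = step)
  mean(vapply(starts, function(s) {
    cor(x[s:(s + w - 1)], y[s:(s + w - 1)])
  }, numeric(1)))
}

# Lattice points within a sphere by exhaustive enumeration.
oracle_sphere_count <- function(coords, center, radius) {
  sum(sqrt(rowSums(sweep(coords, 2, center, `-`)^2)) <= radius + 1e-9)
}

# Salience/non-salience membership by direct set comprehension.
oracle_select_clusters <- function(r, hi_p, lo_p, hi_floor, lo_ceiling) {
  v <- r[!is.na(r)]
  hi <- quantile(v, hi_p / 100, type = 7, names = FALSE)
  lo <- quantile(v, lo_p / 100, type = 7, names = FALSE)
  list(sal = which(!is.na(r) & r > hi & r > hi_floor),
       non = which(!is.na(r) & r < lo & r < lo_ceiling))
}
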