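# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops, explicit trigonometric DFT sums, and
# direct counting, so they can certify the implementation.

oracle_windows <- function(duration, window, step) {
  starts <- numeric(0)
  k <- 0
  while (k * step + window <= duration + 1e-9) {
    starts <- c(starts, k * step)
    k <- k + 1
  }
  starts
}

# Median frequency by explicit DFT sums and a cumulative-power walk
# (same Hann taper definition as the documented feature, independent path).
oracle_median_frequency <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xw <- x * w
  nk <- floor(n / 2) + 1
  p <- numeric(nk)
  for (k in seq_len(nk)) {
    re <- 0; im <- 0
    for (i in seq_len(n)) {
      ang <- -2 * pi * (k - 1) * (i - 1) / n
      re <- re + xw[i] * cos(ang)
      im <- im + xw[i] * sin(ang)
    }
    p[k] <- re^2 + im^2
  }
  total <- sum(p)
  if (total <= 0) return(0)
  half <- total / 2
  cum <- 0
  freqs <- (seq_len(nk) - 1) * fs / n
  for (k in seq_len(nk)) {
    if (cum + p[k] >= half) {
      f_prev <- if (k == 1) 0 else freqs[k - 1]
      return(f_prev + (half - cum) / p[k] * (freqs[k] - f_prev))
    }
    cum <- cum + p[k]
  }
  freqs[nk]
}

oracle_hist_bins <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  if (s == 0) return(c(1, 0, 0))
  h <- c(0, 0, 0)
  for (xi in x) {
    z <- abs(xi - m) / s
    if (z <= 1) h[1] <- h[1] + 1
    else if (z <= 2) h[2] <- h[2] + 1
    else h[3] <- h[3] + 1
  }
  h / length(x)
}

# Numerically stable angle between vectors without acos of a dot product.
oracle_angle <- function(a, b) {
  ua <- a / sqrt(sum(a^2))
  ub <- b / sqrt(sum(b^2))
  2 * atan2(sqrt(sum((ua - ub)^2)), sqrt(sum((ua + ub)^2))) * 180 / pi
}

oracle_cohens_d <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
  (ma - mb) / sp
}

oracle_sens_spec <- function(truth, pred, cl) {
  tp <- sum(truth == cl & pred == cl)
  fn <- sum(truth == cl & pred != cl)
  fp <- sum(truth != cl & pred == cl)
  tn <- sum(truth != cl & pred != cl)
  c(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}
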