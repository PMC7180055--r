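# Independent reference implementations and fixture builders used across
# the suite. These stay deliberately naive (sequential scans, exhaustive
# enumeration, grid search) so they cannot share defects with the package.

# one-pass sequential-scan debounce reference
seq_filter_oracle <- function(ts, min_gap = 0.008) {
  ts <- sort(ts)
  out <- numeric(0)
  for (t in ts) {
    if (length(out) == 0 || t - out[length(out)] >= min_gap)
      out <- c(out, t)
  }
  unique(out)
}

# brute-force bout-onset scan
bout_onset_oracle <- function(ts, min_gap = 1) {
  on <- numeric(0)
  for (i in seq_along(ts)) {
    if (i == 1 || ts[i] - ts[i - 1] >= min_gap) on <- c(on, ts[i])
  }
  on
}

# exhaustive minimum-cost segmentation with at most 2 changepoints,
# L2 segment cost + linear penalty; returns first-index-of-new-segment
exhaustive_cp2_oracle <- function(x, penalty) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s * s / (j - i + 1)
  }
  head_cost <- vapply(1:n, function(t) segcost(1, t), 0)
  tail_cost <- vapply(1:n, function(t) segcost(t, n), 0)
  best_cost <- segcost(1, n); best_cps <- integer()
  for (t in 1:(n - 1)) {
    c1 <- head_cost[t] + tail_cost[t + 1] + penalty
    if (c1 < best_cost) { best_cost <- c1; best_cps <- t + 1L }
  }
  for (t1 in 1:(n - 2)) {
    t2 <- (t1 + 1):(n - 1)
    s <- cs[t2 + 1] - cs[t1 + 1]
    mid <- (cs2[t2 + 1] - cs2[t1 + 1]) - s * s / (t2 - t1)
    c2 <- head_cost[t1] + mid + tail_cost[t2 + 1] + 2 * penalty
    b <- which.min(c2)
    if (c2[b] < best_cost) {
      best_cost <- c2[b]; best_cps <- c(t1 + 1L, t2[b] + 1L)
    }
  }
  best_cps
}

# direct discrete-convolution smoothing reference (zero-padded edges)
conv_smooth_oracle <- function(x, bin_width, sd, halfwidth = 2) {
  K <- max(1L, round(halfwidth / bin_width))
  w <- dnorm((-K:K) * bin_width, 0, sd)
  w <- w / sum(w)
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    for (k in -K:K) {
      j <- i + k
      if (j >= 1 && j <= n) y[i] <- y[i] + x[j] * w[k + K + 1]
    }
  }
  y
}

# grid-search Gaussian least-squares oracle (amplitude profiled out)
grid_gauss_oracle <- function(t, y, mu_grid, sigma_grid) {
  best <- c(rss = Inf, a = NA, mu = NA, sigma = NA)
  for (mu in mu_grid) for (sg in sigma_grid) {
    g <- exp(-(t - mu)^2 / (2 * sg^2))
    a <- sum(y * g) / sum(g * g)
    rss <- sum((y - a * g)^2)
    if (rss < best["rss"]) best <- c(rss = rss, a = a, mu = mu, sigma = sg)
  }
  best
}

# lick train with a Gaussian-envelope rate profile: event times found by
# inverting the cumulative intensity of lambda(t) = peak_rate *
# exp(-(t-center)^2 / (2 sd^2)) on a fine grid (deterministic)
gaussian_envelope_licks <- function(center = 10, sd = 1.2, peak_rate = 7,
                                    span = c(0, 20)) {
  tg <- seq(span[1], span[2], by = 1e-3)
  lam <- peak_rate * exp(-(tg - center)^2 / (2 * sd^2))
  Lam <- cumsum(lam) * 1e-3
  n <- floor(max(Lam))
  if (n < 1) return(numeric())
  vapply(seq_len(n), function(k) tg[which(Lam >= k)[1]], 0)
}

# all-probe-trial table with uniform spacing, optionally stimulated
mk_probe_trials <- function(n, laser_onset = NA_real_, spacing = 45,
                            laser_frequency = 25, every_other = FALSE) {
  onset <- rep(laser_onset, n)
  if (every_other) onset[seq(2, n, by = 2)] <- NA_real_
  trial_table(seq_len(n), cumsum(rep(spacing, n)), rep("peak", n),
              laser_onset_rel = onset,
              laser_duration = ifelse(is.na(onset), NA_real_, 1),
              laser_frequency = ifelse(is.na(onset), NA_real_,
                                       laser_frequency),
              probe_duration = rep(spacing, n))
}

# fixed-trial table, optionally with laser on a subset of trials
mk_fixed_trials <- function(n, interval = 10, laser_onset = NA_real_,
                            laser_trials = integer(),
                            laser_frequency = 25) {
  onset <- rep(NA_real_, n)
  onset[laser_trials] <- laser_onset
  trial_table(seq_len(n), cumsum(rep(interval, n)), rep("fixed", n),
              laser_onset_rel = onset,
              laser_duration = ifelse(is.na(onset), NA_real_, 1),
              laser_frequency = ifelse(is.na(onset), NA_real_,
                                       laser_frequency))
}
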