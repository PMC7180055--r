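# Trial-aligned lick-rate estimation and frequency-domain analysis:
# binned/smoothed rate traces, averaged periodogram PSD of lick trains,
# band occupancy and peak frequency.

#' Trial-aligned lick-rate trace
#'
#' Bins licks on a trial-aligned time axis (100-ms bins by default), divides
#' by the bin width to obtain Hz, and smooths with a truncated Gaussian
#' kernel. The kernel honors a nominal smoothing "width" of 1 s as sd =
#' 0.25 s (so the +/-2 sd core spans 1 s), with support truncated at +/-2 s;
#' the kernel is normalized, so smoothing conserves total lick count up to
#' edge truncation.
#'
#' @param licks A [lick_train()] or numeric vector of lick times, seconds.
#' @param align_time Time origin (e.g. the trial's reward), seconds.
#' @param window Two-element window `c(a, b)` relative to `align_time`;
#'   licks in `[a, b)` are counted.
#' @param bin_width Bin width, seconds.
#' @param smoothing_sd Gaussian kernel sd, seconds; 0 disables smoothing.
#' @param kernel_halfwidth Kernel support half-width, seconds.
#' @return An object of class `rate_trace` with fields `bin_centers`
#'   (trial-relative), `rate` (smoothed, Hz), `raw_rate`, `bin_width`,
#'   `smoothing_sd`, `n_licks`.
#' @export
rate_trace <- function(licks, align_time = 0, window = c(0, 20),
                       bin_width = 0.1, smoothing_sd = 0.25,
                       kernel_halfwidth = 2) {
  a <- window[1]; b <- window[2]
  if (!(b > a)) stop("empty analysis window", call. = FALSE)
  nb <- round((b - a) / bin_width)
  if (abs(nb * bin_width - (b - a)) > 1e-6)
    stop("bin_width must divide the window length", call. = FALSE)
  rel <- as.numeric(licks) - align_time
  rel <- rel[rel >= a & rel < b]
  idx <- pmin(nb, floor((rel - a) / bin_width) + 1L)
  counts <- tabulate(idx, nbins = nb)
  raw <- counts / bin_width
  sm <- if (smoothing_sd > 0) {
    gauss_smooth(raw, bin_width, smoothing_sd, kernel_halfwidth)
  } else raw
  structure(list(bin_centers = a + (seq_len(nb) - 0.5) * bin_width,
                 rate = sm, raw_rate = raw, bin_width = bin_width,
                 smoothing_sd = smoothing_sd, n_licks = length(rel)),
            class = "rate_trace")
}

# discrete Gaussian smoothing, zero-padded edges, kernel normalized to 1
gauss_smooth <- function(x, bin_width, sd, halfwidth = 2) {
  K <- max(1L, round(halfwidth / bin_width))
  w <- stats::dnorm((-K:K) * bin_width, 0, sd)
  w <- w / sum(w)
  n <- length(x)
  xp <- c(rep(0, K), x, rep(0, K))
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(K + 1):(K + n)])
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace> %d bins x %.2g s, %d licks, peak %.2f Hz\n",
              length(x$rate), x$bin_width, x$n_licks, max(x$rate)))
  invisible(x)
}

#' @export
plot.rate_trace <- function(x, ..., xlab = "time (s)", ylab = "lick rate (Hz)") {
  graphics::plot(x$bin_centers, x$rate, type = "l", xlab = xlab,
                 ylab = ylab, ...)
  if (!is.null(x$sem)) {
    graphics::lines(x$bin_centers, x$rate + x$sem, lty = 3)
    graphics::lines(x$bin_centers, pmax(0, x$rate - x$sem), lty = 3)
  }
  invisible(x)
}

#' Mean rate trace across trials
#'
#' @param traces List of [rate_trace()] objects on identical grids.
#' @return A `rate_trace` whose `rate` is the per-bin mean, with an extra
#'   `sem` field (per-bin standard error across trials) and `n_trials`.
#' @export
mean_rate <- function(traces) {
  stopifnot(length(traces) >= 1)
  g <- traces[[1]]$bin_centers
  for (tr in traces)
    if (length(tr$bin_centers) != length(g) ||
        any(abs(tr$bin_centers - g) > 1e-9))
      stop("rate traces are on mismatched time grids", call. = FALSE)
  m <- do.call(rbind, lapply(traces, `[[`, "rate"))
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m)) else
    rep(0, ncol(m))
  out <- traces[[1]]
  out$rate <- mu
  out$raw_rate <- colMeans(do.call(rbind, lapply(traces, `[[`, "raw_rate")))
  out$sem <- sem
  out$n_trials <- length(traces)
  out$n_licks <- sum(vapply(traces, `[[`, 0, "n_licks"))
  out
}

#' Slice a lick train into fixed-length epochs
#'
#' @param licks Lick times, seconds.
#' @param starts Epoch start times, seconds.
#' @param epoch_length Epoch length, seconds.
#' @return A list of numeric vectors of lick times relative to each epoch
#'   start.
#' @export
slice_epochs <- function(licks, starts, epoch_length = 1) {
  x <- as.numeric(licks)
  lapply(starts, function(s) x[x >= s & x < s + epoch_length] - s)
}

#' Power spectral density of lick trains
#'
#' Each epoch's lick train is binarized on a 2-ms grid (500 Hz sampling),
#' lightly smoothed with a Gaussian kernel (sd `smooth_sd`, acting as a
#' low-pass that attenuates the comb harmonics of a rhythmic train so the
#' licking fundamental carries the peak), mean-subtracted, Hann-tapered,
#' and its periodogram computed; periodograms are averaged across epochs.
#' One-second epochs give a 1-Hz frequency resolution. Epochs with fewer
#' than 2 licks contribute an all-zero spectrum and are counted in
#' `n_flagged` rather than erroring.
#'
#' @param epochs List of numeric vectors: lick times relative to epoch
#'   start (see [slice_epochs()]).
#' @param epoch_length Epoch length, seconds.
#' @param fs Binarization sampling rate, Hz.
#' @param smooth_sd Gaussian pre-smoothing sd, seconds (0 disables).
#' @return An object of class `lick_psd`: `frequencies` (Hz, up to `fs/2`),
#'   `power` (arbitrary units), `normalization`, `n_epochs`, `n_flagged`.
#' @export
lick_psd <- function(epochs, epoch_length = 1, fs = 500, smooth_sd = 0.01) {
  if (!is.list(epochs)) epochs <- list(epochs)
  if (length(epochs) < 1) stop("need >= 1 epoch", call. = FALSE)
  n <- round(epoch_length * fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nf <- floor(n / 2) + 1
  freqs <- (seq_len(nf) - 1) / epoch_length
  acc <- numeric(nf)
  flagged <- 0L
  for (ep in epochs) {
    ep <- ep[ep >= 0 & ep < epoch_length]
    if (length(ep) < 2) { flagged <- flagged + 1L; next }
    x <- tabulate(floor(ep * fs) + 1L, nbins = n)
    if (smooth_sd > 0)
      x <- gauss_smooth(x, 1 / fs, smooth_sd, halfwidth = 5 * smooth_sd)
    x <- (x - mean(x)) * hann
    X <- stats::fft(x)
    p <- (Mod(X)^2 / (fs * sum(hann^2)))[seq_len(nf)]
    acc <- acc + p
  }
  used <- length(epochs) - flagged
  power <- if (used > 0) acc / length(epochs) else acc
  structure(list(frequencies = freqs, power = power,
                 normalization = "raw", n_epochs = length(epochs),
                 n_flagged = flagged, fs = fs,
                 epoch_length = epoch_length),
            class = "lick_psd")
}

#' @export
print.lick_psd <- function(x, ...) {
  cat(sprintf("<lick_psd> %d epochs (%d flagged), %.3g-Hz resolution\n",
              x$n_epochs, x$n_flagged, 1 / x$epoch_length))
  invisible(x)
}

#' @export
plot.lick_psd <- function(x, fmax = 20, ..., xlab = "frequency (Hz)",
                          ylab = "power") {
  sel <- x$frequencies <= fmax
  graphics::plot(x$frequencies[sel], x$power[sel], type = "h",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Percent of spectral power per licking-frequency band
#'
#' Power is totalled over 0.5-20 Hz and the percentage falling in each band
#' is reported. Bands are half-open `[lo, hi)` except the last, which is
#' closed at its upper edge (e.g. 4-5.99, 6-7.99, 8-10 Hz).
#'
#' @param psd A [lick_psd()] object covering at least 0-20 Hz.
#' @param bands List of `c(lo, hi)` band edges, Hz.
#' @param total_range Range over which total power is computed, Hz.
#' @return A data.frame with one row per band plus an `other` row for the
#'   out-of-band remainder; `percent` sums to 100.
#' @export
band_occupancy <- function(psd, bands = list(c(4, 6), c(6, 8), c(8, 10)),
                           total_range = c(0.5, 20)) {
  f <- psd$frequencies
  if (max(f) < total_range[2])
    stop("psd does not cover the analysis range", call. = FALSE)
  in_tot <- f >= total_range[1] & f <= total_range[2]
  total <- sum(psd$power[in_tot])
  if (total <= 0)
    stop("zero total power in the analysis range; band occupancy undefined",
         call. = FALSE)
  nb <- length(bands)
  pct <- numeric(nb)
  covered <- rep(FALSE, length(f))
  for (i in seq_len(nb)) {
    lo <- bands[[i]][1]; hi <- bands[[i]][2]
    sel <- if (i == nb) f >= lo & f <= hi else f >= lo & f < hi
    sel <- sel & in_tot
    pct[i] <- 100 * sum(psd$power[sel]) / total
    covered <- covered | sel
  }
  lab <- vapply(bands, function(b) sprintf("%g-%g Hz", b[1], b[2]), "")
  out <- data.frame(band = c(lab, "other"),
                    lo = c(vapply(bands, `[`, 0, 1), NA),
                    hi = c(vapply(bands, `[`, 0, 2), NA),
                    percent = c(pct, 100 * sum(psd$power[in_tot & !covered]) /
                                  total))
  out
}

#' Peak frequency of a lick PSD
#'
#' The frequency of maximal spectral power within the licking range
#' (2-12 Hz by default, excluding DC and stimulation-train artifacts).
#' Ties resolve to the lowest frequency.
#'
#' @param psd A [lick_psd()] object.
#' @param range Search range `c(lo, hi)`, Hz.
#' @return Peak frequency, Hz.
#' @export
peak_frequency <- function(psd, range = c(2, 12)) {
  sel <- psd$frequencies >= range[1] & psd$frequencies <= range[2]
  p <- psd$power[sel]
  if (all(p <= 0))
    stop("no spectral power in the licking range", call. = FALSE)
  psd$frequencies[sel][which.max(p)]   # which.max takes the first (lowest) tie
}
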