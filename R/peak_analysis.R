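# Single-trial peak detection on probe trials: change-in-mean segmentation
# of the smoothed lick-rate trace, Gaussian fitting of the candidate peak,
# validity rules, retry-by-window-shift, and session-level peak statistics.

#' Change-in-mean segmentation of a rate signal
#'
#' Detects steep transitions in a (smoothed) lick-rate signal by exact
#' penalized change-in-mean segmentation: segments carry an L2 cost
#' (within-segment sum of squared deviations from the segment mean) and
#' each changepoint a linear penalty; dynamic programming over up to
#' `max_changepoints` changepoints returns the global minimum. Each
#' changepoint is then classified rising or falling by the sign of the mean
#' of the 5 bins after it minus the mean of the 5 bins before it (clipped
#' at the signal edges); zero-difference points are dropped.
#'
#' @param signal Numeric vector of rate values per bin (>= 10 bins).
#' @param penalty Per-changepoint penalty; default `2 * log(n) * var(signal)`.
#' @param max_changepoints Maximum changepoints considered.
#' @param slope_halfwidth Bins on each side used for the direction test.
#' @return A data.frame with columns `index` (first bin of the new segment,
#'   1-based) and `direction` (`"rising"`/`"falling"`); zero rows for a
#'   constant signal.
#' @export
changepoints_mean <- function(signal, penalty = NULL, max_changepoints = 8,
                              slope_halfwidth = 5) {
  n <- length(signal)
  if (n < 10) stop("need >= 10 bins", call. = FALSE)
  if (max(signal) - min(signal) <= 0)
    return(data.frame(index = integer(), direction = character()))
  if (is.null(penalty)) penalty <- 2 * log(n) * stats::var(signal)

  cps <- segment_mean_dp(signal, penalty, max_changepoints)
  if (length(cps) == 0)
    return(data.frame(index = integer(), direction = character()))
  dir <- vapply(cps, function(i) {
    after <- signal[i:min(n, i + slope_halfwidth - 1)]
    before <- signal[max(1, i - slope_halfwidth):(i - 1)]
    d <- mean(after) - mean(before)
    if (d > 0) "rising" else if (d < 0) "falling" else ""
  }, "")
  keep <- dir != ""
  data.frame(index = cps[keep], direction = dir[keep],
             stringsAsFactors = FALSE)
}

# exact segment-neighbourhood dynamic programme: minimize sum of L2 segment
# costs + k * penalty over k = 0..K changepoints; returns the first index of
# each new segment. O(K n^2), exact (no pruning).
segment_mean_dp <- function(x, penalty, K) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) {  # cost of segment x[i..j]
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s * s / (j - i + 1)
  }
  # D[k+1, j]: min cost of x[1..j] with exactly k changepoints
  K <- min(K, n - 1)
  D <- matrix(Inf, K + 1, n)
  B <- matrix(0L, K + 1, n)   # backpointer: last segment start - 1
  D[1, ] <- vapply(seq_len(n), function(j) segcost(1, j), 0)
  if (K >= 1) {
    for (k in seq_len(K)) {
      for (j in (k + 1):n) {
        # last segment starts at t+1, previous part has k-1 changepoints
        t <- k:(j - 1)
        s <- cs[j + 1] - cs[t + 1]
        cand <- D[k, t] + (cs2[j + 1] - cs2[t + 1]) - s * s / (j - t)
        b <- which.min(cand)
        D[k + 1, j] <- cand[b]
        B[k + 1, j] <- t[b]
      }
    }
  }
  tot <- D[, n] + penalty * (0:K)
  kbest <- which.min(tot) - 1L
  if (kbest == 0L) return(integer())
  cps <- integer(kbest)
  j <- n
  for (k in kbest:1) {
    t <- B[k + 1, j]
    cps[k] <- t + 1L          # first index of the segment after the break
    j <- t
  }
  cps
}

#' Least-squares Gaussian fit of a rate segment
#'
#' Fits `a * exp(-(t - mu)^2 / (2 sigma^2))` to a rate segment by bounded
#' nonlinear least squares (`nls`, port algorithm). Initialization:
#' amplitude = max, mu = argmax, sigma = segment length / 4; bounds keep mu
#' inside the segment and sigma in [0.1, 10] s.
#'
#' @param t Bin-center times, seconds (>= 5 bins).
#' @param y Rate values, Hz.
#' @return Named numeric `c(amplitude, mean, sigma)`.
#' @export
fit_gaussian <- function(t, y) {
  if (length(t) < 5) stop("segment too short for a Gaussian fit",
                          call. = FALSE)
  if (all(y <= 0)) stop("all-zero segment; Gaussian fit undefined",
                        call. = FALSE)
  start <- list(a = max(y), mu = t[which.max(y)],
                sigma = max(0.1, (max(t) - min(t)) / 4))
  fit <- stats::nls(y ~ a * exp(-(t - mu)^2 / (2 * sigma^2)),
                    start = start, algorithm = "port",
                    lower = c(a = 1e-6, mu = min(t), sigma = 0.1),
                    upper = c(a = 2 * max(y) + 1, mu = max(t), sigma = 10),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = FALSE))
  cf <- stats::coef(fit)
  c(amplitude = unname(cf["a"]), mean = unname(cf["mu"]),
    sigma = unname(cf["sigma"]))
}

#' Detect the response peak of a single probe trial
#'
#' Implements the single-trial peak procedure: licks are aligned to the
#' trial's initiating reward and a 20-s analysis window starting at
#' `window_start` is binned (100-ms bins) and Gaussian-smoothed; the first
#' rising changepoint and the next falling changepoint delimit the candidate
#' peak; a Gaussian is fit to the smoothed rate between them and its mean
#' taken as the peak time. A valid peak must last at least 2 s and its
#' maximum smoothed rate must exceed 3 Hz. On failure the window is shifted
#' +500 ms and the procedure retried, up to 5 shifts, after which the trial
#' is discarded (`NULL` is returned). For trials with direct-pathway
#' stimulation at +3/+5 s the initial `window_start` should be 3/5 s, and
#' for rebound-recovery trials 6 s, to keep evoked/rebound licking out of
#' the peak (see [detect_session_peaks()]).
#'
#' @param licks A [lick_train()] or numeric lick times (absolute seconds).
#' @param align_time The initiating reward time, seconds.
#' @param window_start Start of the analysis window after `align_time`, s.
#' @param window_len Analysis window length, seconds.
#' @param shift_step,max_shifts Retry schedule on failure.
#' @param min_duration,min_rate Validity thresholds: minimum peak duration
#'   (s) and minimum peak smoothed rate (Hz).
#' @param bin_width,smoothing_sd Rate-trace parameters (see [rate_trace()]).
#' @param penalty Changepoint penalty (see [changepoints_mean()]).
#' @return A list of class `lick_peak` (fields `start`, `end`, `peak_time`,
#'   `amplitude`, `sigma`, `n_window_shifts_used`, `valid`; times relative
#'   to `align_time`), or `NULL` if no valid peak was found.
#' @export
detect_peak <- function(licks, align_time = 0, window_start = 0,
                        window_len = 20, shift_step = 0.5, max_shifts = 5,
                        min_duration = 2, min_rate = 3, bin_width = 0.1,
                        smoothing_sd = 0.25, penalty = NULL) {
  for (shift in 0:max_shifts) {
    ws <- window_start + shift * shift_step
    tr <- rate_trace(licks, align_time, window = c(ws, ws + window_len),
                     bin_width = bin_width, smoothing_sd = smoothing_sd)
    cand <- peak_candidate(tr, min_duration, min_rate, penalty)
    if (!is.null(cand)) {
      cand$n_window_shifts_used <- shift
      class(cand) <- "lick_peak"
      return(cand)
    }
  }
  NULL
}

# one window attempt: changepoints -> first rising + next falling ->
# validity -> Gaussian fit; NULL on any failure
peak_candidate <- function(tr, min_duration, min_rate, penalty) {
  cp <- changepoints_mean(tr$rate, penalty = penalty)
  if (nrow(cp) == 0) return(NULL)
  ri <- which(cp$direction == "rising")
  if (length(ri) == 0) return(NULL)
  i_rise <- cp$index[ri[1]]
  fa <- which(cp$direction == "falling" & cp$index > i_rise)
  if (length(fa) == 0) return(NULL)   # no falling changepoint: failure
  i_fall <- cp$index[fa[1]]
  start <- tr$bin_centers[i_rise]
  end <- tr$bin_centers[i_fall]
  seg <- i_rise:i_fall
  if (end - start < min_duration) return(NULL)
  if (max(tr$rate[seg]) <= min_rate) return(NULL)
  fit <- tryCatch(fit_gaussian(tr$bin_centers[seg], tr$rate[seg]),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(start = start, end = end, peak_time = unname(fit["mean"]),
       amplitude = unname(fit["amplitude"]), sigma = unname(fit["sigma"]),
       valid = TRUE)
}

#' @export
print.lick_peak <- function(x, ...) {
  cat(sprintf(
    "<lick_peak> t = %.2f s (start %.2f, end %.2f), %.1f Hz, %d shift(s)\n",
    x$peak_time, x$start, x$end, x$amplitude, x$n_window_shifts_used))
  invisible(x)
}

#' Detect peaks on every probe trial of a session
#'
#' Applies [detect_peak()] to each peak probe trial, aligning to the
#' initiating reward. With `window_start = "auto"`, stimulation trials with
#' a positive laser onset get their window start shifted right by the onset
#' (the +3/+5-s rule for direct-pathway trials), and trials listed in
#' `recovery_trials` use a 6-s shift (rebound-recovery rule).
#'
#' @param bundle A [session_bundle()].
#' @param window_start `"auto"` or a number applied to all trials.
#' @param recovery_trials Trial ids classified rebound-recovery, whose
#'   window starts at 6 s.
#' @param first_half If `TRUE`, restrict to the first half of trials first.
#' @param ... Passed to [detect_peak()].
#' @return A data.frame of class `lick_peaks`: one row per probe trial with
#'   the peak fields, `laser` flag, and `valid = FALSE` rows for discarded
#'   trials.
#' @export
detect_session_peaks <- function(bundle, window_start = "auto",
                                 recovery_trials = integer(),
                                 first_half = FALSE, ...) {
  if (first_half) bundle <- select_first_half(bundle)
  tt <- bundle$trials
  pk <- tt[tt$kind == "peak", , drop = FALSE]
  if (nrow(pk) == 0) stop("session has no peak probe trials", call. = FALSE)
  align <- align_times(tt)[tt$kind == "peak"]
  rows <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    ws <- if (identical(window_start, "auto")) {
      if (pk$trial_id[i] %in% recovery_trials) 6
      else if (!is.na(pk$laser_onset_rel[i]) && pk$laser_onset_rel[i] > 0)
        pk$laser_onset_rel[i]
      else 0
    } else window_start
    p <- detect_peak(bundle$licks, align[i], window_start = ws, ...)
    rows[[i]] <- data.frame(
      trial_id = pk$trial_id[i], align_time = align[i],
      laser = !is.na(pk$laser_onset_rel[i]), window_start = ws,
      start = if (is.null(p)) NA_real_ else p$start,
      end = if (is.null(p)) NA_real_ else p$end,
      peak_time = if (is.null(p)) NA_real_ else p$peak_time,
      amplitude = if (is.null(p)) NA_real_ else p$amplitude,
      sigma = if (is.null(p)) NA_real_ else p$sigma,
      n_window_shifts_used = if (is.null(p)) NA_integer_ else
        p$n_window_shifts_used,
      valid = !is.null(p))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lick_peaks", "data.frame")
  out
}

#' Session-level peak statistics
#'
#' Width = end - start per valid peak; mean peak time over valid trials;
#' skewness = sample third standardized moment of the pooled trial-relative
#' lick times falling inside each trial's detected [start, end]; peak shift
#' = mean laser-trial peak time minus mean no-laser peak time.
#'
#' @param peaks A [detect_session_peaks()] result.
#' @param licks The session's [lick_train()] (for the skewness pool).
#' @return A list of class `peak_session_stats`.
#' @export
peak_stats <- function(peaks, licks) {
  v <- peaks[peaks$valid, , drop = FALSE]
  if (nrow(v) == 0) stop("no valid peaks", call. = FALSE)
  widths <- v$end - v$start
  pool <- unlist(lapply(seq_len(nrow(v)), function(i) {
    x <- as.numeric(licks)
    sel <- x >= v$align_time[i] + v$start[i] &
      x <= v$align_time[i] + v$end[i]
    x[sel] - v$align_time[i]
  }))
  shift <- if (any(v$laser) && any(!v$laser)) {
    mean(v$peak_time[v$laser]) - mean(v$peak_time[!v$laser])
  } else NA_real_
  structure(list(
    mean_peak_time = mean(v$peak_time),
    peak_shift = shift,
    mean_width = mean(widths),
    skewness = skewness(pool),
    n_trials_used = nrow(v),
    n_discarded = sum(!peaks$valid)
  ), class = "peak_session_stats")
}

#' @export
print.peak_session_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<peak_session_stats> mean peak %.2f s, width %.2f s, skew %.3f",
    " (%d used, %d discarded)\n"),
    x$mean_peak_time, x$mean_width, x$skewness, x$n_trials_used,
    x$n_discarded))
  if (!is.na(x$peak_shift))
    cat(sprintf("  peak shift (laser - no laser): %.2f s\n", x$peak_shift))
  invisible(x)
}

# sample third standardized moment g1 = m3 / m2^(3/2)
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Peak shift as a function of stimulation onset
#'
#' For sessions with probe-trial stimulation at different onsets (0, +3,
#' +5 s after the initiating reward), computes the mean laser-trial peak
#' time minus the mean no-laser peak time per onset condition. Peak
#' analyses here use the entire session (not the first half) to maximize
#' statistical power.
#'
#' @param bundles List of [session_bundle()]s, one or more per onset
#'   condition.
#' @param ... Passed to [detect_session_peaks()].
#' @return A data.frame `stim_onset`, `shift`, `n_laser`, `n_nolaser`;
#'   conditions without matched laser/no-laser probe trials are omitted
#'   with a warning.
#' @export
peak_shift_curve <- function(bundles, ...) {
  if (inherits(bundles, "session_bundle")) bundles <- list(bundles)
  rows <- list()
  for (b in bundles) {
    pk <- detect_session_peaks(b, ...)
    tt <- b$trials
    onset <- unique(stats::na.omit(
      tt$laser_onset_rel[tt$kind == "peak"]))
    if (length(onset) == 0) next
    for (on in onset) {
      las <- pk$valid & pk$laser
      ctl <- pk$valid & !pk$laser
      if (!any(las) || !any(ctl)) {
        warning(sprintf(
          "onset %+g s: missing matched laser/no-laser peaks; omitted", on))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        stim_onset = on,
        shift = mean(pk$peak_time[las]) - mean(pk$peak_time[ctl]),
        n_laser = sum(las), n_nolaser = sum(ctl))
    }
  }
  if (length(rows) == 0)
    return(data.frame(stim_onset = numeric(), shift = numeric(),
                      n_laser = integer(), n_nolaser = integer()))
  out <- do.call(rbind, rows)
  stats::aggregate(cbind(shift, n_laser, n_nolaser) ~ stim_onset, out, mean)
}
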