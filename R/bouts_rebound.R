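# Bout-onset detection, stimulation-effect metrics (delta lick rate, evoked
# and rebound latencies, post-offset counts), rebound-trial classification,
# and the quartile (motivation) analysis.

#' Lick-bout onsets
#'
#' A bout onset is the first lick after an inter-lick interval of 1 s or
#' greater; the session's first lick is always an onset (no preceding
#' interval exists).
#'
#' @param licks A [lick_train()] or sorted numeric lick times.
#' @param min_gap Minimum preceding gap defining an onset, seconds.
#' @return Numeric vector of onset times (a subset of the lick times).
#' @export
bout_onsets <- function(licks, min_gap = 1) {
  x <- as.numeric(licks)
  if (length(x) == 0) return(numeric())
  x[c(TRUE, diff(x) >= min_gap)]
}

# first onset inside [lo, hi] (closed), or NA
first_onset_in <- function(onsets, lo, hi) {
  hit <- onsets[onsets >= lo & onsets <= hi]
  if (length(hit) == 0) NA_real_ else hit[1]
}

# mean lick rate (raw count / duration) in the absolute window [lo, hi)
window_rate <- function(licks, lo, hi) {
  x <- as.numeric(licks)
  sum(x >= lo & x < hi) / (hi - lo)
}

# matched no-laser windows: same trial-relative offsets on no-laser trials
# of the same kind as the laser trials
matched_windows <- function(trials, rel_lo, rel_hi, kind) {
  ctl <- trials$kind == kind & is.na(trials$laser_onset_rel)
  a <- align_times(trials)[ctl]
  data.frame(trial_id = trials$trial_id[ctl], lo = a + rel_lo,
             hi = a + rel_hi)
}

# a session may stimulate both fixed and probe trials (at different
# onsets); stimulation metrics compare like with like, so restrict to the
# condition of the first laser trial: returns its laser windows plus the
# defining (kind, onset, duration)
stim_condition <- function(trials) {
  lw <- laser_windows(trials)
  if (nrow(lw) == 0) stop("session has no laser trials", call. = FALSE)
  i <- match(lw$trial_id, trials$trial_id)
  kind <- trials$kind[i]
  onset <- trials$laser_onset_rel[i]
  sel <- kind == kind[1] & abs(onset - onset[1]) < 1e-9
  list(lw = lw[sel, , drop = FALSE], kind = kind[1], rel_lo = onset[1],
       rel_hi = onset[1] + trials$laser_duration[i][1])
}

#' Stimulation-induced change in lick rate
#'
#' Lick rate during each trial's laser window (raw count over the window)
#' minus the mean rate over the identical trial-relative window on the
#' session's matched no-laser trials of the same kind. Sessions mixing
#' stimulation conditions are restricted to the condition of the first
#' laser trial.
#'
#' @param bundle A [session_bundle()] with laser and matched no-laser
#'   trials.
#' @return A list with `per_trial` (data.frame `trial_id`, `rate`,
#'   `delta_rate`), `baseline_rate` (Hz) and `mean_delta` (Hz).
#' @export
delta_lick_rate <- function(bundle) {
  tt <- bundle$trials
  sc <- stim_condition(tt)
  lw <- sc$lw
  mw <- matched_windows(tt, sc$rel_lo, sc$rel_hi, sc$kind)
  if (nrow(mw) == 0)
    stop("no matched no-laser trials for the baseline", call. = FALSE)
  base <- mean(vapply(seq_len(nrow(mw)), function(k)
    window_rate(bundle$licks, mw$lo[k], mw$hi[k]), 0))
  rate <- vapply(seq_len(nrow(lw)), function(k)
    window_rate(bundle$licks, lw$on[k], lw$off[k]), 0)
  per_trial <- data.frame(trial_id = lw$trial_id, rate = rate,
                          delta_rate = rate - base)
  list(per_trial = per_trial, baseline_rate = base,
       mean_delta = mean(per_trial$delta_rate))
}

#' Latency to the first evoked lick-bout onset
#'
#' First bout onset within the laser train, per stimulation trial; trials
#' without an onset in the window are excluded (latency `NA`).
#'
#' @param bundle A [session_bundle()].
#' @return data.frame `trial_id`, `latency` (s after laser onset, `NA` if
#'   no onset during the train).
#' @export
evoke_latency <- function(bundle) {
  lw <- stim_condition(bundle$trials)$lw
  onsets <- bout_onsets(bundle$licks)
  lat <- vapply(seq_len(nrow(lw)), function(k) {
    o <- first_onset_in(onsets, lw$on[k], lw$off[k])
    o - lw$on[k]
  }, 0)
  data.frame(trial_id = lw$trial_id, latency = lat)
}

#' Rebound lick-onset latency after laser offset
#'
#' First bout onset in the closed window [offset, offset + 3 s] after each
#' laser train, and the same trial-relative window on matched no-laser
#' trials for the within-session baseline. Trials without an onset in the
#' window are excluded (`NA`).
#'
#' @param bundle A [session_bundle()].
#' @param window Search window after offset, seconds.
#' @return A list with `per_trial` (laser trials), `baseline` (no-laser
#'   trials), and `variance` (sample variance of the non-missing laser
#'   latencies).
#' @export
rebound_latency <- function(bundle, window = 3) {
  tt <- bundle$trials
  sc <- stim_condition(tt)
  lw <- sc$lw
  onsets <- bout_onsets(bundle$licks)
  lat <- vapply(seq_len(nrow(lw)), function(k) {
    o <- first_onset_in(onsets, lw$off[k], lw$off[k] + window)
    o - lw$off[k]
  }, 0)
  mw <- matched_windows(tt, sc$rel_hi, sc$rel_hi + window, sc$kind)
  blat <- vapply(seq_len(nrow(mw)), function(k) {
    o <- first_onset_in(onsets, mw$lo[k], mw$hi[k])
    o - mw$lo[k]
  }, 0)
  list(per_trial = data.frame(trial_id = lw$trial_id, latency = lat),
       baseline = data.frame(trial_id = mw$trial_id, latency = blat),
       variance = stats::var(lat[!is.na(lat)]))
}

#' Lick count in the 1 s after laser offset
#'
#' @param bundle A [session_bundle()].
#' @param window Count window after offset, seconds.
#' @return A list with `per_trial` (laser trials, integer `count`) and
#'   `baseline` (no-laser trials, identical trial-relative window).
#' @export
post_offset_count <- function(bundle, window = 1) {
  tt <- bundle$trials
  sc <- stim_condition(tt)
  lw <- sc$lw
  x <- as.numeric(bundle$licks)
  cnt <- vapply(seq_len(nrow(lw)), function(k)
    as.numeric(sum(x >= lw$off[k] & x <= lw$off[k] + window)), 0)
  mw <- matched_windows(tt, sc$rel_hi, sc$rel_hi + window, sc$kind)
  bcnt <- vapply(seq_len(nrow(mw)), function(k)
    as.numeric(sum(x >= mw$lo[k] & x <= mw$hi[k])), 0)
  list(per_trial = data.frame(trial_id = lw$trial_id, count = as.integer(cnt)),
       baseline = data.frame(trial_id = mw$trial_id,
                             count = as.integer(bcnt)))
}

#' Classify one rebound probe trial
#'
#' Rule for probe trials with indirect-pathway stimulation mid-interval:
#' a trial with no bout onset in the closed 2-s window after stimulation
#' onset is `no_rebound`; otherwise, if a second onset follows within the
#' half-open window (rebound onset, rebound onset + 8 s] the trial is
#' `recovery` (rebound then a separate peak bout); otherwise `initiation`
#' (the rebound merges into the peak; also called rebound absorption).
#'
#' @param onsets Bout-onset times (see [bout_onsets()]), absolute seconds.
#' @param stim_on Stimulation onset, absolute seconds.
#' @param rebound_window Onset search window after `stim_on`, seconds.
#' @param second_window Second-onset window after the rebound onset, s.
#' @return `"recovery"`, `"initiation"`, or `"no_rebound"`.
#' @export
classify_rebound_trial <- function(onsets, stim_on, rebound_window = 2,
                                   second_window = 8) {
  r <- first_onset_in(onsets, stim_on, stim_on + rebound_window)
  if (is.na(r)) return("no_rebound")
  second <- onsets[onsets > r & onsets <= r + second_window]
  if (length(second) > 0) "recovery" else "initiation"
}

#' Classify all rebound probe trials of a session
#'
#' @param bundle A [session_bundle()] whose laser probe trials carry
#'   mid-interval (positive-onset) stimulation.
#' @return data.frame `trial_id`, `stim_on`, `label`; labels are the
#'   [classify_rebound_trial()] classes.
#' @export
classify_rebound <- function(bundle) {
  tt <- bundle$trials
  sel <- tt$kind == "peak" & !is.na(tt$laser_onset_rel)
  if (!any(sel))
    stop("no stimulated probe trials to classify", call. = FALSE)
  if (any(tt$laser_onset_rel[sel] <= 0))
    stop("rebound classification requires mid-interval (positive-onset) stimulation",
         call. = FALSE)
  a <- align_times(tt)[sel]
  on <- a + tt$laser_onset_rel[sel]
  onsets <- bout_onsets(bundle$licks)
  lab <- vapply(on, function(s) classify_rebound_trial(onsets, s), "")
  data.frame(trial_id = tt$trial_id[sel], stim_on = on, label = lab,
             stringsAsFactors = FALSE)
}

#' Quartile (motivation) analysis of stimulation effects
#'
#' Laser trials are split into four ordinal quartiles by presentation order
#' (the full session is used, never the first-half selection) and the chosen
#' metric aggregated per quartile, exposing satiety-related drift.
#'
#' @param bundle A [session_bundle()] with >= 4 laser trials.
#' @param metric One of `"delta_rate"`, `"evoke_latency"`,
#'   `"rebound_latency"`.
#' @return data.frame `quartile`, `n`, `mean`, `sd` (missing latencies are
#'   dropped within quartile).
#' @export
quartile_analysis <- function(bundle,
                              metric = c("delta_rate", "evoke_latency",
                                         "rebound_latency")) {
  metric <- match.arg(metric)
  tt <- bundle$trials
  nlaser <- sum(!is.na(tt$laser_onset_rel))
  if (nlaser < 4) stop("need >= 4 laser trials", call. = FALSE)
  vals <- switch(metric,
    delta_rate = delta_lick_rate(bundle)$per_trial[, c("trial_id",
                                                       "delta_rate")],
    evoke_latency = evoke_latency(bundle),
    rebound_latency = rebound_latency(bundle)$per_trial)
  names(vals)[2] <- "value"
  # presentation order of laser trials
  q <- as.integer(cut(seq_len(nrow(vals)), breaks = 4, labels = FALSE))
  out <- do.call(rbind, lapply(1:4, function(k) {
    v <- vals$value[q == k]
    v <- v[!is.na(v)]
    data.frame(quartile = k, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out
}

#' Rebound-class fractions per session half
#'
#' @param labels Character vector of [classify_rebound_trial()] labels in
#'   trial presentation order (the alias `"absorption"` is accepted for
#'   `"initiation"`).
#' @return data.frame `half`, `label`, `fraction`; fractions sum to 1
#'   within each half.
#' @export
rebound_session_half_fractions <- function(labels) {
  labels[labels == "absorption"] <- "initiation"
  lv <- c("recovery", "initiation", "no_rebound")
  if (!all(labels %in% lv))
    stop("unknown rebound label(s)", call. = FALSE)
  n <- length(labels)
  cut1 <- ceiling(n / 2)
  halves <- list(`1` = labels[seq_len(cut1)],
                 `2` = labels[setdiff(seq_len(n), seq_len(cut1))])
  if (any(vapply(halves, length, 0L) < 2))
    stop("need >= 2 classified trials per session half", call. = FALSE)
  do.call(rbind, lapply(names(halves), function(h) {
    tab <- table(factor(halves[[h]], levels = lv))
    data.frame(half = as.integer(h), label = lv,
               fraction = as.numeric(tab) / length(halves[[h]]))
  }))
}
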