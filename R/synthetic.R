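# Synthetic session generator: task scheduler, naturalistic bout-level
# licking, and injectable optogenetic stimulation effects. Every downstream
# analysis is testable against the ground truth this module records.

#' Task scheduler parameters
#'
#' Defaults encode the fixed-time task: a 10-s reward interval; after three
#' consecutive plain fixed trials a decision point is entered, drawing
#' laser-on-normal / laser-on-peak / plain-peak with probability 0.3 each
#' and re-entering the decision with probability 0.1; peak probe spans are
#' 30 s plus a Gamma(shape 2.5, scale 4) excess (mean 10 s).
#'
#' @param interval Fixed reward interval, seconds.
#' @param n_trials Number of trials to schedule.
#' @param p_laser_normal,p_laser_peak,p_peak_plain Decision-point outcome
#'   probabilities; with `p_redraw` they must sum to 1.
#' @param p_redraw Probability that a decision point is redrawn.
#' @param probe_base Minimum probe span, seconds.
#' @param probe_gamma_shape,probe_gamma_scale Gamma parameters of the probe
#'   excess duration.
#' @param stim_onset_normal Laser onset relative to reward on stimulated
#'   fixed trials, seconds (negative = before reward).
#' @param stim_onset_peak Laser onset relative to the initiating reward on
#'   stimulated probe trials, seconds.
#' @param laser_frequency Laser pulse frequency, Hz (0/5/10/25/50).
#' @param laser_duration Laser train duration, seconds.
#' @param seed Integer seed; the scheduler is deterministic given it.
#' @return A list of class `task_params`.
#' @export
task_params <- function(interval = 10, n_trials = 100,
                        p_laser_normal = 0.3, p_laser_peak = 0.3,
                        p_peak_plain = 0.3, p_redraw = 0.1,
                        probe_base = 30, probe_gamma_shape = 2.5,
                        probe_gamma_scale = 4,
                        stim_onset_normal = -1, stim_onset_peak = 5,
                        laser_frequency = 25, laser_duration = 1,
                        seed = 1L) {
  if (abs(p_laser_normal + p_laser_peak + p_peak_plain + p_redraw - 1) > 1e-9)
    stop("decision probabilities must sum to 1", call. = FALSE)
  if (probe_gamma_shape <= 0 || probe_gamma_scale <= 0)
    stop("gamma shape and scale must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "task_params")
}

#' Simulate the trial scheduler
#'
#' Blocks of three plain fixed-time trials are followed by a decision point
#' drawn 0.3/0.3/0.3 (laser-normal / laser-peak / plain-peak) with a 0.1
#' redraw; probe spans are `probe_base + Gamma(shape, scale)`. The
#' consecutive-reward counter resets after every decision-outcome trial
#' (including each peak trial's terminal reward), so no two decision
#' outcomes are adjacent.
#'
#' @param task A [task_params()] object.
#' @return A [trial_table()] of `task$n_trials` trials.
#' @export
simulate_scheduler <- function(task = task_params()) {
  stopifnot(inherits(task, "task_params"))
  set.seed(task$seed)
  n <- task$n_trials
  kind <- character(n); reward <- numeric(n)
  l_on <- rep(NA_real_, n); l_dur <- rep(NA_real_, n)
  l_freq <- rep(NA_real_, n); probe <- rep(NA_real_, n)
  t <- 0; counter <- 0L
  p_out <- c(task$p_laser_normal, task$p_laser_peak, task$p_peak_plain)
  for (i in seq_len(n)) {
    if (counter < 3L) {
      kind[i] <- "fixed"; t <- t + task$interval; reward[i] <- t
      counter <- counter + 1L
    } else {
      outcome <- draw_decision(p_out, task$p_redraw)
      if (outcome == 1L) {             # laser on a normal trial
        kind[i] <- "fixed"; t <- t + task$interval; reward[i] <- t
        l_on[i] <- task$stim_onset_normal
        l_dur[i] <- task$laser_duration; l_freq[i] <- task$laser_frequency
      } else {                         # peak probe, with or without laser
        kind[i] <- "peak"
        probe[i] <- task$probe_base +
          stats::rgamma(1, shape = task$probe_gamma_shape,
                        scale = task$probe_gamma_scale)
        t <- t + probe[i]; reward[i] <- t
        if (outcome == 2L) {
          l_on[i] <- task$stim_onset_peak
          l_dur[i] <- task$laser_duration; l_freq[i] <- task$laser_frequency
        }
      }
      counter <- 0L
    }
  }
  trial_table(seq_len(n), reward, kind, l_on, l_dur, l_freq, probe)
}

# one decision point: outcomes 1..3 with probabilities p_out, redraw with
# prob 1 - sum(p_out); returns the first non-redraw outcome
draw_decision <- function(p_out, p_redraw) {
  repeat {
    u <- stats::runif(1)
    cs <- cumsum(p_out)
    if (u < cs[1]) return(1L)
    if (u < cs[2]) return(2L)
    if (u < cs[3]) return(3L)
    # else redraw
  }
}

#' Naturalistic licking-model parameters
#'
#' Licking is modeled as a bout-level renewal process: a jittered metronome
#' inside bouts (anticipatory ~5.5 Hz, consummatory ~7 Hz, matching the
#' 4-8 Hz rhythmic licking of mice), bout onsets tied to task events.
#' Anticipatory bouts start `|Normal(anticipation_onset_mean, sd)|` seconds
#' before each fixed-trial reward; a consummatory bout follows every reward;
#' probe trials get a peak bout centered `Normal(peak_bout_center,
#' peak_center_sd)` seconds after the initiating reward. Within-bout
#' inter-lick intervals are `1/frequency + Normal(0, ili_jitter_sd)`,
#' truncated at 0.05 s (the 10 Hz biological cap). Sparse baseline licks
#' fill the mid-interval at `baseline_rate`.
#'
#' @param bout_frequency Anticipatory/peak bout lick rate, Hz.
#' @param consummatory_frequency Consummatory bout lick rate, Hz.
#' @param ili_jitter_sd SD of within-bout inter-lick-interval jitter, s.
#' @param anticipation_onset_mean,anticipation_onset_sd Anticipatory bout
#'   onset before reward, seconds (folded normal).
#' @param consummatory_duration Consummatory bout length, seconds.
#' @param peak_bout_center Mean probe-bout center after the initiating
#'   reward, seconds (defaults to the trained 10-s interval).
#' @param peak_center_sd Trial-to-trial SD of the probe-bout center, s.
#' @param peak_bout_halfwidth Probe bout half-length, seconds.
#' @param baseline_rate Sparse lick rate between bouts, Hz.
#' @param satiety_slope Per-trial linear drift multiplier applied to
#'   stimulation-response latencies and to rebound-bout probability
#'   (0 = stationary session).
#' @param seed Integer master seed; per-trial substreams are derived from it.
#' @return A list of class `lick_model_params`.
#' @export
lick_model_params <- function(bout_frequency = 5.5,
                              consummatory_frequency = 7,
                              ili_jitter_sd = 0.01,
                              anticipation_onset_mean = 3,
                              anticipation_onset_sd = 1,
                              consummatory_duration = 2,
                              peak_bout_center = 10,
                              peak_center_sd = 1,
                              peak_bout_halfwidth = 2,
                              baseline_rate = 0.2,
                              satiety_slope = 0,
                              seed = 1L) {
  if (bout_frequency <= 0 || bout_frequency > 12 ||
      consummatory_frequency <= 0 || consummatory_frequency > 12)
    stop("bout frequencies must lie in (0, 12] Hz", call. = FALSE)
  if (ili_jitter_sd < 0 || peak_center_sd < 0 || anticipation_onset_sd < 0)
    stop("sds must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "lick_model_params")
}

#' Stimulation-effect parameters
#'
#' Injectable optogenetic effects. `d1_evoke` (direct pathway) evokes a
#' lick bout during the laser train at a frequency given by
#' `evoked_frequency_map` (capped at 10 Hz), with onset latency from
#' `evoke_latency_map`, persisting `post_offset_persist` seconds beyond
#' laser offset. `a2a_suppress` (indirect pathway) suppresses licking
#' during the train and produces a rebound bout after offset with latency
#' from `rebound_latency_map`. `timing_mode` controls the effect on the
#' internal clock during probe trials: `reset` re-centers the peak bout at
#' stimulation onset + the trained interval; `pause` delays it by the
#' stimulation duration (plus the rebound duration in
#' `pause_plus_rebound`).
#'
#' @param mode `"d1_evoke"`, `"a2a_suppress"`, or `"none"`.
#' @param evoked_frequency_map Named numeric, stimulation Hz -> evoked lick
#'   Hz (values must be <= 10).
#' @param evoke_latency_mean,evoke_latency_sd Named numeric maps,
#'   stimulation Hz -> evoked-bout onset latency mean/sd, seconds.
#' @param post_offset_persist Seconds evoked licking persists past laser
#'   offset.
#' @param rebound_latency_mean,rebound_latency_sd Named numeric maps,
#'   stimulation Hz -> rebound onset latency mean/sd after offset, seconds.
#' @param rebound_duration Rebound bout length, seconds.
#' @param rebound_prob Baseline probability that a rebound bout occurs.
#' @param timing_mode One of `"none"`, `"reset"`, `"pause"`,
#'   `"pause_plus_rebound"`.
#' @return A list of class `stim_effect_params`.
#' @export
stim_effect_params <- function(mode = c("none", "d1_evoke", "a2a_suppress"),
                               evoked_frequency_map =
                                 c(`5` = 6, `10` = 9, `25` = 10, `50` = 10),
                               evoke_latency_mean =
                                 c(`5` = 0.6, `10` = 0.45, `25` = 0.3,
                                   `50` = 0.2),
                               evoke_latency_sd = 0.05,
                               post_offset_persist = 0.5,
                               rebound_latency_mean =
                                 c(`5` = 1.0, `10` = 0.7, `25` = 0.5,
                                   `50` = 0.35),
                               rebound_latency_sd = 0.1,
                               rebound_duration = 1.5,
                               rebound_prob = 0.95,
                               timing_mode = c("none", "reset", "pause",
                                               "pause_plus_rebound")) {
  mode <- match.arg(mode)
  timing_mode <- match.arg(timing_mode)
  if (any(evoked_frequency_map > 10))
    stop("evoked lick frequencies are capped at 10 Hz", call. = FALSE)
  if (any(evoke_latency_mean < 0) || any(rebound_latency_mean < 0))
    stop("latencies must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "stim_effect_params")
}

freq_lookup <- function(map, f) {
  if (length(map) == 1 && is.null(names(map))) return(unname(map))
  key <- as.character(f)
  if (key %in% names(map)) return(unname(map[key]))
  # linear interpolation for off-grid stimulation frequencies
  ks <- as.numeric(names(map))
  stats::approx(ks, map, xout = f, rule = 2)$y
}

# jittered-metronome bout: licks from start to end at `freq` Hz, ILIs
# truncated at `min_ili` (0.05 s default; 0.1 s for stimulation-evoked
# bouts so instantaneous rates honor the 10 Hz cap)
metronome_bout <- function(start, end, freq, jitter_sd, min_ili = 0.05) {
  if (end <= start) return(numeric())
  out <- numeric(ceiling((end - start) * freq) + 2)
  t <- start; k <- 0L
  while (t <= end) {
    k <- k + 1L; out[k] <- t
    t <- t + max(min_ili, 1 / freq + stats::rnorm(1, 0, jitter_sd))
  }
  out[seq_len(k)]
}

#' Simulate licking for a scheduled session
#'
#' Generates a full synthetic session: naturalistic bouts tied to the trial
#' structure, plus injected stimulation effects, as described in
#' [lick_model_params()] and [stim_effect_params()]. The ground truth used
#' by each trial (true bout onsets, true peak centers, true latencies) is
#' recorded for parameter-recovery tests and retrievable with
#' [ground_truth()].
#'
#' @param trials A [trial_table()], e.g. from [simulate_scheduler()].
#' @param lick A [lick_model_params()] object.
#' @param stim A [stim_effect_params()] object.
#' @param interval Trained task interval, seconds (the clock that `reset`
#'   restarts).
#' @param metadata Extra metadata stored on the bundle.
#' @return A [session_bundle()] carrying a `ground_truth` attribute.
#' @export
simulate_licking <- function(trials, lick = lick_model_params(),
                             stim = stim_effect_params(),
                             interval = 10, metadata = list()) {
  stopifnot(inherits(trials, "trial_table"),
            inherits(lick, "lick_model_params"),
            inherits(stim, "stim_effect_params"))
  set.seed(lick$seed)
  n <- nrow(trials)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
  align <- align_times(trials)
  lw_on <- align + trials$laser_onset_rel
  lw_off <- lw_on + trials$laser_duration

  licks <- vector("list", n)
  gt <- data.frame(trial_id = trials$trial_id, kind = trials$kind,
                   bout_onset = rep(NA_real_, n),
                   peak_center = rep(NA_real_, n),
                   evoke_latency = rep(NA_real_, n),
                   rebound_latency = rep(NA_real_, n),
                   suppressed = rep(FALSE, n),
                   timing_mode = rep(stim$timing_mode, n),
                   stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    set.seed(trial_seeds[i])
    sat <- 1 + lick$satiety_slope * (i - 1)   # motivational drift multiplier
    R <- trials$reward_time[i]
    A <- align[i]
    t0 <- if (i == 1) 0 else trials$reward_time[i - 1]
    tl <- list()

    if (trials$kind[i] == "fixed") {
      onset <- R - abs(stats::rnorm(1, lick$anticipation_onset_mean,
                                    lick$anticipation_onset_sd))
      onset <- max(onset, t0)
      gt$bout_onset[i] <- onset
      tl$antic <- metronome_bout(onset, R, lick$bout_frequency,
                                 lick$ili_jitter_sd)
    } else {
      center <- A + stats::rnorm(1, lick$peak_bout_center,
                                 lick$peak_center_sd)
      haslaser <- !is.na(trials$laser_onset_rel[i])
      if (haslaser && stim$timing_mode == "reset") {
        center <- lw_on[i] + interval +
          stats::rnorm(1, 0, lick$peak_center_sd)
      } else if (haslaser && stim$timing_mode %in%
                 c("pause", "pause_plus_rebound")) {
        center <- center + trials$laser_duration[i] + stim$rebound_duration
      }
      gt$peak_center[i] <- center - A
      tl$peak <- metronome_bout(center - lick$peak_bout_halfwidth,
                                center + lick$peak_bout_halfwidth,
                                lick$bout_frequency, lick$ili_jitter_sd)
      gt$bout_onset[i] <- center - lick$peak_bout_halfwidth
    }

    # consummatory bout follows every delivered reward
    tl$cons <- metronome_bout(R, R + lick$consummatory_duration,
                              lick$consummatory_frequency,
                              lick$ili_jitter_sd)

    # sparse baseline licking over the trial span
    if (lick$baseline_rate > 0) {
      span <- R - t0
      nb <- stats::rpois(1, lick$baseline_rate * span)
      if (nb > 0) tl$base <- sort(stats::runif(nb, t0, R))
    }

    # stimulation effects
    if (!is.na(trials$laser_onset_rel[i]) && stim$mode != "none") {
      f <- trials$laser_frequency[i]
      on <- lw_on[i]; off <- lw_off[i]
      if (stim$mode == "d1_evoke") {
        lat <- abs(stats::rnorm(1, freq_lookup(stim$evoke_latency_mean, f) *
                                  sat, freq_lookup(stim$evoke_latency_sd, f)))
        gt$evoke_latency[i] <- lat
        ef <- min(10, freq_lookup(stim$evoked_frequency_map, f))
        # evoked licking replaces natural licking within the train
        tl <- lapply(tl, function(v) v[v < on | v > off])
        tl$evoked <- metronome_bout(on + lat,
                                    off + stim$post_offset_persist, ef,
                                    lick$ili_jitter_sd, min_ili = 0.1)
      } else if (stim$mode == "a2a_suppress") {
        tl <- lapply(tl, function(v) v[v < on | v > off])
        gt$suppressed[i] <- TRUE
        p_reb <- min(1, stim$rebound_prob / sat)
        if (stats::runif(1) < p_reb) {
          lat <- abs(stats::rnorm(1,
                                  freq_lookup(stim$rebound_latency_mean, f) *
                                    sat,
                                  freq_lookup(stim$rebound_latency_sd, f)))
          gt$rebound_latency[i] <- lat
          tl$rebound <- metronome_bout(off + lat,
                                       off + lat + stim$rebound_duration,
                                       lick$bout_frequency,
                                       lick$ili_jitter_sd)
        }
      }
    }
    licks[[i]] <- sort(unlist(tl, use.names = FALSE))
  }

  all_licks <- sort(unlist(licks, use.names = FALSE))
  all_licks <- all_licks[all_licks >= 0]
  lt <- filter_licks(all_licks)
  meta <- c(list(interval = interval, synthetic = TRUE), metadata)
  bundle <- session_bundle(lt, trials, meta)
  attr(bundle, "ground_truth") <- gt
  bundle
}

#' Per-trial ground truth of a synthetic session
#'
#' @param bundle A [session_bundle()] produced by [simulate_licking()].
#' @return The per-trial truth table: true bout onsets, true peak centers
#'   (relative to the initiating reward), true evoked/rebound latencies,
#'   suppression flags and the timing mode.
#' @export
ground_truth <- function(bundle) {
  gt <- attr(bundle, "ground_truth")
  if (is.null(gt) || !isTRUE(bundle$metadata$synthetic))
    stop("ground truth is only available for synthetic bundles",
         call. = FALSE)
  gt
}
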