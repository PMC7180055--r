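# Leaky-integrator / central-pattern-generator simulator: basal-ganglia
# output modeled as a leaky integrator filled by direct-pathway pulses and
# discharged by indirect-pathway pulses, gating a discrete-mode lick
# pattern generator capped at 10 Hz, with a hyperpolarization-driven
# rebound burst on release from sustained indirect-pathway drive.

#' Integrator-CPG parameters
#'
#' The integrator level I obeys `dI/dt = -leak_rate * I` between pulses;
#' each direct-pathway (D1) pulse adds `fill_gain`, each indirect-pathway
#' (A2A) pulse subtracts `discharge_gain`, and I is clipped at 0. Three
#' thresholds map the level to discrete CPG modes (off / low / mid / high)
#' emitting rhythmic licks at `mode_frequencies`, hard-capped at `cap` Hz.
#' Sustained A2A drive charges a hyperpolarization variable H
#' (`dH/dt = -rebound_decay * H` plus `rebound_gain` per pulse); at drive
#' offset a rebound burst is injected into I after a latency
#' `rebound_latency_scale / (1 + H)` - so more accumulated charge means an
#' earlier rebound.
#'
#' All constants are free parameters of the conceptual model; the defaults
#' are calibrated so that a 1-s pulse train reproduces the qualitative
#' phenomena: faster filling and earlier lick onset at higher stimulation
#' frequency, longer post-offset persistence, output saturating at the
#' 10-Hz cap, and rebound latency decreasing with stimulation frequency.
#'
#' @param fill_gain Level units added per D1 pulse.
#' @param discharge_gain Level units removed per A2A pulse.
#' @param leak_rate Integrator leak, per second.
#' @param thresholds Increasing triple (theta1, theta2, theta3) mapping
#'   level to modes off / low / mid / high.
#' @param mode_frequencies Lick rate per mode, Hz (all <= `cap`).
#' @param cap Hard ceiling on emitted lick frequency, Hz.
#' @param rebound_gain Hyperpolarization charge per A2A pulse.
#' @param rebound_decay Hyperpolarization decay, per second.
#' @param rebound_latency_scale Seconds; rebound latency =
#'   scale / (1 + H at offset).
#' @param rebound_boost Level injected at rebound = boost * H at offset.
#' @param dt Simulation step, seconds (must be <= 0.01).
#' @return A list of class `cpg_params`.
#' @export
cpg_params <- function(fill_gain = 0.2, discharge_gain = 0.2,
                       leak_rate = 1, thresholds = c(0.3, 0.35, 2.5),
                       mode_frequencies = c(5, 7, 9.5), cap = 10,
                       rebound_gain = 0.15, rebound_decay = 2,
                       rebound_latency_scale = 1, rebound_boost = 1,
                       dt = 0.001) {
  if (dt > 0.01) stop("dt too coarse: must be <= 0.01 s", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!(thresholds[1] < thresholds[2] && thresholds[2] < thresholds[3]))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (any(mode_frequencies > cap))
    stop("mode frequencies must not exceed the cap", call. = FALSE)
  structure(as.list(environment()), class = "cpg_params")
}

#' Regular pulse train
#'
#' @param frequency Pulse frequency, Hz.
#' @param start Train onset, seconds.
#' @param duration Train duration, seconds.
#' @return Pulse times in `[start, start + duration)`.
#' @export
pulse_train <- function(frequency, start = 0, duration = 1) {
  if (frequency <= 0 || duration <= 0) return(numeric())
  start + seq(0, duration - 1e-12, by = 1 / frequency)
}

#' Simulate the integrator-CPG model
#'
#' Discrete-time simulation on a `dt` grid. Between pulses the level and
#' hyperpolarization decay by the exact exponential factor
#' `exp(-rate * dt)`, so the free decay phase matches the closed-form
#' solution to machine precision; pulses act as impulses. Licks are emitted
#' by a metronome re-phased at every mode transition (an immediate lick at
#' mode entry, then one per `1/mode_frequency`), with a hard refractory
#' floor of `1/cap` between consecutive licks.
#'
#' @param d1_pulses,a2a_pulses Pulse times, seconds (see [pulse_train()]).
#' @param duration Total simulated time, seconds.
#' @param params A [cpg_params()] object.
#' @return An object of class `cpg_sim`: `time`, `level`, `hyper`, `mode`
#'   (0 = off), `licks` (emitted lick times), `rebound_onset` (NA if no
#'   rebound was triggered), `params`.
#' @export
simulate_cpg <- function(d1_pulses = numeric(), a2a_pulses = numeric(),
                         duration = 5, params = cpg_params()) {
  stopifnot(inherits(params, "cpg_params"))
  if ((length(d1_pulses) && (min(d1_pulses) < 0 ||
                             max(d1_pulses) > duration)) ||
      (length(a2a_pulses) && (min(a2a_pulses) < 0 ||
                              max(a2a_pulses) > duration)))
    stop("protocol pulse times must lie within the simulation span",
         call. = FALSE)
  dt <- params$dt
  n <- ceiling(duration / dt) + 1L
  tgrid <- (seq_len(n) - 1) * dt
  decayI <- exp(-params$leak_rate * dt)
  decayH <- exp(-params$rebound_decay * dt)
  # impulse counts per step
  d1c <- tabulate(pmin(n, floor(d1_pulses / dt) + 1L), nbins = n)
  a2c <- tabulate(pmin(n, floor(a2a_pulses / dt) + 1L), nbins = n)
  a2a_off <- if (length(a2a_pulses)) max(a2a_pulses) + dt else NA_real_

  level <- numeric(n); hyper <- numeric(n); mode <- integer(n)
  licks <- numeric(n); nl <- 0L
  I <- 0; H <- 0
  cur_mode <- 0L; next_lick <- Inf; last_lick <- -Inf
  t_reb <- NA_real_; reb_pending <- !is.na(a2a_off)
  reb_onset_rec <- NA_real_; reb_boost <- 0

  th <- params$thresholds
  mf <- params$mode_frequencies
  min_ili <- 1 / params$cap

  for (k in seq_len(n)) {
    t <- tgrid[k]
    if (k > 1) {
      I <- I * decayI
      H <- H * decayH
    }
    I <- I + params$fill_gain * d1c[k] - params$discharge_gain * a2c[k]
    if (I < 0) I <- 0
    H <- H + params$rebound_gain * a2c[k]
    # at A2A offset, schedule the rebound burst from the accumulated charge
    if (reb_pending && t >= a2a_off) {
      t_reb <- a2a_off + params$rebound_latency_scale / (1 + H)
      reb_onset_rec <- t_reb
      reb_boost <- params$rebound_boost * H
      reb_pending <- FALSE
    }
    if (!is.na(t_reb) && t >= t_reb) {
      I <- I + reb_boost
      t_reb <- NA_real_
    }
    m <- sum(I >= th)
    if (m != cur_mode) {
      # re-phase the metronome: a fresh bout licks immediately; a mode
      # switch within a bout keeps phase but adopts the new period
      next_lick <- if (m == 0L) Inf
      else if (cur_mode == 0L) t
      else min(next_lick, max(t, last_lick + 1 / mf[m]))
      cur_mode <- m
    }
    if (cur_mode > 0L && t >= next_lick) {
      if (t - last_lick >= min_ili) {
        nl <- nl + 1L
        licks[nl] <- t
        last_lick <- t
        next_lick <- t + 1 / mf[cur_mode]
      } else {
        next_lick <- last_lick + min_ili
      }
    }
    level[k] <- I; hyper[k] <- H; mode[k] <- m
  }
  structure(list(time = tgrid, level = level, hyper = hyper, mode = mode,
                 licks = licks[seq_len(nl)],
                 rebound_onset = reb_onset_rec,
                 d1_pulses = d1_pulses, a2a_pulses = a2a_pulses,
                 params = params),
            class = "cpg_sim")
}

#' @export
print.cpg_sim <- function(x, ...) {
  cat(sprintf("<cpg_sim> %.3g s, %d licks, peak level %.3g\n",
              max(x$time), length(x$licks), max(x$level)))
  invisible(x)
}

#' @export
plot.cpg_sim <- function(x, ..., xlab = "time (s)") {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$level, type = "l", xlab = xlab,
                 ylab = "integrator level", ...)
  graphics::abline(h = x$params$thresholds, lty = 3)
  graphics::plot(x$licks, rep(1, length(x$licks)), pch = "|",
                 xlab = xlab, ylab = "licks", yaxt = "n",
                 xlim = range(x$time))
  invisible(x)
}

#' Evoked licking frequency versus stimulation frequency
#'
#' For each direct-pathway stimulation frequency, simulates a 1-s pulse
#' train and reports the PSD peak frequency of the emitted licks, averaged
#' over consecutive 1-s epochs spanning the evoked bout (stimulation plus
#' post-offset persistence). The curve is non-decreasing and saturates at
#' the cap.
#'
#' @param params A [cpg_params()] object.
#' @param stim_frequencies Stimulation frequencies to sweep, Hz.
#' @param stim_duration Train duration, seconds.
#' @return data.frame `stim_hz`, `lick_hz`, `n_licks`.
#' @export
evoked_frequency_curve <- function(params = cpg_params(),
                                   stim_frequencies = c(5, 10, 25, 50),
                                   stim_duration = 1) {
  rows <- lapply(stim_frequencies, function(f) {
    sim <- simulate_cpg(pulse_train(f, 0, stim_duration),
                        duration = stim_duration + 5, params = params)
    n_ep <- max(1, ceiling(max(c(sim$licks, stim_duration))))
    ep <- slice_epochs(sim$licks, seq(0, n_ep - 1), epoch_length = 1)
    lick_hz <- if (length(sim$licks) >= 2)
      peak_frequency(lick_psd(ep, epoch_length = 1)) else NA_real_
    data.frame(stim_hz = f, lick_hz = lick_hz, n_licks = length(sim$licks))
  })
  do.call(rbind, rows)
}

#' Post-offset persistence of suprathreshold output
#'
#' Duration for which the integrator level stays above the lowest mode
#' threshold after the input train ends. With the exact exponential decay
#' this equals `log(I_end / theta1) / leak_rate` for `I_end > theta1`.
#'
#' @param params A [cpg_params()] object.
#' @param stim_frequency D1 train frequency, Hz.
#' @param stim_duration Train duration, seconds.
#' @return Persistence in seconds (0 if the level is already below
#'   threshold at offset).
#' @export
post_offset_persistence <- function(params = cpg_params(),
                                    stim_frequency = 25,
                                    stim_duration = 1) {
  horizon <- stim_duration + 20
  sim <- simulate_cpg(pulse_train(stim_frequency, 0, stim_duration),
                      duration = horizon, params = params)
  after <- sim$time >= stim_duration
  lv <- sim$level[after]; tm <- sim$time[after]
  above <- lv >= params$thresholds[1]
  if (!above[1]) return(0)
  drop <- which(!above)
  end <- if (length(drop) == 0) max(tm) else tm[drop[1]]
  end - stim_duration
}
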