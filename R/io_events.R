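# Canonical data model for lick/event streams: lick trains, trial tables,
# session bundles, the 8-ms inter-lick-interval filter, and session I/O.

MIN_ILI <- 0.008   # debounce: retain a lick only if >= 8 ms after the last retained lick
PEAK_MIN_PROBE <- 30

#' Construct a lick train
#'
#' A lick train is the atomic input of every analysis: an ordered vector of
#' lick contact times, in seconds from session start. Timestamps must be
#' strictly increasing; use [filter_licks()] to build one from raw,
#' possibly bounce-contaminated lickometer output.
#'
#' @param timestamps Numeric vector of lick times in seconds, strictly
#'   increasing.
#' @param session_id Optional session identifier string.
#' @return An object of class `lick_train`: a numeric vector with a
#'   `session_id` attribute.
#' @examples
#' lt <- lick_train(c(0.1, 0.35, 0.62))
#' @export
lick_train <- function(timestamps = numeric(), session_id = "") {
  timestamps <- as.numeric(timestamps)
  if (any(!is.finite(timestamps)))
    stop("malformed lick train: non-finite timestamps", call. = FALSE)
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("malformed lick train: timestamps must be strictly increasing",
         call. = FALSE)
  structure(timestamps, session_id = as.character(session_id),
            class = "lick_train")
}

#' @export
print.lick_train <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<lick_train> %d licks", n))
  if (n > 0)
    cat(sprintf(" spanning %.3f-%.3f s", x[1], x[n]))
  sid <- attr(x, "session_id")
  if (nzchar(sid)) cat(sprintf(" [session %s]", sid))
  cat("\n")
  invisible(x)
}

#' @export
`[.lick_train` <- function(x, i, ...) {
  structure(unclass(x)[i], session_id = attr(x, "session_id"),
            class = "lick_train")
}

#' Filter raw lick timestamps with the 8-ms debounce rule
#'
#' Lickometer contact sensors register mechanical bounces as spurious events
#' a few milliseconds apart. Events closer than 8 ms to the previously
#' *retained* lick are discarded in a single greedy forward scan: the first
#' lick is always retained, and each subsequent lick is retained iff its gap
#' from the last retained lick is at least 0.008 s. The scan is idempotent
#' and guarantees all output inter-lick intervals are >= 8 ms.
#'
#' @param raw_timestamps Numeric vector of raw lick times in seconds.
#'   Sorted input is expected; unsorted finite input is sorted with a
#'   warning since hardware streams are occasionally interleaved.
#' @param session_id Optional session identifier.
#' @return A [lick_train()] whose consecutive differences are all >= 0.008 s.
#' @examples
#' filter_licks(c(0, 0.005, 0.2))  # drops the 5-ms bounce
#' @export
filter_licks <- function(raw_timestamps, session_id = "") {
  ts <- as.numeric(raw_timestamps)
  if (any(!is.finite(ts)))
    stop("malformed input: non-finite timestamps", call. = FALSE)
  if (is.unsorted(ts)) {
    warning("unsorted raw timestamps; sorting before filtering")
    ts <- sort(ts)
  }
  n <- length(ts)
  if (n == 0) return(lick_train(numeric(), session_id))
  keep <- logical(n)
  keep[1] <- TRUE
  last <- ts[1]
  for (i in seq_len(n)[-1]) {
    if (ts[i] - last >= MIN_ILI) {
      keep[i] <- TRUE
      last <- ts[i]
    }
  }
  # exact ties after sorting collapse to one event
  out <- ts[keep]
  if (anyDuplicated(out)) out <- unique(out)
  lick_train(out, session_id)
}

#' Construct a per-trial table of task events
#'
#' One row per trial. Every trial terminates in a reward delivery
#' (`reward_time`, absolute seconds); `kind` distinguishes ordinary
#' fixed-time trials from unrewarded peak probe trials, whose span
#' (`probe_duration`, >= 30 s) runs from the *initiating* reward (the
#' previous trial's reward) to the terminal reward that resets the schedule.
#' Laser columns describe the optogenetic train: onset relative to the
#' trial's alignment reward (the trial reward for fixed trials, the
#' initiating reward for peak trials), duration (default 1 s) and pulse
#' frequency in Hz.
#'
#' @param trial_id Integer trial identifiers, unique.
#' @param reward_time Absolute reward delivery times, seconds.
#' @param kind Character, `"fixed"` or `"peak"`.
#' @param laser_onset_rel Laser onset relative to the alignment reward
#'   (negative = before reward); `NA` for no laser.
#' @param laser_duration Laser train duration, seconds (default 1).
#' @param laser_frequency Laser pulse frequency, Hz, one of 0/5/10/25/50.
#' @param probe_duration Probe span in seconds for peak trials, `NA` for
#'   fixed trials.
#' @return A `data.frame` of class `trial_table`, ordered by `reward_time`.
#' @export
trial_table <- function(trial_id, reward_time, kind,
                        laser_onset_rel = NA_real_,
                        laser_duration = NA_real_,
                        laser_frequency = NA_real_,
                        probe_duration = NA_real_) {
  n <- length(trial_id)
  tt <- data.frame(
    trial_id = as.integer(trial_id),
    reward_time = as.numeric(reward_time),
    kind = as.character(kind),
    laser_onset_rel = rep_len(as.numeric(laser_onset_rel), n),
    laser_duration = rep_len(as.numeric(laser_duration), n),
    laser_frequency = rep_len(as.numeric(laser_frequency), n),
    probe_duration = rep_len(as.numeric(probe_duration), n),
    stringsAsFactors = FALSE
  )
  validate_trial_table(tt)
  tt <- tt[order(tt$reward_time), , drop = FALSE]
  rownames(tt) <- NULL
  class(tt) <- c("trial_table", "data.frame")
  tt
}

validate_trial_table <- function(tt) {
  if (anyDuplicated(tt$trial_id))
    stop("trial_ids must be unique", call. = FALSE)
  if (!all(tt$kind %in% c("fixed", "peak")))
    stop("trial kind must be 'fixed' or 'peak'", call. = FALSE)
  pk <- tt$kind == "peak"
  if (any(pk & (is.na(tt$probe_duration) | tt$probe_duration < PEAK_MIN_PROBE)))
    stop("peak trials must have probe_duration >= 30 s", call. = FALSE)
  haslaser <- !is.na(tt$laser_onset_rel)
  if (any(haslaser & !(tt$laser_duration > 0)))
    stop("laser duration must be > 0 when laser present", call. = FALSE)
  invisible(tt)
}

#' Alignment reward for each trial
#'
#' The trial-relative time origin used throughout the analyses: the trial's
#' own reward for fixed trials, the initiating reward (start of the probe
#' span) for peak trials.
#'
#' @param trials A [trial_table()].
#' @return Numeric vector of absolute times, one per trial.
#' @export
align_times <- function(trials) {
  ifelse(trials$kind == "peak",
         trials$reward_time - trials$probe_duration,
         trials$reward_time)
}

#' Absolute laser window per trial
#'
#' @param trials A [trial_table()].
#' @return A data.frame with columns `trial_id`, `on`, `off` for laser
#'   trials only.
#' @export
laser_windows <- function(trials) {
  has <- !is.na(trials$laser_onset_rel)
  on <- align_times(trials)[has] + trials$laser_onset_rel[has]
  data.frame(trial_id = trials$trial_id[has], on = on,
             off = on + trials$laser_duration[has])
}

#' Bundle a session's licks, trials and metadata
#'
#' @param licks A [lick_train()].
#' @param trials A [trial_table()].
#' @param metadata Named list of free-form session metadata (e.g. `subject`,
#'   `group` in D1-ChR2 / A2A-ChR2 / eYFP-control, `interval`).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(licks, trials, metadata = list()) {
  stopifnot(inherits(licks, "lick_train"), inherits(trials, "trial_table"))
  span_end <- max(c(0, trials$reward_time, unclass(licks)))
  lw <- laser_windows(trials)
  if (nrow(lw) > 0 && (any(lw$on < 0) || any(lw$off > span_end + 1e-9)))
    stop("laser events outside session span", call. = FALSE)
  structure(list(licks = licks, trials = trials, metadata = metadata),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d licks, %d trials (%d peak, %d laser)\n",
              length(x$licks), nrow(x$trials),
              sum(x$trials$kind == "peak"),
              sum(!is.na(x$trials$laser_onset_rel))))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.session_bundle <- function(object, ...) {
  tt <- object$trials
  data.frame(
    n_trials = nrow(tt),
    n_peak = sum(tt$kind == "peak"),
    n_laser = sum(!is.na(tt$laser_onset_rel)),
    n_licks = length(object$licks),
    span_s = max(c(0, tt$reward_time, unclass(object$licks)))
  )
}

#' Restrict a session to its first half of trials
#'
#' Motivational (satiety) drift contaminates late trials, so unless stated
#' otherwise analyses use only the first half of trials. With an odd trial
#' count the first ceiling(N/2) trials are kept. Licks are truncated to the
#' retained trial span. Quartile/motivation analyses deliberately bypass
#' this selection.
#'
#' @param bundle A [session_bundle()].
#' @return A `session_bundle` with trials `1..ceiling(N/2)` and the licks
#'   within their span.
#' @export
select_first_half <- function(bundle) {
  tt <- bundle$trials
  if (nrow(tt) < 2) stop("need >= 2 trials", call. = FALSE)
  keep <- seq_len(ceiling(nrow(tt) / 2))
  tt2 <- tt[keep, , drop = FALSE]
  class(tt2) <- c("trial_table", "data.frame")
  cut <- max(tt2$reward_time)
  lk <- unclass(bundle$licks)
  licks2 <- lick_train(lk[lk <= cut], attr(bundle$licks, "session_id"))
  session_bundle(licks2, tt2, bundle$metadata)
}

# ---- session I/O -----------------------------------------------------------

EVENT_CODES <- c("lick", "reward", "laser_on", "laser_off")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a session to disk
#'
#' Writes the events-CSV dialect: `events.csv` with columns
#' `time_s,event,trial_id` (event in lick/reward/laser_on/laser_off; licks
#' carry no trial_id), and a sidecar `meta.yaml` holding session metadata
#' plus the task parameters needed to reconstruct the trial table (interval,
#' session-level laser frequency and duration). Numbers are written with 17
#' significant digits so that [read_session()] is an exact inverse.
#'
#' @param bundle A [session_bundle()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tt <- bundle$trials
  ev <- data.frame(
    time_s = fmt_num(unclass(bundle$licks)),
    event = "lick", trial_id = "", stringsAsFactors = FALSE
  )
  ev <- rbind(ev, data.frame(time_s = fmt_num(tt$reward_time),
                             event = "reward",
                             trial_id = as.character(tt$trial_id)))
  lw <- laser_windows(tt)
  if (nrow(lw) > 0) {
    ev <- rbind(ev,
                data.frame(time_s = fmt_num(lw$on), event = "laser_on",
                           trial_id = as.character(lw$trial_id)),
                data.frame(time_s = fmt_num(lw$off), event = "laser_off",
                           trial_id = as.character(lw$trial_id)))
  }
  ev <- ev[order(as.numeric(ev$time_s)), , drop = FALSE]
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- bundle$metadata
  meta$session_id <- attr(bundle$licks, "session_id")
  if (is.null(meta$interval)) meta$interval <- 10
  lf <- tt$laser_frequency[!is.na(tt$laser_frequency)]
  if (length(lf) > 0) meta$laser_frequency <- lf[1]
  ld <- tt$laser_duration[!is.na(tt$laser_duration)]
  if (length(ld) > 0) meta$laser_duration <- ld[1]
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  gt <- attr(bundle, "ground_truth")
  if (!is.null(gt))
    utils::write.csv(gt, file.path(path, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]. Trial kinds are reconstructed from
#' inter-reward gaps: a trial whose gap from the previous reward exceeds the
#' task interval (beyond float tolerance) is a peak probe trial and the gap
#' is its probe duration. Laser onsets are re-expressed relative to each
#' trial's alignment reward.
#'
#' @param path Directory written by [write_session()].
#' @return A [session_bundle()].
#' @export
read_session <- function(path) {
  evf <- file.path(path, "events.csv")
  if (!file.exists(evf)) stop("no events.csv under ", path, call. = FALSE)
  ev <- utils::read.csv(evf, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("time_s", "event", "trial_id")
  miss <- setdiff(req, names(ev))
  if (length(miss) > 0)
    stop("events.csv missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ev$time_s <- as.numeric(ev$time_s)
  if (any(!is.finite(ev$time_s)))
    stop(sprintf("non-numeric time_s at row %d",
                 which(!is.finite(ev$time_s))[1]), call. = FALSE)
  bad <- which(!(ev$event %in% EVENT_CODES))
  if (length(bad) > 0)
    stop(sprintf("unknown event code '%s' at row %d", ev$event[bad[1]],
                 bad[1]), call. = FALSE)
  meta <- list()
  mf <- file.path(path, "meta.yaml")
  if (file.exists(mf)) meta <- yaml::read_yaml(mf)
  interval <- if (!is.null(meta$interval)) meta$interval else 10

  rw <- ev[ev$event == "reward", , drop = FALSE]
  rw <- rw[order(rw$time_s), , drop = FALSE]
  tid <- suppressWarnings(as.integer(rw$trial_id))
  if (any(is.na(tid)))
    stop("reward rows must carry integer trial_id", call. = FALSE)
  if (anyDuplicated(tid)) {
    dup <- tid[duplicated(tid)][1]
    stop(sprintf("duplicate trial_id %d among reward rows", dup),
         call. = FALSE)
  }
  gaps <- diff(c(0, rw$time_s))
  kind <- ifelse(gaps > interval + 1e-6, "peak", "fixed")
  probe <- ifelse(kind == "peak", gaps, NA_real_)

  lon <- ev[ev$event == "laser_on", , drop = FALSE]
  loff <- ev[ev$event == "laser_off", , drop = FALSE]
  laser_on_rel <- rep(NA_real_, nrow(rw))
  laser_dur <- rep(NA_real_, nrow(rw))
  if (nrow(lon) > 0) {
    align <- rw$time_s - ifelse(kind == "peak", probe, 0)
    for (i in seq_len(nrow(lon))) {
      j <- match(as.integer(lon$trial_id[i]), tid)
      if (is.na(j))
        stop(sprintf("laser_on row %d references unknown trial_id %s",
                     i, lon$trial_id[i]), call. = FALSE)
      laser_on_rel[j] <- lon$time_s[i] - align[j]
      offj <- loff$time_s[as.integer(loff$trial_id) == tid[j]]
      laser_dur[j] <- if (length(offj) > 0) offj[1] - lon$time_s[i] else 1
    }
  }
  lf <- if (!is.null(meta$laser_frequency)) meta$laser_frequency else NA_real_
  tt <- trial_table(tid, rw$time_s, kind,
                    laser_onset_rel = laser_on_rel,
                    laser_duration = laser_dur,
                    laser_frequency = ifelse(is.na(laser_on_rel), NA_real_, lf),
                    probe_duration = probe)
  sid <- if (!is.null(meta$session_id)) meta$session_id else ""
  licks <- lick_train(sort(ev$time_s[ev$event == "lick"]), sid)
  meta$session_id <- NULL
  meta$laser_frequency <- NULL
  meta$laser_duration <- NULL
  bundle <- session_bundle(licks, tt, meta)
  gtf <- file.path(path, "ground_truth.csv")
  if (file.exists(gtf))
    attr(bundle, "ground_truth") <- utils::read.csv(gtf,
                                                    stringsAsFactors = FALSE)
  bundle
}
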