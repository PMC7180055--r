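test_that("bout onsets follow the 1-s inter-lick-interval rule", {
  expect_equal(bout_onsets(c(0, 0.2, 0.4, 3.0, 3.2)), c(0, 3.0))
  expect_equal(bout_onsets(5.0), 5.0)
  expect_length(bout_onsets(numeric()), 0)
  set.seed(12)
  for (rep in 1:5) {
    ts <- sort(runif(300, 0, 60))
    expect_equal(bout_onsets(ts), bout_onset_oracle(ts))
  }
})

test_that("bout onsets commute with time shifts", {
  set.seed(14)
  ts <- sort(runif(200, 0, 50))
  for (delta in c(-5, 3.7, 120)) {
    expect_equal(bout_onsets(ts + delta), bout_onsets(ts) + delta,
                 tolerance = 1e-12)
  }
})

test_that("delta lick rate contrasts laser against matched no-laser windows", {
  # hand-built session: 4 fixed trials, laser on trials 1-2 at -1 s;
  # stim trials lick at 8 Hz in the window, controls at 2 Hz
  tt <- mk_fixed_trials(4, laser_onset = -1, laser_trials = 1:2)
  licks <- sort(c(seq(9.001, 9.97, by = 1 / 8), seq(19.001, 19.97, by = 1 / 8),
                  seq(29.001, 29.97, by = 1 / 2), seq(39.001, 39.97, by = 1 / 2)))
  b <- session_bundle(filter_licks(licks), tt)
  d <- delta_lick_rate(b)
  expect_equal(d$baseline_rate, 2)
  expect_equal(d$mean_delta, 6)
  # identical behavior in both conditions: delta 0
  licks2 <- sort(unlist(lapply(c(9, 19, 29, 39), function(s)
    seq(s + 0.001, s + 0.97, by = 0.25))))
  d2 <- delta_lick_rate(session_bundle(filter_licks(licks2), tt))
  expect_equal(d2$mean_delta, 0)

  expect_error(delta_lick_rate(session_bundle(lick_train(1), mk_fixed_trials(3))),
               "no laser")
  tt_all <- mk_fixed_trials(3, laser_onset = -1, laser_trials = 1:3)
  expect_error(delta_lick_rate(session_bundle(lick_train(1), tt_all)),
               "no matched")
})

test_that("suppression sessions show the negative rate change", {
  tt <- mk_fixed_trials(80, laser_onset = -1, laser_trials = seq(1, 80, 2))
  lk <- lick_model_params(bout_frequency = 6, anticipation_onset_mean = 3,
                          anticipation_onset_sd = 0.3, baseline_rate = 0,
                          seed = 41)
  b <- simulate_licking(tt, lk, stim_effect_params("a2a_suppress"))
  d <- delta_lick_rate(b)
  expect_equal(d$mean_delta, -6, tolerance = 0.6)
  # control-style session (no injected effect): delta ~ 0
  b0 <- simulate_licking(tt, lk, stim_effect_params("none"))
  expect_equal(delta_lick_rate(b0)$mean_delta, 0, tolerance = 0.5)
})

test_that("evoked-bout latency is recovered from the generator", {
  tt <- mk_fixed_trials(200, laser_onset = -5, laser_trials = 1:200)
  # keep anticipatory licking clear of the early-interval laser window so
  # the evoked onset is the only candidate
  lk <- lick_model_params(anticipation_onset_mean = 2,
                          anticipation_onset_sd = 0.3,
                          baseline_rate = 0, seed = 43)
  st <- stim_effect_params("d1_evoke")
  b <- simulate_licking(tt, lk, st)
  lat <- evoke_latency(b)
  expect_equal(lat$latency, ground_truth(b)$evoke_latency, tolerance = 1e-9)
  # mean within 2 SEM of the configured 25-Hz map latency (0.3 s, sd 0.05)
  expect_equal(mean(lat$latency, na.rm = TRUE), 0.3,
               tolerance = 2 * 0.05 / sqrt(200) / 0.3)
  # hand case: onset 0.3 s after laser onset
  tt1 <- mk_fixed_trials(2, laser_onset = -5, laser_trials = 1)
  b1 <- session_bundle(lick_train(c(5.3, 5.45, 5.6)), tt1)
  expect_equal(evoke_latency(b1)$latency, 0.3)
  # no onset inside the train: excluded
  b2 <- session_bundle(lick_train(c(7.5, 7.7)), tt1)
  expect_true(is.na(evoke_latency(b2)$latency))
})

test_that("rebound latency searches [0, 3] s after offset with baseline", {
  tt <- mk_fixed_trials(4, laser_onset = -5, laser_trials = 1:2)
  # offsets at 6 and 16; onsets 0.4 / 0.6 s later; controls silent
  b <- session_bundle(lick_train(c(6.4, 6.5, 16.6, 16.7)), tt)
  r <- rebound_latency(b)
  expect_equal(r$per_trial$latency, c(0.4, 0.6))
  expect_equal(r$variance, 0.02)
  expect_true(all(is.na(r$baseline$latency)))
  # onset beyond the 3-s window is missing
  b2 <- session_bundle(lick_train(c(9.6, 9.7)), tt)
  expect_true(all(is.na(rebound_latency(b2)$per_trial$latency)))

  # generator recovery at n = 200 (25-Hz map: mean 0.5 s, sd 0.1);
  # anticipation kept late so the rebound onset is the first in-window onset
  tt2 <- mk_fixed_trials(200, laser_onset = -5, laser_trials = 1:200)
  bb <- simulate_licking(tt2,
                         lick_model_params(anticipation_onset_mean = 2,
                                           anticipation_onset_sd = 0.3,
                                           baseline_rate = 0, seed = 47),
                         stim_effect_params("a2a_suppress",
                                            rebound_prob = 1))
  rr <- rebound_latency(bb)
  expect_equal(mean(rr$per_trial$latency, na.rm = TRUE), 0.5,
               tolerance = 2 * 0.1 / sqrt(200) / 0.5)
})

test_that("post-offset lick counts use the 1-s window", {
  tt <- mk_fixed_trials(2, laser_onset = -5, laser_trials = 1)
  b <- session_bundle(lick_train(c(6.1, 6.3, 6.5, 6.7, 7.5)), tt)
  pc <- post_offset_count(b)
  expect_equal(pc$per_trial$count, 4)
  b0 <- session_bundle(lick_train(c(9.5)), tt)
  expect_equal(post_offset_count(b0)$per_trial$count, 0)

  # generator: 0.5-s persistence at 6 Hz -> ~3 licks after offset
  tt2 <- mk_fixed_trials(100, laser_onset = -5, laser_trials = 1:100)
  st <- stim_effect_params("d1_evoke",
                           evoked_frequency_map = c(`25` = 6),
                           post_offset_persist = 0.5)
  bb <- simulate_licking(tt2, lick_model_params(baseline_rate = 0, seed = 51),
                         st)
  expect_equal(mean(post_offset_count(bb)$per_trial$count), 3,
               tolerance = 0.7)
})

test_that("rebound classification applies the 2-s and 8-s onset rules", {
  on <- 100
  expect_equal(classify_rebound_trial(c(on + 1.2, on + 1.2 + 4), on),
               "recovery")
  expect_equal(classify_rebound_trial(c(on + 1.2), on), "initiation")
  expect_equal(classify_rebound_trial(c(on + 2.5), on), "no_rebound")
  # boundary behavior: onset exactly at +2 s counts as rebound; second
  # onset exactly at +8 s counts as recovery
  expect_equal(classify_rebound_trial(c(on + 2, on + 2 + 8), on), "recovery")
  expect_equal(classify_rebound_trial(c(on + 2, on + 2 + 8.01), on),
               "initiation")
})

test_that("classification partitions constructed trials and matches truth", {
  set.seed(61)
  n <- 90
  planted <- sample(c("recovery", "initiation", "no_rebound"), n, TRUE)
  stim_on <- 50 * seq_len(n)
  labels <- vapply(seq_len(n), function(i) {
    s <- stim_on[i]
    tr_on <- switch(planted[i],
                    recovery = c(s + 1.0, s + 5.5),
                    initiation = s + 1.0,
                    no_rebound = s + 2.5)
    classify_rebound_trial(tr_on, s)
  }, "")
  expect_identical(labels, planted)
  expect_equal(sum(table(factor(labels, levels = c("recovery", "initiation",
                                                   "no_rebound")))), n)
})

test_that("session-level classification requires mid-interval probes", {
  tt <- mk_probe_trials(20, laser_onset = 5)
  b <- simulate_licking(tt, lick_model_params(baseline_rate = 0, seed = 63),
                        stim_effect_params("a2a_suppress"))
  cls <- classify_rebound(b)
  expect_equal(nrow(cls), 20)
  expect_true(all(cls$label %in% c("recovery", "initiation", "no_rebound")))
  bad <- session_bundle(lick_train(1:5 * 1.0), mk_fixed_trials(4))
  expect_error(classify_rebound(bad), "no stimulated probe")
  tt_neg <- trial_table(1:4, 50 + 45 * (0:3), rep("peak", 4),
                        laser_onset_rel = -1, laser_duration = 1,
                        laser_frequency = 25, probe_duration = 45)
  b_neg <- simulate_licking(tt_neg, lick_model_params(seed = 1),
                            stim_effect_params())
  expect_error(classify_rebound(b_neg), "mid-interval")
})

test_that("quartile analysis splits laser trials by presentation order", {
  tt <- mk_fixed_trials(40, laser_onset = -5, laser_trials = 1:40)
  b <- simulate_licking(tt, lick_model_params(anticipation_onset_mean = 2,
                                              anticipation_onset_sd = 0.3,
                                              baseline_rate = 0, seed = 71),
                        stim_effect_params("d1_evoke"))
  q <- quartile_analysis(b, "evoke_latency")
  expect_equal(q$quartile, 1:4)
  expect_equal(sum(q$n), 40)
  expect_true(all(q$n == 10))

  # satiety drift: late-session evoked latencies are longer
  lk_sat <- lick_model_params(anticipation_onset_mean = 2,
                              anticipation_onset_sd = 0.3,
                              baseline_rate = 0, satiety_slope = 0.02,
                              seed = 73)
  tt2 <- mk_fixed_trials(80, laser_onset = -5, laser_trials = 1:80)
  b2 <- simulate_licking(tt2, lk_sat, stim_effect_params("d1_evoke"))
  q2 <- quartile_analysis(b2, "evoke_latency")
  expect_gt(q2$mean[4], q2$mean[1])

  expect_error(
    quartile_analysis(
      session_bundle(lick_train(1),
                     mk_fixed_trials(5, laser_onset = -1, laser_trials = 1:3))),
    ">= 4 laser")
})

test_that("rebound fractions per half sum to one and track satiety", {
  fr <- rebound_session_half_fractions(rep("recovery", 10))
  expect_equal(fr$fraction[fr$label == "recovery"], c(1, 1))
  expect_equal(as.vector(tapply(fr$fraction, fr$half, sum)), c(1, 1))
  expect_error(rebound_session_half_fractions(c("recovery")), ">= 2")
  expect_error(rebound_session_half_fractions(c("a", "b", "c", "d")),
               "unknown")
  # alias accepted
  fr2 <- rebound_session_half_fractions(c("absorption", "absorption",
                                          "initiation", "initiation"))
  expect_equal(fr2$fraction[fr2$label == "initiation"], c(1, 1))

  # satiety shrinks rebound probability: recovery rarer in second half
  tt <- mk_probe_trials(60, laser_onset = 5)
  lk <- lick_model_params(baseline_rate = 0, satiety_slope = 0.05, seed = 77)
  b <- simulate_licking(tt, lk,
                        stim_effect_params("a2a_suppress", rebound_prob = 1))
  cls <- classify_rebound(b)
  fr3 <- rebound_session_half_fractions(cls$label)
  rec <- fr3$fraction[fr3$label == "recovery"]
  expect_lt(rec[2], rec[1])
})
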