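test_that("simulation is deterministic for a fixed seed", {
  sch <- state_schedule(c("boredom", "stress"), c(0, 30), c(30, 60))
  s1 <- simulate_session(sim_profile(), sch, seed = 77)
  s2 <- simulate_session(sim_profile(), sch, seed = 77)
  expect_identical(s1$trace, s2$trace)
  expect_identical(as.data.frame(s1$track), as.data.frame(s2$track))
  expect_identical(s1$sensor, s2$sensor)
  s3 <- simulate_session(sim_profile(), sch, seed = 78)
  expect_false(identical(s1$trace$g, s3$trace$g))
})

test_that("a noise-free constant-rate pulse is recovered on every window", {
  prof <- sim_profile(effect = 0, hr_center = 72, hr_drift = 0,
                      noise_sd = 0, motion_step = 0, blink_rate = 0,
                      event_rate = 0, artifact_rate = 0)
  s <- simulate_session(prof, state_schedule("boredom", 0, 60), seed = 1)
  est <- estimate_hr(s$trace, analysis_windows(0, 60))
  expect_equal(nrow(est), 46)
  expect_true(all(abs(est$bpm - 72) <= 1))
})

test_that("state contrast shows up in heart rate and blink statistics", {
  prof <- sim_profile() # 70 vs 90 bpm, 2x blink rate
  sch <- state_schedule(c("boredom", "stress"), c(0, 60), c(60, 120))
  s <- simulate_session(prof, sch, seed = 13)
  hr_b <- mean(s$truth$hr[s$truth$state == "boredom"])
  hr_s <- mean(s$truth$hr[s$truth$state == "stress"])
  expect_gt(hr_s - hr_b, 15)
  # sensor stream tracks the ground truth within its jitter
  approx_truth <- s$truth$hr[match(round(s$sensor$t * 50) + 1,
                                   round(s$truth$t * 50) + 1)]
  expect_lte(max(abs(s$sensor$bpm - approx_truth)), 1)
  # blinks depress the eye area more often under stress
  ff <- facial_features(s$track)
  ea_sd_b <- sd(ff$F3[s$truth$state == "boredom"])
  ea_sd_s <- sd(ff$F3[s$truth$state == "stress"])
  expect_gt(ea_sd_s, ea_sd_b * 0.8)
})

test_that("blink counts concentrate around rate x duration", {
  prof <- sim_profile(effect = 0, blink_rate = 0.4, motion_step = 0,
                      event_rate = 0, noise_sd = 0, artifact_rate = 0)
  dur <- 120
  counts <- vapply(1:5, function(sd) {
    s <- simulate_session(prof, state_schedule("boredom", 0, dur), seed = sd)
    ff <- facial_features(s$track)
    # count dips of the eye area below half its open value
    open <- max(ff$F3)
    sum(diff(ff$F3 < open / 2) == 1)
  }, numeric(1))
  expected <- 0.4 * dur
  expect_true(all(abs(counts - expected) <= 3 * sqrt(expected)))
})

test_that("rPPG recovery degrades monotonically with noise", {
  # recovery failure rate (estimate missing or off by more than 2 bpm);
  # a failure-rate readout is robust to the sub-bpm bin quantisation
  # that makes raw median errors noisy at low noise levels
  fail_rate <- vapply(c(0.3, 3, 10), function(ns) {
    prof <- sim_profile(effect = 0, hr_center = 75, noise_sd = ns,
                        motion_step = 0, blink_rate = 0, event_rate = 0,
                        artifact_rate = 0)
    s <- simulate_session(prof, state_schedule("boredom", 0, 40), seed = 3)
    w <- analysis_windows(0, 40)
    est <- estimate_hr(s$trace, w)
    truth <- vapply(seq_len(nrow(w)), function(i) {
      mean(s$truth$hr[s$truth$t >= w$window_start_s[i] &
                        s$truth$t < w$window_end_s[i]])
    }, numeric(1))
    err <- abs(est$bpm - truth)
    mean(is.na(err) | err > 2)
  }, numeric(1))
  expect_true(all(diff(fail_rate) >= 0))
  expect_gt(fail_rate[3], fail_rate[1])
})

test_that("cohort manifests reproduce the design bookkeeping", {
  co <- simulate_cohort(20, study = 1, seed = 2, exclude_subjects = 9,
                        manifest_only = TRUE)
  expect_equal(count_segments(co$manifest)$h0_h1_pairs, 57)
  co2 <- simulate_cohort(62, study = 2, seed = 3, manifest_only = TRUE)
  cts <- count_segments(co2$manifest)
  expect_equal(cts$h0_h1_pairs, 186)
  expect_equal(cts$eval_segments, 434)
})

test_that("generated self-reports follow the level design", {
  co <- simulate_cohort(6, study = 2, seed = 4, manifest_only = TRUE)
  sel <- lapply(co$subjects, function(su) select_eval_levels(su$reports))
  # in the default profile the designed stressful/boring levels dominate
  stress_lv <- unlist(lapply(sel, function(s) s$level[s$class == "stress"]))
  bored_lv <- unlist(lapply(sel, function(s) s$level[s$class == "boredom"]))
  expect_gt(mean(stress_lv %in% c(3, 6)), 0.8)
  expect_gt(mean(bored_lv %in% c(4, 7)), 0.8)
})

test_that("invalid schedules are rejected", {
  expect_error(state_schedule("panic", 0, 10), class = "remoteaffect_invalid_input")
  expect_error(state_schedule(c("boredom", "stress"), c(0, 5), c(6, 10)),
               class = "remoteaffect_invalid_input")
})
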