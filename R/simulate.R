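# Synthetic psychophysiological sessions: a pulse embedded in RGB pixel
# traces, landmark tracks with blink/motion/facial-event processes whose
# rates depend on the scheduled emotional state, a 1 Hz sensor heart-rate
# stream, and self-reports consistent with the schedule. Every stream
# shares the session clock, so the generated files exercise the whole
# pipeline with known ground truth.

#' Simulation profile
#'
#' Per-state (boredom, stress) parameters of the generator. The single
#' `effect` knob scales the boredom/stress contrast: at `effect = 1` the
#' states differ by 20 bpm in mean heart rate and by a factor 2 in blink,
#' head-motion and facial-event intensity; at `effect = 0` the two states
#' are identical (a null profile). Pulse amplitudes are green-dominant
#' (R:G:B = 0.3:1.0:0.6), reflecting the stronger photoplethysmographic
#' signal of the green channel.
#'
#' @param effect Contrast between states in \[0, 1\] (default 1).
#' @param hr_center Mean of the two state heart rates (default 80 bpm).
#' @param hr_delta Heart-rate difference between stress and boredom at
#'   `effect = 1` (default 20 bpm).
#' @param hr_drift Stationary standard deviation of the
#'   Ornstein-Uhlenbeck heart-rate drift (default 1.5 bpm).
#' @param blink_rate Boredom-state blink rate in events/s (default 0.25).
#' @param motion_step Boredom-state head random-walk step scale in
#'   px/frame (default 0.06).
#' @param event_rate Boredom-state mouth/brow event rate in events/s
#'   (default 0.05).
#' @param pulse_scale Green-channel pulse amplitude in pixel-value units
#'   (default 1).
#' @param noise_sd White-noise standard deviation per channel in
#'   pixel-value units (default 0.3).
#' @param artifact_rate Rate of step-like motion artifacts in events/s
#'   (default 0.02).
#' @param report_confusion Probability that a generated self-report
#'   contradicts the scheduled state (default 0.05).
#' @return A list of class `sim_profile` with per-state parameter pairs.
#' @export
sim_profile <- function(effect = 1, hr_center = 80, hr_delta = 20,
                        hr_drift = 1.5, blink_rate = 0.25,
                        motion_step = 0.06, event_rate = 0.05,
                        pulse_scale = 1, noise_sd = 0.3,
                        artifact_rate = 0.02, report_confusion = 0.05) {
  stopifnot(effect >= 0, hr_center >= 45, hr_center <= 240)
  rate_factor <- 1 + effect # x2 at full effect
  structure(list(
    effect = effect,
    hr_bpm = c(boredom = hr_center - effect * hr_delta / 2,
               stress = hr_center + effect * hr_delta / 2),
    hr_drift = hr_drift,
    blink_rate = c(boredom = blink_rate, stress = blink_rate * rate_factor),
    motion_step = c(boredom = motion_step, stress = motion_step * rate_factor),
    event_rate = c(boredom = event_rate, stress = event_rate * rate_factor),
    pulse_amp = c(r = 0.3, g = 1.0, b = 0.6) * pulse_scale,
    noise_sd = noise_sd,
    artifact_rate = artifact_rate,
    report_confusion = report_confusion
  ), class = "sim_profile")
}

#' State schedule helper
#'
#' @param state Character vector of states (`"boredom"`/`"stress"`).
#' @param start_s,end_s Interval bounds; intervals must be ordered and
#'   non-overlapping.
#' @return A schedule tibble.
#' @export
state_schedule <- function(state, start_s, end_s) {
  s <- tibble(state = state, start_s = start_s, end_s = end_s)
  if (!all(s$state %in% c("boredom", "stress"))) {
    stop_invalid("schedule states must be 'boredom' or 'stress'")
  }
  if (any(s$end_s <= s$start_s) ||
      (nrow(s) > 1 && any(diff(s$start_s) <= 0)) ||
      (nrow(s) > 1 && any(s$start_s[-1] < s$end_s[-nrow(s)] - 1e-9))) {
    stop_invalid("schedule intervals must be ordered and non-overlapping")
  }
  s
}

state_at <- function(schedule, t) {
  state <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(schedule))) {
    inside <- t >= schedule$start_s[i] - 1e-9 & t < schedule$end_s[i] - 1e-9
    state[inside] <- schedule$state[i]
  }
  state[is.na(state)] <- schedule$state[nrow(schedule)]
  state
}

# triangular envelope over event duration: 0 -> 1 -> 0
event_envelope <- function(n_frames, at, dur_frames) {
  env <- numeric(n_frames)
  for (a in at) {
    idx <- a:min(n_frames, a + dur_frames - 1)
    u <- (idx - a) / max(1, dur_frames - 1)
    env[idx] <- pmax(env[idx], 1 - abs(2 * u - 1))
  }
  env
}

#' Simulate one recording session
#'
#' Generates all streams the pipeline consumes, with ground truth:
#'
#' * heart rate: an Ornstein-Uhlenbeck process reverting to the scheduled
#'   state's mean;
#' * RGB trace: baseline + pulse `sin(2 pi integral f dt)` with a
#'   0.3-amplitude second harmonic injected with green-dominant
#'   amplitudes, plus white noise and occasional step artifacts;
#' * landmarks: the neutral [face_template()] under a rigid random walk
#'   (state-scaled step), Poisson blink events collapsing the eye
#'   contours over 300 ms, and Poisson mouth/brow events deforming the
#'   lips and inner brows over 500 ms;
#' * sensor heart rate: the ground-truth trajectory sampled at 1 Hz with
#'   +/- 1 bpm uniform jitter.
#'
#' Deterministic for a given seed.
#'
#' @param profile A [sim_profile()].
#' @param schedule A [state_schedule()] covering `[0, T)`.
#' @param fps Frames per second (default 50).
#' @param seed RNG seed.
#' @return A list of class `sim_session`: `track` ([landmark_track()]),
#'   `trace` ([rgb_trace()]), `sensor` (tibble `t`, `bpm`), `truth`
#'   (tibble `t`, `hr`, `state`), `schedule`, `fps`, `seed`.
#' @export
simulate_session <- function(profile, schedule, fps = 50, seed = 1L) {
  schedule <- state_schedule(schedule$state, schedule$start_s, schedule$end_s)
  T_end <- schedule$end_s[nrow(schedule)]
  n <- as.integer(round(T_end * fps))
  dt <- 1 / fps
  t <- (seq_len(n) - 1) * dt
  state <- state_at(schedule, t)
  with_seed(seed, {
    # --- heart rate: OU around the state mean ---
    theta <- 0.5 # mean-reversion rate, 1/s
    sig <- profile$hr_drift * sqrt(2 * theta)
    per_state <- function(par) {
      unname(c(boredom = par[["boredom"]], stress = par[["stress"]])[state])
    }
    mu <- per_state(profile$hr_bpm)
    hr <- numeric(n)
    hr[1] <- mu[1]
    eps <- rnorm(n)
    for (i in 2:n) {
      hr[i] <- hr[i - 1] + theta * (mu[i] - hr[i - 1]) * dt +
        sig * sqrt(dt) * eps[i]
    }
    hr <- pmin(240, pmax(45, hr))

    # --- RGB trace: pulse + noise + step artifacts ---
    phase <- 2 * pi * cumsum(hr / 60 * dt)
    pulse <- sin(phase) + 0.3 * sin(2 * phase)
    n_art <- rpois(1, profile$artifact_rate * T_end)
    art <- numeric(n)
    if (n_art > 0) {
      at <- sort(sample.int(n, n_art))
      jumps <- rnorm(n_art, 0, 3)
      for (j in seq_len(n_art)) art[at[j]:n] <- art[at[j]:n] + jumps[j]
    }
    base <- c(r = 120, g = 100, b = 80)
    chan <- lapply(c("r", "g", "b"), function(ch) {
      base[[ch]] + profile$pulse_amp[[ch]] * pulse +
        rnorm(n, 0, profile$noise_sd) + art
    })
    trace <- rgb_trace(t, chan[[1]], chan[[2]], chan[[3]], fps = fps)

    # --- landmarks ---
    template <- face_template()
    # rigid head motion: random walk with mild anchoring so the face
    # stays in frame
    step_sd <- per_state(profile$motion_step)
    shift <- matrix(0, n, 2)
    for (i in 2:n) {
      shift[i, ] <- shift[i - 1, ] * (1 - 0.002) +
        rnorm(2, 0, step_sd[i])
    }
    # Poisson events per state (thinning by per-frame probability)
    draw_events <- function(rates) which(runif(n) < rates * dt)
    blinks <- draw_events(per_state(profile$blink_rate))
    facial <- draw_events(per_state(profile$event_rate))
    blink_env <- event_envelope(n, blinks, max(2L, as.integer(round(0.3 * fps))))
    facial_env <- event_envelope(n, facial, max(2L, as.integer(round(0.5 * fps))))

    pts <- array(rep(template, each = n), dim = c(n, 68, 2))
    # blinks: collapse eye contours toward each eye's centreline
    for (eye_idx in list(37:42, 43:48)) {
      cy <- mean(template[eye_idx, 2])
      for (j in eye_idx) {
        pts[, j, 2] <- cy + (template[j, 2] - cy) * (1 - blink_env)
      }
    }
    # facial events: widen mouth corners, draw inner brows together
    mouth_l <- 49; mouth_r <- 55 # 1-based points 48 and 54
    pts[, mouth_l, 1] <- pts[, mouth_l, 1] - 6 * facial_env
    pts[, mouth_r, 1] <- pts[, mouth_r, 1] + 6 * facial_env
    brow_r <- 22; brow_l <- 23 # 1-based points 21 and 22
    pts[, brow_r, 1] <- pts[, brow_r, 1] + 5 * facial_env
    pts[, brow_l, 1] <- pts[, brow_l, 1] - 5 * facial_env
    pts[, , 1] <- pts[, , 1] + shift[, 1]
    pts[, , 2] <- pts[, , 2] + shift[, 2]
    track <- landmark_track(t, pts, fps = fps)

    # --- 1 Hz sensor HR ---
    ts <- seq(0, floor(T_end - 1))
    idx <- pmin(n, as.integer(round(ts * fps)) + 1L)
    sensor <- tibble(t = ts, bpm = hr[idx] + runif(length(ts), -1, 1))

    structure(list(
      track = track, trace = trace, sensor = sensor,
      truth = tibble(t = t, hr = hr, state = state),
      schedule = schedule, fps = fps, seed = seed
    ), class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session: %.0f s @ %g fps, states %s>\n",
              max(x$truth$t) + 1 / x$fps, x$fps,
              paste(unique(x$schedule$state), collapse = "/")))
  invisible(x)
}

# evaluation-level design pattern: which scheduled state each of the 7
# levels elicits (3 and 6 stressful, 4 and 7 boring, others mixed)
level_design <- function() {
  tibble(level = 1:7,
         name = c("A1", "A2", "A3", "B1", "B2", "B3", "C1"),
         design = c("mixed", "mixed", "stress", "boredom",
                    "mixed", "stress", "boredom"))
}

level_schedule <- function(design, duration_s) {
  switch(design,
    stress = state_schedule("stress", 0, duration_s),
    boredom = state_schedule("boredom", 0, duration_s),
    mixed = state_schedule(c("boredom", "stress"),
                           c(0, duration_s / 2),
                           c(duration_s / 2, duration_s)))
}

sim_reports <- function(design, confusion, n_levels = length(design)) {
  draw <- function(d) {
    flip <- runif(1) < confusion
    d_eff <- if (!flip) d else switch(d, stress = "boredom",
                                      boredom = "stress", mixed = "mixed")
    switch(d_eff,
      stress = c(rstress = sample(4:5, 1), rboredom = sample(1:2, 1)),
      boredom = c(rstress = sample(1:2, 1), rboredom = sample(4:5, 1)),
      mixed = c(rstress = sample(2:3, 1), rboredom = sample(2:3, 1)))
  }
  m <- t(vapply(design, draw, numeric(2)))
  tibble(level = seq_len(nrow(m)), rstress = as.integer(m[, 1]),
         rboredom = as.integer(m[, 2]))
}

#' Simulate a cohort of subjects
#'
#' Per subject: three calibration sessions whose schedule is boredom for
#' the first half and stress for the second (emulating the
#' ramping-difficulty elicitation design, so that the post-warm-up first
#' third is purely boring and the final third purely stressful); for
#' study 2, seven evaluation levels whose scheduled states follow the
#' evaluation-game design (levels 3 and 6 stressful, 4 and 7 boring,
#' others mixed) together with Likert self-reports consistent with the
#' schedule. Subject-level parameter jitter (baseline heart rate +/- 5
#' bpm, mild rate jitter) provides cohort heterogeneity.
#'
#' @param n_subjects Number of subjects.
#' @param study 1 (calibration games only) or 2 (adds evaluation levels
#'   and self-reports).
#' @param profile A [sim_profile()]; per-subject jitter is applied on top.
#' @param seed Cohort RNG seed.
#' @param cal_duration_s Calibration-session duration (default 165 s).
#' @param level_duration_s Evaluation-level duration (default 90 s).
#' @param fps Frames per second (default 50).
#' @param exclude_subjects Subject ids flagged as excluded in the
#'   manifest (calibration problems; default none).
#' @param manifest_only If `TRUE`, skip signal synthesis and return only
#'   the cohort manifest and self-reports (design bookkeeping is cheap
#'   even for large cohorts).
#' @return A list of class `sim_cohort`: `subjects` (list with per-subject
#'   `calibration` sessions, `evaluation` sessions, `reports`),
#'   `manifest` ([session_manifest()] across the cohort), `profile`,
#'   `study`, `seed`.
#' @export
simulate_cohort <- function(n_subjects, study = 2, profile = sim_profile(),
                            seed = 1L, cal_duration_s = 165,
                            level_duration_s = 90, fps = 50,
                            exclude_subjects = integer(0),
                            manifest_only = FALSE) {
  stopifnot(n_subjects >= 1, study %in% c(1, 2))
  seeds <- with_seed(seed, matrix(sample.int(2^30, n_subjects * 12),
                                  nrow = n_subjects))
  cal_sched <- state_schedule(c("boredom", "stress"),
                              c(0, cal_duration_s / 2),
                              c(cal_duration_s / 2, cal_duration_s))
  design <- level_design()
  subjects <- lapply(seq_len(n_subjects), function(i) {
    prof_i <- with_seed(seeds[i, 1], {
      p <- profile
      jit <- rnorm(1, 0, 2.5)
      p$hr_bpm <- setNames(pmin(240, pmax(45, p$hr_bpm + jit)), names(p$hr_bpm))
      p$blink_rate <- p$blink_rate * runif(1, 0.9, 1.1)
      p$motion_step <- p$motion_step * runif(1, 0.9, 1.1)
      p
    })
    calibration <- if (!manifest_only) lapply(1:3, function(g) {
      simulate_session(prof_i, cal_sched, fps = fps, seed = seeds[i, 1 + g])
    })
    evaluation <- NULL
    reports <- NULL
    if (study == 2) {
      if (!manifest_only) {
        evaluation <- lapply(design$level, function(m) {
          simulate_session(prof_i, level_schedule(design$design[m], level_duration_s),
                           fps = fps, seed = seeds[i, 4 + m])
        })
      }
      reports <- with_seed(seeds[i, 12],
                           sim_reports(design$design, profile$report_confusion))
      reports <- dplyr::mutate(reports, subject = i, .before = 1)
    }
    list(subject = i, profile = prof_i, calibration = calibration,
         evaluation = evaluation, reports = reports)
  })
  manifest <- purrr::map_dfr(subjects, function(su) {
    cal <- session_manifest(
      subject = su$subject, kind = "calibration", id = 1:3,
      start_s = 0, end_s = cal_duration_s,
      excluded = su$subject %in% exclude_subjects,
      reason = ifelse(su$subject %in% exclude_subjects,
                      "calibration problem", NA_character_))
    if (study == 2) {
      ev <- session_manifest(subject = su$subject, kind = "evaluation",
                             id = 1:7, start_s = 0, end_s = level_duration_s)
      bind_rows(cal, ev)
    } else {
      cal
    }
  })
  class(manifest) <- c("session_manifest", class(tibble()))
  structure(list(subjects = subjects, manifest = manifest, profile = profile,
                 study = study, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort: %d subjects, study %d>\n",
              length(x$subjects), x$study))
  invisible(x)
}
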