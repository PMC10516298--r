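test_that("BCEA has its closed form, degenerate zero and quadratic scaling", {
  expect_equal(bcea(0, 0, 0), 0)
  expect_equal(bcea(1, 1, 0), 2 * pi * (-log(0.05)), tolerance = 1e-12)
  expect_equal(bcea(1, 1, 0), 18.82, tolerance = 1e-3)
  expect_equal(bcea(2, 2, 0) / bcea(1, 1, 0), 4) # doubling both sigmas quadruples
  expect_lt(bcea(1, 1, 0.6), bcea(1, 1, 0))
  expect_error(bcea(-1, 1, 0), ">= 0")
  # on sampled data: estimated BCEA from 2x-scaled samples is ~4x
  withr::with_seed(1, {
    x <- rnorm(5000); y <- rnorm(5000)
  })
  b1 <- bcea(sd(x), sd(y), cor(x, y))
  b2 <- bcea(sd(2 * x), sd(2 * y), cor(2 * x, 2 * y))
  expect_equal(b2 / b1, 4, tolerance = 1e-9)
})

test_that("identical gaze points give zero BCEA through the fixation pipeline", {
  spec <- make_task_battery(1)$fixation
  sim <- simulate_gaze_recording(spec, quiet_truth(), seed = 1)
  rec <- remove_artifacts(sim$recording)
  ev <- detect_saccades(rec)
  out <- compute_fixation_params(rec, ev, spec)
  expect_equal(out$fix_bcea95, 0, tolerance = 1e-12)
  expect_equal(out$fix_intrusion_rate, 0)
  expect_true(is.na(out$fix_intrusion_amp)) # no intrusions: structurally missing
})

test_that("planted intrusion rate is recovered within Poisson error", {
  truth <- planted_truth(intrusion_rate = 0.5, blink_rate = 0,
                         fix_sigma_x = 0.15, fix_sigma_y = 0.15)
  spec <- make_task_battery(1)$fixation
  rates <- sapply(1:8, function(seed) {
    sim <- simulate_gaze_recording(spec, truth, seed)
    rec <- remove_artifacts(sim$recording)
    compute_fixation_params(rec, detect_saccades(rec), spec)$fix_intrusion_rate
  })
  # ~0.5/s over 8 x 5 trials x ~5.9 s analysed: Poisson SE ~0.046
  expect_lt(abs(mean(rates) - 0.5), 3 * sqrt(0.5 / (8 * 5 * 5.9)) + 0.05)
})

# hand-built one-trial pro-saccade scenario
pro_scenario <- function(amplitude, target_x = 10) {
  spec <- tibble::tibble(
    trial = 1L, fix_onset = 0, fix_dur = 1, target_onset = 1,
    target_offset = 2.5, target_x = target_x, target_y = 0,
    eccentricity = abs(target_x), ecc_class = "large"
  )
  n <- 150
  t <- (seq_len(n) - 1) / 60
  x <- ifelse(t < 1.2, 0, amplitude)
  rec <- remove_artifacts(as_recording(x))
  ev <- tibble::tibble(
    event = 1L, onset_s = 1.2, offset_s = 1.25, t_peak = 1.22,
    amplitude_deg = amplitude, angle_deg = 0,
    peak_vel_dps = main_sequence(amplitude, 500, 6), eta = 500, c = 6,
    t0_s = 1.2, rmse_deg = 0, fitted = TRUE, provenance = "detected"
  )
  list(spec = spec, rec = rec, ev = ev)
}

test_that("pro-saccade gain is amplitude over eccentricity", {
  sc <- pro_scenario(10)
  out <- compute_prosaccade_params(sc$rec, sc$ev, sc$spec)
  expect_equal(out$pro_gain_large, 1.0)
  expect_equal(out$pro_latency_large, 200)
  expect_true(is.na(out$pro_gain_short)) # no short trials: missing per class
  expect_lte(out$pro_latency_large, out$pro_ttt_large)

  sc5 <- pro_scenario(5)
  out5 <- compute_prosaccade_params(sc5$rec, sc5$ev, sc5$spec)
  expect_equal(out5$pro_gain_large, 0.5)
  expect_true(is.na(out5$pro_ttt_large)) # never reaches the 2-degree radius
})

test_that("trials without an in-window saccade are invalid; all invalid means missing", {
  sc <- pro_scenario(10)
  late <- sc$ev
  late$onset_s <- 2.1 # outside the 80-800 ms acceptance window
  out <- compute_prosaccade_params(sc$rec, late, sc$spec)
  expect_true(all(is.na(unlist(out))))
})

test_that("planted pro-saccade latency is recovered within 2 SEM over the large trials", {
  truth <- planted_truth(latency_pro_mean = 220, latency_pro_sd = 30)
  battery <- make_task_battery(5)
  lats <- c()
  for (seed in 1:3) {
    sim <- simulate_gaze_recording(battery$prosaccade, truth, seed + 40)
    rec <- remove_artifacts(sim$recording)
    ev <- fit_saccades(rec, detect_saccades(rec))
    out <- compute_prosaccade_params(rec, ev, battery$prosaccade)
    lats <- c(lats, out$pro_latency_short, out$pro_latency_large)
  }
  expect_lt(abs(mean(lats) - 220), 2 * 30 / sqrt(3 * 24) + 3)
})

# hand-built anti-saccade trial: first saccade toward/away, optional correction
anti_scenario <- function(first_dir, side = -1, t_first = 1.25, t_second = NA) {
  trial <- tibble::tibble(
    trial = 1L, side = side, fix_onset = 0, fix_dur = 1, target_onset = 1,
    target_x = side * 10, target_y = 0, blank_onset = 1.1, arrow_onset = 2.3,
    arrow_dir = "up", answer_onset = 2.7, answer_offset = 7.7
  )
  ev <- tibble::tibble(
    event = 1L, onset_s = t_first, offset_s = t_first + 0.06,
    t_peak = t_first + 0.03, amplitude_deg = 9.5,
    angle_deg = ifelse(first_dir > 0, 0, 180),
    peak_vel_dps = 400, eta = 500, c = 6, t0_s = t_first, rmse_deg = 0,
    fitted = TRUE, provenance = "detected"
  )
  if (!is.na(t_second)) {
    second <- ev
    second$event <- 2L
    second$onset_s <- t_second
    second$offset_s <- t_second + 0.08
    second$t_peak <- t_second + 0.04
    second$angle_deg <- ifelse(first_dir > 0, 180, 0)
    second$amplitude_deg <- 19
    second$t0_s <- t_second
    ev <- dplyr::bind_rows(ev, second)
  }
  n <- 480
  t <- (seq_len(n) - 1) / 60
  x <- numeric(n)
  x[t >= t_first] <- first_dir * 9.5
  if (!is.na(t_second)) x[t >= t_second] <- -first_dir * 9.5
  list(trial = trial, rec = remove_artifacts(as_recording(x)), ev = ev)
}

test_that("anti-saccade trials classify by first-saccade direction", {
  # target left, first saccade left -> error
  sc <- anti_scenario(first_dir = -1, side = -1)
  out <- classify_antisaccade_trial(sc$rec, sc$ev, sc$trial)
  expect_equal(out$class, "uncorrected_error")
  expect_equal(out$latency_ms, 250)
  expect_true(is.na(out$time_to_target_ms))

  # error at 250 ms corrected at 480 ms -> corrected error, ttc 230 ms
  sc2 <- anti_scenario(first_dir = -1, side = -1, t_second = 1.48)
  out2 <- classify_antisaccade_trial(sc2$rec, sc2$ev, sc2$trial)
  expect_equal(out2$class, "corrected_error")
  expect_equal(out2$time_to_correct_ms, 230)
  expect_equal(out2$time_to_target_ms, 560, tolerance = 1e-9) # end of corrective saccade

  # target left, first saccade right -> correct
  sc3 <- anti_scenario(first_dir = 1, side = -1)
  out3 <- classify_antisaccade_trial(sc3$rec, sc3$ev, sc3$trial)
  expect_equal(out3$class, "correct")

  # no qualifying saccade -> invalid
  out4 <- classify_antisaccade_trial(sc$rec, sc$ev[0, ], sc$trial)
  expect_equal(out4$class, "invalid")
})

test_that("anti-saccade rates are simple counts over the right denominators", {
  trials <- tibble::tibble(
    trial = 1:12,
    class = c(rep("correct", 6), rep("corrected_error", 3),
              "uncorrected_error", rep("invalid", 2)),
    latency_ms = c(rnorm(6, 280), rnorm(3, 230), 230, NA, NA),
    time_to_correct_ms = c(rep(NA, 6), 210, 250, 230, rep(NA, 3)),
    time_to_target_ms = c(rnorm(6, 400), rnorm(3, 600), NA, NA, NA)
  )
  out <- compute_antisaccade_params(trials)
  expect_equal(out$anti_error_rate, 0.4)
  expect_equal(out$anti_correction_rate, 0.75)
  expect_equal(out$anti_time_to_correct, 230)

  no_err <- trials[trials$class == "correct", ]
  out2 <- compute_antisaccade_params(no_err)
  expect_equal(out2$anti_error_rate, 0)
  expect_true(is.na(out2$anti_correction_rate)) # empty denominator
  expect_true(is.na(out2$anti_time_to_correct))

  all_inv <- trials[trials$class == "invalid", ]
  out3 <- compute_antisaccade_params(all_inv)
  expect_true(all(is.na(unlist(out3))))
})

test_that("classification partitions the trials and corrected errors never exceed errors", {
  truth <- planted_truth(anti_error_prob = 0.4, anti_correction_prob = 0.6)
  battery <- make_task_battery(9)
  sim <- simulate_gaze_recording(battery$antisaccade, truth, 31)
  rec <- remove_artifacts(sim$recording)
  ev <- fit_saccades(rec, detect_saccades(rec))
  spec <- battery$antisaccade
  trials <- dplyr::bind_rows(lapply(seq_len(nrow(spec)), function(i)
    classify_antisaccade_trial(rec, ev, spec[i, ])))
  expect_equal(nrow(trials), nrow(spec))
  tab <- table(factor(trials$class, levels = c("correct", "corrected_error",
                                               "uncorrected_error", "invalid")))
  expect_equal(sum(tab), nrow(spec))
  expect_lte(tab[["corrected_error"]], tab[["corrected_error"]] + tab[["uncorrected_error"]])
})

test_that("perfect tracking gives pursuit gain 1, zero lag, full pursuit time and no catch-ups", {
  spec <- make_task_battery(1)$pursuit
  truth <- quiet_truth(pursuit_gain = 1, pursuit_lag = 0, catchup_threshold = 50,
                       pursuit_latency = 1e-6)
  sim <- simulate_gaze_recording(spec, truth, 3)
  rec <- remove_artifacts(sim$recording)
  vel <- estimate_velocity(rec)
  ev <- detect_saccades(rec, vel = vel)[0, ] # "no saccades": empty event list
  out <- compute_pursuit_params(rec, ev, spec, vel = vel)
  expect_equal(out$pursuit_gain, 1, tolerance = 0.02)
  expect_lt(out$pursuit_lag, 1.6) # the 1.5-degree step is never fully closed
  expect_equal(out$pursuit_prop_time, 1)
  expect_equal(out$pursuit_catchup_count, 0)
})

test_that("eye speed at 80% of target speed reads out as gain 0.8", {
  spec <- make_task_battery(1)$pursuit
  truth <- quiet_truth(pursuit_gain = 0.8, catchup_threshold = 50,
                       pursuit_latency = 1e-6)
  sim <- simulate_gaze_recording(spec, truth, 4)
  rec <- remove_artifacts(sim$recording)
  out <- compute_pursuit_params(rec, detect_saccades(rec)[0, ], spec)
  expect_equal(out$pursuit_gain, 0.8, tolerance = 0.02)
})

test_that("desaccading recovers the planted gain in the presence of catch-up saccades", {
  spec <- make_task_battery(1)$pursuit
  truth <- planted_truth(pursuit_gain = 0.75, fix_sigma_x = 0.15,
                         fix_sigma_y = 0.15, blink_rate = 0)
  gains <- sapply(1:6, function(seed) {
    sim <- simulate_gaze_recording(spec, truth, seed + 50)
    rec <- remove_artifacts(sim$recording)
    vel <- estimate_velocity(rec)
    ev <- fit_saccades(rec, detect_saccades(rec, vel = vel))
    compute_pursuit_params(rec, ev, spec, vel = vel)$pursuit_gain
  })
  expect_gt(sum(sapply(1:6, function(seed)
    sum(simulate_gaze_recording(spec, truth, seed + 50)$events$kind == "catchup"))), 5)
  expect_lt(abs(mean(gains) - 0.75), 0.05)
})

test_that("profiles assemble into the canonical 20 (+1) slots with explicit missingness", {
  nms <- oculomotor_parameters()
  expect_length(nms, 20)
  expect_length(oculomotor_parameters(TRUE), 21)

  fix <- tibble::tibble(fix_bcea95 = 1, fix_intrusion_rate = 0.2,
                        fix_intrusion_amp = 1.1)
  pur <- tibble::tibble(pursuit_gain = 0.9, pursuit_lag = 0.4,
                        pursuit_prop_time = 0.95, pursuit_catchup_count = 3)
  prof <- assemble_profile(fixation = fix, pursuit = pur)
  expect_equal(names(prof), oculomotor_parameters(TRUE))
  anti_slots <- grep("^anti_", names(prof), value = TRUE)
  expect_length(anti_slots, 6) # 5 canonical + optional time-to-target
  expect_true(all(is.na(prof[anti_slots])))
  expect_true(all(!is.na(prof[names(fix)])))

  expect_error(assemble_profile(fixation = fix, pursuit = fix), "Duplicate")
})

test_that("a profile table round-trips through CSV unchanged", {
  prof <- assemble_profile(
    fixation = tibble::tibble(fix_bcea95 = 1.25, fix_intrusion_rate = 0.3,
                              fix_intrusion_amp = NA_real_)
  )
  prof <- dplyr::bind_cols(tibble::tibble(participant = "P001"), prof)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(prof, path)
  back <- read_profiles_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
})
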