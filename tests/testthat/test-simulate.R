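test_that("a noise-free fixation simulation is constant at the target during fixation epochs", {
  spec <- make_task_battery(seed = 1)$fixation
  sim <- simulate_gaze_recording(spec, quiet_truth(), seed = 2)
  rec <- sim$recording
  for (i in seq_len(nrow(spec))) {
    epoch <- rec$t_s >= spec$onset[i] + 1.5 & rec$t_s <= spec$offset[i] - 0.1
    expect_equal(rec$x_deg[epoch], rep(spec$target_x[i], sum(epoch)),
                 tolerance = 1e-6)
    expect_equal(rec$y_deg[epoch], rep(spec$target_y[i], sum(epoch)),
                 tolerance = 1e-6)
  }
})

test_that("noise-free unit-gain pursuit moves at the 8.65 deg/s target speed on the ramp", {
  spec <- make_task_battery(seed = 1)$pursuit
  truth <- quiet_truth(pursuit_gain = 1, pursuit_lag = 0,
                       catchup_threshold = 50)
  sim <- simulate_gaze_recording(spec, truth, seed = 3)
  vel <- estimate_velocity(remove_artifacts(sim$recording))
  expect_equal(nrow(sim$events), 3) # only inter-trial refixations
  for (i in seq_len(nrow(spec))) {
    core <- vel$t_s >= spec$ramp_onset[i] + truth$pursuit_latency + 0.1 &
      vel$t_s <= spec$ramp_offset[i] - 0.1
    v_along <- vel$vx[core] * spec$dir_x[i] + vel$vy[core] * spec$dir_y[i]
    expect_equal(mean(v_along), 8.65, tolerance = 0.01)
  }
})

test_that("zero latency spread pins every planted pro-saccade onset to the latency after target onset", {
  spec <- make_task_battery(seed = 4)$prosaccade
  sim <- simulate_gaze_recording(spec, quiet_truth(latency_pro_mean = 200),
                                 seed = 5)
  pro <- dplyr::filter(sim$events, kind == "pro")
  expect_equal(nrow(pro), 24)
  lat <- pro$t_on - spec$target_onset[pro$trial]
  expect_equal(lat, rep(0.2, 24), tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed", {
  spec <- make_task_battery(seed = 1)$prosaccade
  truth <- planted_truth()
  a <- simulate_gaze_recording(spec, truth, seed = 9)
  b <- simulate_gaze_recording(spec, truth, seed = 9)
  expect_identical(a$recording, b$recording)
  expect_identical(a$events, b$events)
  c <- simulate_gaze_recording(spec, truth, seed = 10)
  expect_false(identical(a$recording$x_deg, c$recording$x_deg))
})

test_that("every logged saccade displaces the noise-free trace by its amplitude", {
  # the logged onset/offset bracket the 1%..99% traversal of the waveform,
  # so the displacement between them is 0.98 * amplitude
  truth <- quiet_truth(intrusion_rate = 0.4)
  for (task in c("fixation", "prosaccade")) {
    spec <- make_task_battery(seed = 2)[[task]]
    sim <- simulate_gaze_recording(spec, truth, seed = 6)
    rec <- sim$recording
    for (j in seq_len(nrow(sim$events))) {
      ev <- sim$events[j, ]
      # bracketing samples: a 30 ms intrusion spans ~2 samples, so the
      # nearest-sample positions can sit well inside the ramp
      i0 <- max(which(rec$t_s <= ev$t_on))
      i1 <- min(which(rec$t_s >= ev$t_off))
      disp <- sqrt((rec$x_deg[i1] - rec$x_deg[i0])^2 +
                     (rec$y_deg[i1] - rec$y_deg[i0])^2)
      expect_lt(abs(disp - ev$amplitude), 0.05 * ev$amplitude + 0.05)
    }
  }
})

test_that("ground-truth peak velocities follow the planted main sequence", {
  truth <- planted_truth(eta = 450, c = 5)
  sim <- simulate_gaze_recording(make_task_battery(1)$prosaccade, truth, 7)
  expect_equal(sim$events$peak_vel,
               main_sequence(sim$events$amplitude, 450, 5), tolerance = 1e-12)
})

test_that("blink gaps appear as invalid runs of 100-300 ms", {
  truth <- planted_truth(blink_rate = 0.5)
  sim <- simulate_gaze_recording(make_task_battery(1)$fixation, truth, 8)
  runs <- rle(!sim$recording$valid)
  gaps <- runs$lengths[runs$values] / 60
  expect_gt(length(gaps), 0)
  expect_true(all(gaps >= 0.08)) # at least a 100 ms blink (blinks may merge)
  expect_true(all(is.na(sim$recording$x_deg[!sim$recording$valid])))
})

test_that("an invalid task spec is rejected", {
  spec <- make_task_battery(1)$fixation
  attr(spec, "duration_s") <- 0
  expect_error(simulate_gaze_recording(spec, planted_truth(), 1), "duration")
  expect_error(simulate_gaze_recording(data.frame(), planted_truth(), 1),
               "task spec")
})

test_that("a zero-noise identity severity map yields EDSS exactly equal to severity", {
  cfg <- cohort_config(
    n_participants = 3, seed = 1, severity = c(1, 2, 3),
    clinical_map = list(edss = list(base = 0, beta = 1, sd = 0)),
    effect_map = list(), simulate_gaze = FALSE
  )
  cs <- simulate_cohort(cfg)
  expect_equal(cs$cohort$edss, c(1, 2, 3))
})

test_that("cohort simulation has the right cardinalities and is seed-deterministic", {
  cfg <- cohort_config(n_participants = 60, seed = 2, simulate_gaze = FALSE)
  cs <- simulate_cohort(cfg)
  expect_equal(nrow(cs$cohort), 60)
  expect_equal(nrow(cs$truths), 60)
  expect_true(all(cs$cohort$edss %% 0.5 == 0))
  expect_true(all(cs$cohort$edss >= 0 & cs$cohort$edss <= 10))
  cs2 <- simulate_cohort(cfg)
  expect_identical(cs$cohort, cs2$cohort)

  cfg_gaze <- cohort_config(n_participants = 2, seed = 3)
  rec <- simulate_cohort(cfg_gaze)$recordings
  expect_equal(nrow(rec), 2 * 4) # four task recordings per participant
})

test_that("a strong severity-latency coupling shows up as a large positive Spearman correlation", {
  cfg <- cohort_config(
    n_participants = 200, seed = 7, simulate_gaze = FALSE,
    effect_map = list(latency_pro_mean = list(base = 220, beta = 40, sd = 5,
                                              link = "identity"))
  )
  cs <- simulate_cohort(cfg)
  rho <- cor(cs$truths$latency_pro_mean, cs$cohort$edss, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("an effect map naming an unknown parameter is rejected up front", {
  expect_error(
    cohort_config(effect_map = list(not_a_parameter = list(base = 1, beta = 0, sd = 0))),
    "unknown planted-truth parameter"
  )
  expect_error(
    cohort_config(clinical_map = list(iq = list(base = 100, beta = 0, sd = 0))),
    "unknown score"
  )
  expect_error(cohort_config(n_participants = 1), ">= 2")
})
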