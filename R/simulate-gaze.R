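# Gaze-trace simulator: renders a 60 Hz cyclopean gaze trace for one task
# spec and one planted truth, together with a ground-truth event log.
#
# Saccades are rendered with the same parametric waveform family the
# extraction stage fits: position along the saccade direction follows a
# logistic ramp s(t) = A * plogis(k * (t - tm)) whose peak velocity
# A*k/4 is pinned to the main sequence Vp = eta*(1 - exp(-A/c)).  The
# nominal onset/offset bracket the 1%..99% traversal of the ramp, so a
# planted saccade of amplitude A displaces the trace by 0.98 * A between
# its logged onset and offset (and by A overall).

saccade_kinematics <- function(amplitude, eta, c) {
  vp <- main_sequence(amplitude, eta, c)
  k <- 4 * vp / amplitude
  half <- log(99) / k
  list(vp = vp, k = k, duration = 2 * half, half = half)
}

# one logged saccade event; from/to are 2-vectors, t_on is the 1% point
make_event <- function(kind, trial, t_on, from, to, eta, c) {
  delta <- to - from
  amplitude <- sqrt(sum(delta^2))
  kin <- saccade_kinematics(amplitude, eta, c)
  tibble(
    kind = kind, trial = trial,
    t_on = t_on, t_off = t_on + kin$duration, t_mid = t_on + kin$half,
    amplitude = amplitude, peak_vel = kin$vp, k = kin$k,
    dir_x = delta[1] / amplitude, dir_y = delta[2] / amplitude,
    x0 = from[1], y0 = from[2], x1 = to[1], y1 = to[2]
  )
}

# sum-of-logistic-ramps renderer: start position plus every event's
# displacement ramp evaluated at the sample times
render_saccade_path <- function(t, start, events) {
  x <- rep(start[1], length(t))
  y <- rep(start[2], length(t))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ramp <- plogis(events$k[i] * (t - events$t_mid[i]))
      x <- x + (events$x1[i] - events$x0[i]) * ramp
      y <- y + (events$y1[i] - events$y0[i]) * ramp
    }
  }
  list(x = x, y = y)
}

# Ornstein-Uhlenbeck fixational drift with stationary covariance
# (sigma_x^2, sigma_y^2, rho) and correlation time tau
ou_scatter <- function(n, dt, sigma_x, sigma_y, rho, tau) {
  if (sigma_x <= 0 && sigma_y <= 0) {
    return(cbind(numeric(n), numeric(n)))
  }
  phi <- exp(-dt / tau)
  sig <- matrix(c(sigma_x^2, rho * sigma_x * sigma_y,
                  rho * sigma_x * sigma_y, sigma_y^2), 2, 2)
  l <- tryCatch(chol(sig), error = function(e) NULL)
  z0 <- rnorm(2)
  innov <- matrix(rnorm(2 * n), n, 2) * sqrt(1 - phi^2)
  if (is.null(l)) { # degenerate (a zero sigma): scale axes independently
    out <- cbind(
      stats::filter(innov[, 1], phi, method = "recursive", init = z0[1]),
      stats::filter(innov[, 2], phi, method = "recursive", init = z0[2])
    )
    return(sweep(out, 2, c(sigma_x, sigma_y), `*`))
  }
  u <- cbind(
    stats::filter(innov[, 1], phi, method = "recursive", init = z0[1]),
    stats::filter(innov[, 2], phi, method = "recursive", init = z0[2])
  )
  u %*% l
}

# draws truncated-below normal values
rnorm_trunc <- function(n, mean, sd, lower) {
  pmax(lower, rnorm(n, mean, sd))
}

#' Simulate a 60 Hz gaze recording for one task
#'
#' Renders the eye's response to a task spec under a planted oculomotor
#' truth: targeting and return saccades with planted latency, gain and
#' main-sequence kinematics; fixational Ornstein–Uhlenbeck scatter plus
#' square-wave-jerk intrusion pairs; anti-saccade errors and corrections
#' drawn from the planted probabilities; smooth pursuit at the planted
#' gain interrupted by catch-up saccades whenever positional error would
#' exceed the planted threshold; blinks as invalid-sample gaps; and white
#' sensor noise at the planted precision.
#'
#' @param spec A task spec from [make_task_battery()].
#' @param truth A [planted_truth()].
#' @param seed Integer seed; the same (spec, truth, seed) reproduces the
#'   recording byte for byte.
#' @param rate Sampling rate (Hz).
#' @return A list of class `gaze_simulation` with elements
#'   * `recording`: tibble with columns `t_s`, `x_deg`, `y_deg`, `valid`;
#'   * `events`: ground-truth saccade log (kind, trial, exact onset/offset,
#'     amplitude, peak velocity, direction, start/end positions);
#'   * `spec`: the task spec (stimulus timeline).
#' @export
#' @examples
#' battery <- make_task_battery(seed = 1)
#' sim <- simulate_gaze_recording(battery$fixation, planted_truth(), seed = 2)
#' head(sim$recording)
simulate_gaze_recording <- function(spec, truth, seed = 1L, rate = 60) {
  if (!inherits(spec, "task_spec")) abort("`spec` must be a task spec from make_task_battery().")
  validate_planted_truth(truth)
  duration <- attr(spec, "duration_s")
  if (is.null(duration) || duration <= 0) abort("Invalid task spec: non-positive duration.")
  kind <- attr(spec, "task_kind")
  dt <- 1 / rate
  withr::with_seed(as.integer(seed), {
    t <- seq(0, duration - dt / 2, by = dt)
    sim <- switch(kind,
      fixation    = sim_fixation(t, spec, truth),
      prosaccade  = sim_prosaccade(t, spec, truth),
      antisaccade = sim_antisaccade(t, spec, truth),
      pursuit     = sim_pursuit(t, spec, truth),
      abort(sprintf("Unknown task kind '%s'.", kind))
    )
    n <- length(t)
    drift <- ou_scatter(n, dt, truth$fix_sigma_x, truth$fix_sigma_y,
                        truth$fix_rho, truth$scatter_tau)
    noise_sd <- truth$noise_rms_s2s / 2
    x <- sim$x + drift[, 1] + rnorm(n, 0, noise_sd) + truth$bias_deg
    y <- sim$y + drift[, 2] + rnorm(n, 0, noise_sd)
    valid <- rep(TRUE, n)
    n_blinks <- rpois(1, truth$blink_rate * duration)
    if (n_blinks > 0) {
      starts <- runif(n_blinks, 0, duration)
      durs <- runif(n_blinks, 0.1, 0.3)
      for (b in seq_len(n_blinks)) {
        valid[t >= starts[b] & t <= starts[b] + durs[b]] <- FALSE
      }
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    rec <- tibble(t_s = t, x_deg = x, y_deg = y, valid = valid)
  })
  structure(list(recording = rec, events = sim$events, spec = spec),
            class = c("gaze_simulation", "list"))
}

# intrusion pairs (square-wave jerks) inside [t0, t1] around position pos
swj_events <- function(t0, t1, pos, trial, truth) {
  window <- t1 - t0
  if (window <= 0 || truth$intrusion_rate <= 0) return(NULL)
  n_pairs <- rpois(1, truth$intrusion_rate / 2 * window)
  if (n_pairs == 0) return(NULL)
  starts <- sort(runif(n_pairs, t0, t1 - 0.6))
  keep <- c(TRUE, diff(starts) > 0.8) # pairs must not overlap
  starts <- starts[keep]
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    amp <- rnorm_trunc(1, truth$intrusion_amp_mean, truth$intrusion_amp_sd, 0.5)
    ang <- sample(c(0, pi), 1) + rnorm(1, 0, 0.15) # SWJs are mostly horizontal
    u <- c(cos(ang), sin(ang))
    out_ev <- make_event("intrusion", trial, starts[i], pos, pos + amp * u,
                         truth$eta, truth$c)
    back_ev <- make_event("intrusion", trial, out_ev$t_off + truth$swj_interval,
                          pos + amp * u, pos, truth$eta, truth$c)
    out[[i]] <- bind_rows(out_ev, back_ev)
  }
  bind_rows(out)
}

sim_fixation <- function(t, spec, truth) {
  events <- list()
  start <- c(spec$target_x[1], spec$target_y[1])
  pos <- start
  for (i in seq_len(nrow(spec))) {
    tgt <- c(spec$target_x[i], spec$target_y[i])
    if (i > 1 && sqrt(sum((tgt - pos)^2)) > 0.01) {
      lat <- rnorm_trunc(1, truth$latency_pro_mean, truth$latency_pro_sd, 90) / 1000
      ev <- make_event("transition", i, spec$onset[i] + lat, pos, tgt,
                       truth$eta, truth$c)
      events <- c(events, list(ev))
      pos <- tgt
    }
    settle <- if (i == 1) 0.3 else 1.0
    events <- c(events, list(
      swj_events(spec$onset[i] + settle, spec$offset[i] - 0.3, pos, i, truth)
    ))
  }
  events <- bind_rows(events)
  path <- render_saccade_path(t, start, events)
  list(x = path$x, y = path$y, events = events)
}

sim_prosaccade <- function(t, spec, truth) {
  events <- list()
  pos <- c(0, 0)
  for (i in seq_len(nrow(spec))) {
    if (i > 1 && sqrt(sum(pos^2)) > 0.01) { # return to the refixation point
      lat <- rnorm_trunc(1, truth$latency_pro_mean, truth$latency_pro_sd, 90) / 1000
      ev <- make_event("return", i, spec$fix_onset[i] + lat, pos, c(0, 0),
                       truth$eta, truth$c)
      events <- c(events, list(ev))
      pos <- c(0, 0)
    }
    lat <- rnorm_trunc(1, truth$latency_pro_mean, truth$latency_pro_sd, 90) / 1000
    gain <- max(0.3, rnorm(1, truth$amp_gain, truth$amp_gain_sd))
    land <- gain * c(spec$target_x[i], spec$target_y[i])
    ev <- make_event("pro", i, spec$target_onset[i] + lat, pos, land,
                     truth$eta, truth$c)
    events <- c(events, list(ev))
    pos <- land
  }
  events <- bind_rows(events)
  path <- render_saccade_path(t, c(0, 0), events)
  list(x = path$x, y = path$y, events = events)
}

sim_antisaccade <- function(t, spec, truth) {
  events <- list()
  pos <- c(0, 0)
  for (i in seq_len(nrow(spec))) {
    if (i > 1 && sqrt(sum(pos^2)) > 0.01) {
      lat <- rnorm_trunc(1, truth$latency_pro_mean, truth$latency_pro_sd, 90) / 1000
      ev <- make_event("return", i, spec$fix_onset[i] + lat, pos, c(0, 0),
                       truth$eta, truth$c)
      events <- c(events, list(ev))
      pos <- c(0, 0)
    }
    gain <- max(0.3, rnorm(1, truth$amp_gain, truth$amp_gain_sd))
    side <- spec$side[i]
    mirror <- c(-side * 10 * gain, 0)
    toward <- c(side * 10 * gain, 0)
    if (runif(1) < truth$anti_error_prob) {
      lat <- rnorm_trunc(1, truth$latency_anti_error_mean,
                         truth$latency_anti_error_sd, 90) / 1000
      err <- make_event("anti_error", i, spec$target_onset[i] + lat, pos,
                        toward, truth$eta, truth$c)
      events <- c(events, list(err))
      pos <- toward
      if (runif(1) < truth$anti_correction_prob) {
        ttc <- rnorm_trunc(1, truth$time_to_correct_mean,
                           truth$time_to_correct_sd, 80) / 1000
        corr <- make_event("anti_corrective", i, err$t_on + ttc, pos, mirror,
                           truth$eta, truth$c)
        events <- c(events, list(corr))
        pos <- mirror
      }
    } else {
      lat <- rnorm_trunc(1, truth$latency_anti_correct_mean,
                         truth$latency_anti_correct_sd, 90) / 1000
      ev <- make_event("anti_correct", i, spec$target_onset[i] + lat, pos,
                       mirror, truth$eta, truth$c)
      events <- c(events, list(ev))
      pos <- mirror
    }
  }
  events <- bind_rows(events)
  path <- render_saccade_path(t, c(0, 0), events)
  list(x = path$x, y = path$y, events = events)
}

sim_pursuit <- function(t, spec, truth) {
  x <- rep(0, length(t))
  y <- rep(0, length(t))
  events <- list()
  pos_prev_end <- c(0, 0)
  for (i in seq_len(nrow(spec))) {
    u <- c(spec$dir_x[i], spec$dir_y[i])
    v <- spec$speed[i]
    g <- truth$pursuit_gain
    t_on <- spec$ramp_onset[i] + truth$pursuit_latency
    trial_events <- list()
    if (i > 1 && sqrt(sum(pos_prev_end^2)) > 0.01) {
      lat <- rnorm_trunc(1, truth$latency_pro_mean, truth$latency_pro_sd, 90) / 1000
      ev <- make_event("return", i, spec$fix_onset[i] + lat, pos_prev_end,
                       c(0, 0), truth$eta, truth$c)
      events <- c(events, list(ev))
      # render the return saccade globally (it precedes this trial's ramp)
      ramp <- plogis(ev$k * (t - ev$t_mid))
      x <- x + (ev$x1 - ev$x0) * ramp
      y <- y + (ev$y1 - ev$y0) * ramp
    }
    # scalar positions along u, relative to screen centre
    target_s <- function(tt) spec$start_pos[i] + v * (tt - spec$ramp_onset[i])
    # piecewise pursuit: eye moves at g*v from anchors, catch-up saccades
    # fire when target leads the smooth-pursuit track by the threshold
    anchors_t <- t_on
    anchors_s <- 0
    repeat {
      t0 <- anchors_t[length(anchors_t)]
      s0 <- anchors_s[length(anchors_s)]
      lead0 <- target_s(t0) - s0 # current positional error
      if (v * (1 - g) <= 1e-9) break # no error growth: no catch-ups
      t_star <- t0 + (truth$catchup_threshold - lead0) / (v * (1 - g))
      if (t_star <= t0) t_star <- t0 + 1e-3
      if (t_star >= spec$ramp_offset[i] - 0.05) break
      amp <- truth$catchup_threshold - truth$pursuit_lag
      if (amp < 0.3) break
      s_pre <- s0 + g * v * (t_star - t0)
      from <- u * s_pre
      to <- u * (s_pre + amp)
      ev <- make_event("catchup", i, t_star, from, to, truth$eta, truth$c)
      trial_events <- c(trial_events, list(ev))
      anchors_t <- c(anchors_t, t_star)
      anchors_s <- c(anchors_s, s_pre + amp)
    }
    # render the trial's smooth component: 0 before onset, then piecewise
    in_trial <- t >= t_on & t <= spec$ramp_offset[i]
    seg <- findInterval(t[in_trial], anchors_t)
    s_smooth <- anchors_s[seg] + g * v * (t[in_trial] - anchors_t[seg])
    # catch-up displacement is carried by the saccade ramps; remove the
    # anchor jumps from the smooth component so ramps can re-add them
    if (length(anchors_t) > 1) {
      jumps <- diff(anchors_s) - g * v * diff(anchors_t)
      jump_before <- c(0, cumsum(jumps))
      s_smooth <- s_smooth - jump_before[seg]
    }
    x[in_trial] <- x[in_trial] + u[1] * s_smooth
    y[in_trial] <- y[in_trial] + u[2] * s_smooth
    # hold the final position after ramp end (next trial's return handles it)
    after <- t > spec$ramp_offset[i]
    s_end_smooth <- {
      seg_e <- length(anchors_t)
      base <- anchors_s[seg_e] + g * v * (spec$ramp_offset[i] - anchors_t[seg_e])
      if (length(anchors_t) > 1) base - sum(diff(anchors_s) - g * v * diff(anchors_t)) else base
    }
    x[after] <- x[after] + u[1] * s_end_smooth
    y[after] <- y[after] + u[2] * s_end_smooth
    trial_events <- bind_rows(trial_events)
    if (nrow(trial_events) > 0) {
      for (j in seq_len(nrow(trial_events))) {
        ramp <- plogis(trial_events$k[j] * (t - trial_events$t_mid[j]))
        x <- x + (trial_events$x1[j] - trial_events$x0[j]) * ramp
        y <- y + (trial_events$y1[j] - trial_events$y0[j]) * ramp
      }
      events <- c(events, list(trial_events))
    }
    s_end <- {
      seg_e <- length(anchors_t)
      anchors_s[seg_e] + g * v * (spec$ramp_offset[i] - anchors_t[seg_e])
    }
    pos_prev_end <- u * s_end
  }
  events <- bind_rows(events)
  if (nrow(events) > 0) events <- arrange(events, .data$t_on)
  list(x = x, y = y, events = events)
}
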