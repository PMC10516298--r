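# Per-task oculomotor parameters: fixation stability and intrusions,
# pro-saccade latency/accuracy/velocity, anti-saccade trial scoring, and
# smooth-pursuit gain/lag/catch-up metrics.

#' Bivariate contour ellipse area
#'
#' Area of the ellipse containing a given fraction of fixation gaze
#' points under a bivariate-Gaussian assumption:
#' `BCEA_P = 2 * pi * (-log(1 - P)) * sigma_x * sigma_y * sqrt(1 - rho^2)`.
#'
#' @param sigma_x,sigma_y Per-axis SDs of the fixation scatter (deg).
#' @param rho Correlation between the axes.
#' @param p Coverage probability (default 0.95).
#' @return Area in deg^2.
#' @export
#' @examples
#' bcea(1, 1, 0) # ~18.82 deg^2 at 95% coverage
bcea <- function(sigma_x, sigma_y, rho = 0, p = 0.95) {
  if (any(sigma_x < 0) || any(sigma_y < 0)) abort("sigmas must be >= 0.")
  if (any(abs(rho) > 1)) abort("|rho| must be <= 1.")
  2 * pi * (-log(1 - p)) * sigma_x * sigma_y * sqrt(1 - rho^2)
}

# samples falling inside any event interval (with one-sample margin)
in_event_mask <- function(t, events, dt, pad = 1) {
  mask <- rep(FALSE, length(t))
  if (is.null(events) || nrow(events) == 0) return(mask)
  for (i in seq_len(nrow(events))) {
    mask <- mask | (t >= events$onset_s[i] - pad * dt &
                      t <= events$offset_s[i] + pad * dt)
  }
  mask
}

#' Fixation-task parameters
#'
#' Per fixation trial, the 95% bivariate contour ellipse area is computed
#' from intrusion-free usable samples (the first second of each trial is
#' skipped to exclude the refixation transition), the saccadic-intrusion
#' rate is the number of detected saccades at or above the minimum
#' amplitude per second of analysed fixation time, and the intrusion
#' amplitude pools all intrusion events. BCEA and rate are averaged
#' across the (up to five) analysable trials; trials with under one
#' second of usable data are excluded.
#'
#' @param rec Preprocessed fixation-task recording.
#' @param events Detected (optionally fitted) event tibble.
#' @param spec Fixation task spec.
#' @param settings A [detection_settings()].
#' @param settle_s Initial per-trial interval excluded from analysis (s).
#' @return One-row tibble: `fix_bcea95`, `fix_intrusion_rate`,
#'   `fix_intrusion_amp`.
#' @export
compute_fixation_params <- function(rec, events, spec,
                                    settings = detection_settings(),
                                    settle_s = 1.0) {
  dt <- median(diff(rec$t_s))
  ev_mask <- in_event_mask(rec$t_s, events, dt)
  per_trial <- purrr::map(seq_len(nrow(spec)), function(i) {
    lo <- spec$onset[i] + settle_s
    hi <- spec$offset[i] - 0.1
    in_epoch <- rec$t_s >= lo & rec$t_s <= hi
    ok <- in_epoch & rec$usable & !ev_mask
    valid_time <- sum(in_epoch & rec$usable) * dt
    if (valid_time < 1) return(NULL)
    x <- rec$x_deg[ok]
    y <- rec$y_deg[ok]
    if (length(x) < 10) return(NULL)
    sx <- sd(x); sy <- sd(y)
    rho <- if (sx > 0 && sy > 0) cor(x, y) else 0
    intr <- events[events$t_peak >= lo & events$t_peak <= hi &
                     events$amplitude_deg >= settings$min_amp, , drop = FALSE]
    tibble(
      bcea95 = bcea(sx, sy, rho, 0.95),
      rate = nrow(intr) / valid_time,
      amps = list(intr$amplitude_deg)
    )
  }) %>% bind_rows()
  if (nrow(per_trial) == 0) {
    return(tibble(fix_bcea95 = NA_real_, fix_intrusion_rate = NA_real_,
                  fix_intrusion_amp = NA_real_))
  }
  amps <- unlist(per_trial$amps)
  tibble(
    fix_bcea95 = mean(per_trial$bcea95),
    fix_intrusion_rate = mean(per_trial$rate),
    fix_intrusion_amp = if (length(amps) > 0) mean(amps) else NA_real_
  )
}

# first time gaze enters `radius` of the target and stays `dwell_s`
time_to_target <- function(rec, t_from, t_to, target, radius = 2, dwell_s = 0.1) {
  idx <- which(rec$t_s >= t_from & rec$t_s <= t_to)
  if (length(idx) == 0) return(NA_real_)
  close_enough <- rec$usable[idx] &
    sqrt((rec$x_deg[idx] - target[1])^2 + (rec$y_deg[idx] - target[2])^2) <= radius
  r <- rle(close_enough)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- median(diff(rec$t_s))
  for (j in which(r$values)) {
    dur <- r$lengths[j] * dt
    lasts_to_end <- ends[j] == length(idx)
    if (dur >= dwell_s || lasts_to_end) {
      return(rec$t_s[idx[starts[j]]] - t_from)
    }
  }
  NA_real_
}

#' Pro-saccade task parameters
#'
#' Per trial, the primary saccade is the first detected event of at least
#' 1 degree whose onset falls in the 80–800 ms acceptance window after
#' target onset. Latency (ms) uses the event's refined onset, peak
#' velocity the fitted value, gain is the saccade amplitude divided by
#' the target eccentricity, and time-to-target (ms) is the time until
#' gaze first enters a 2-degree radius of the target and dwells there
#' 100 ms. Trial values are averaged within each eccentricity class.
#'
#' @param rec Preprocessed pro-saccade recording.
#' @param events Fitted event tibble.
#' @param spec Pro-saccade task spec.
#' @param settings A [detection_settings()].
#' @param window_ms Latency acceptance window after target onset (ms).
#' @return One-row tibble with the eight `pro_*` parameters.
#' @export
compute_prosaccade_params <- function(rec, events, spec,
                                      settings = detection_settings(),
                                      window_ms = c(80, 800)) {
  per_trial <- purrr::map(seq_len(nrow(spec)), function(i) {
    t_on <- spec$target_onset[i]
    win <- t_on + window_ms / 1000
    cand <- events[events$onset_s >= win[1] & events$onset_s <= win[2] &
                     events$amplitude_deg >= 1, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    first <- cand[which.min(cand$onset_s), ]
    ttt <- time_to_target(rec, t_on, spec$target_offset[i],
                          c(spec$target_x[i], spec$target_y[i]))
    tibble(
      ecc_class = spec$ecc_class[i],
      latency = (first$onset_s - t_on) * 1000,
      ttt = ttt * 1000,
      peak_vel = first$peak_vel_dps,
      gain = first$amplitude_deg / spec$eccentricity[i]
    )
  }) %>% bind_rows()
  out <- tibble(
    pro_latency_short = NA_real_, pro_latency_large = NA_real_,
    pro_ttt_short = NA_real_, pro_ttt_large = NA_real_,
    pro_peakvel_short = NA_real_, pro_peakvel_large = NA_real_,
    pro_gain_short = NA_real_, pro_gain_large = NA_real_
  )
  if (nrow(per_trial) == 0) return(out)
  for (cls in c("short", "large")) {
    sub <- per_trial[per_trial$ecc_class == cls, ]
    if (nrow(sub) == 0) next
    out[[paste0("pro_latency_", cls)]] <- mean(sub$latency)
    out[[paste0("pro_ttt_", cls)]] <- mean(sub$ttt, na.rm = TRUE)
    out[[paste0("pro_peakvel_", cls)]] <- mean(sub$peak_vel)
    out[[paste0("pro_gain_", cls)]] <- mean(sub$gain)
  }
  out
}

# gaze position at the first usable sample at or after time t
gaze_at <- function(rec, t) {
  idx <- which(rec$t_s >= t & rec$usable)
  if (length(idx) == 0) return(c(NA_real_, NA_real_))
  c(rec$x_deg[idx[1]], rec$y_deg[idx[1]])
}

#' Classify one anti-saccade trial
#'
#' The first detected saccade of at least 1 degree with a horizontal
#' displacement of at least 1 degree, with onset in the 80–800 ms window
#' after target onset, determines the trial class: toward the target
#' side is an error, away is correct. An error followed by an
#' opposite-direction saccade before the answer screen is a corrected
#' error (`time_to_correct` is the onset-to-onset delay). Trials with no
#' qualifying saccade are invalid. Time-to-target is the time from
#' target onset to the end of the final saccade landing in the correct
#' hemifield.
#'
#' @param rec Preprocessed anti-saccade recording.
#' @param events Fitted event tibble.
#' @param trial One row of the anti-saccade task spec.
#' @param window_ms Acceptance window after target onset (ms).
#' @return One-row tibble: `trial`, `class`, `latency_ms`,
#'   `time_to_correct_ms`, `time_to_target_ms`.
#' @export
classify_antisaccade_trial <- function(rec, events, trial,
                                       window_ms = c(80, 800)) {
  t_on <- trial$target_onset
  win <- t_on + window_ms / 1000
  horiz <- abs(events$amplitude_deg * cos(events$angle_deg * pi / 180))
  qual <- events$amplitude_deg >= 1 & horiz >= 1
  cand <- events[qual & events$onset_s >= win[1] & events$onset_s <= win[2], ,
                 drop = FALSE]
  res <- tibble(trial = trial$trial, class = "invalid",
                latency_ms = NA_real_, time_to_correct_ms = NA_real_,
                time_to_target_ms = NA_real_)
  if (nrow(cand) == 0) return(res)
  first <- cand[which.min(cand$onset_s), ]
  dir1 <- sign(cos(first$angle_deg * pi / 180))
  res$latency_ms <- (first$onset_s - t_on) * 1000
  is_error <- dir1 == trial$side
  if (is_error) {
    later <- events[qual & events$onset_s > first$onset_s &
                      events$onset_s < trial$answer_onset &
                      sign(cos(events$angle_deg * pi / 180)) == -dir1, ,
                    drop = FALSE]
    if (nrow(later) > 0) {
      second <- later[which.min(later$onset_s), ]
      res$class <- "corrected_error"
      res$time_to_correct_ms <- (second$onset_s - first$onset_s) * 1000
    } else {
      res$class <- "uncorrected_error"
    }
  } else {
    res$class <- "correct"
  }
  # final saccade (before the answer screen) landing in the correct hemifield
  pre_answer <- events[qual & events$onset_s < trial$answer_onset &
                         events$onset_s >= win[1], , drop = FALSE]
  if (nrow(pre_answer) > 0) {
    landings <- purrr::map_dbl(seq_len(nrow(pre_answer)), function(j) {
      gaze_at(rec, pre_answer$offset_s[j])[1]
    })
    correct_land <- which(landings * (-trial$side) > 1)
    if (length(correct_land) > 0) {
      last_ev <- pre_answer[max(correct_land), ]
      res$time_to_target_ms <- (last_ev$offset_s - t_on) * 1000
    }
  }
  res
}

#' Anti-saccade task parameters
#'
#' Aggregates classified trials: direction error rate (errors over
#' non-invalid trials), direction correction rate (corrected errors over
#' errors), mean latencies of correct- and incorrect-direction first
#' saccades, mean time-to-correct over corrected-error trials, and mean
#' time-to-target. Fields whose denominator class is empty are
#' structurally missing.
#'
#' @param trials Tibble of classified trials from
#'   [classify_antisaccade_trial()].
#' @return One-row tibble with the five `anti_*` parameters plus
#'   `anti_time_to_target`.
#' @export
compute_antisaccade_params <- function(trials) {
  valid <- trials[trials$class != "invalid", , drop = FALSE]
  out <- tibble(
    anti_error_rate = NA_real_, anti_correction_rate = NA_real_,
    anti_latency_correct = NA_real_, anti_latency_error = NA_real_,
    anti_time_to_correct = NA_real_, anti_time_to_target = NA_real_
  )
  if (nrow(valid) == 0) return(out)
  errors <- valid[valid$class %in% c("corrected_error", "uncorrected_error"), ]
  corrected <- valid[valid$class == "corrected_error", ]
  correct <- valid[valid$class == "correct", ]
  out$anti_error_rate <- nrow(errors) / nrow(valid)
  if (nrow(errors) > 0) {
    out$anti_correction_rate <- nrow(corrected) / nrow(errors)
    out$anti_latency_error <- mean(errors$latency_ms)
  }
  if (nrow(correct) > 0) out$anti_latency_correct <- mean(correct$latency_ms)
  if (nrow(corrected) > 0) out$anti_time_to_correct <- mean(corrected$time_to_correct_ms)
  ttt <- valid$time_to_target_ms[!is.na(valid$time_to_target_ms)]
  if (length(ttt) > 0) out$anti_time_to_target <- mean(ttt)
  out
}

#' Smooth-pursuit task parameters
#'
#' Per step–ramp trial, saccadic samples are excised (desaccading) and:
#' velocity gain is the mean desaccaded eye velocity along the target
#' direction divided by the target speed; pursuit lag is the mean
#' Euclidean gaze–target distance over pursuit samples; proportion of
#' time in pursuit is pursuit time over pursuit plus catch-up-saccade
#' time between eye-movement onset and ramp end; the catch-up count sums
#' detected saccades co-directional with the target over trials.
#'
#' @param rec Preprocessed pursuit recording.
#' @param events Fitted event tibble.
#' @param spec Pursuit task spec.
#' @param settings A [detection_settings()].
#' @param vel Optional precomputed velocity trace.
#' @return One-row tibble: `pursuit_gain`, `pursuit_lag`,
#'   `pursuit_prop_time`, `pursuit_catchup_count`.
#' @export
compute_pursuit_params <- function(rec, events, spec,
                                   settings = detection_settings(),
                                   vel = NULL) {
  if (is.null(vel)) vel <- estimate_velocity(rec)
  dt <- median(diff(rec$t_s))
  ev_mask <- in_event_mask(rec$t_s, events, dt)
  per_trial <- purrr::map(seq_len(nrow(spec)), function(i) {
    u <- c(spec$dir_x[i], spec$dir_y[i])
    v_t <- spec$speed[i]
    in_ramp <- rec$t_s >= spec$ramp_onset[i] & rec$t_s <= spec$ramp_offset[i]
    v_along <- vel$vx * u[1] + vel$vy * u[2]
    # movement onset: first sample opening a sustained (5-sample) run of
    # along-target velocity above a quarter of target speed — a single
    # supra-threshold sample is routinely produced by noise alone
    moving <- in_ramp & vel$usable & v_along > 0.25 * v_t
    sustained <- stats::filter(as.numeric(moving), rep(1, 5), sides = 1) == 5
    onset_idx <- which(sustained)[1] - 4L
    if (is.na(onset_idx)) return(NULL)
    t_move <- rec$t_s[onset_idx]
    analysis <- rec$t_s >= t_move & rec$t_s <= spec$ramp_offset[i]
    # velocity averages skip the differentiation filter's half-window at
    # both ends, where the smoothed velocity blends into the stationary
    # fixation before/after the ramp
    core <- rec$t_s >= t_move + 2 * dt & rec$t_s <= spec$ramp_offset[i] - 2 * dt
    pursuit_ok <- core & vel$usable & !ev_mask
    if (sum(pursuit_ok) < 5) return(NULL)
    tgt_s <- spec$start_pos[i] + v_t * (rec$t_s - spec$ramp_onset[i])
    dist <- sqrt((rec$x_deg - u[1] * tgt_s)^2 + (rec$y_deg - u[2] * tgt_s)^2)
    saccade_time <- sum(analysis & ev_mask) * dt
    pursuit_time <- sum(pursuit_ok) * dt
    cu <- events[events$t_peak >= spec$ramp_onset[i] &
                   events$t_peak <= spec$ramp_offset[i] &
                   events$amplitude_deg >= settings$min_amp, , drop = FALSE]
    co_dir <- cos(cu$angle_deg * pi / 180) * u[1] +
      sin(cu$angle_deg * pi / 180) * u[2] > 0
    tibble(
      gain = mean(v_along[pursuit_ok]) / v_t,
      lag = mean(dist[pursuit_ok]),
      prop = pursuit_time / (pursuit_time + saccade_time),
      catchup = sum(co_dir)
    )
  }) %>% bind_rows()
  if (nrow(per_trial) == 0) {
    return(tibble(pursuit_gain = NA_real_, pursuit_lag = NA_real_,
                  pursuit_prop_time = NA_real_,
                  pursuit_catchup_count = NA_real_))
  }
  tibble(
    pursuit_gain = mean(per_trial$gain),
    pursuit_lag = mean(per_trial$lag),
    pursuit_prop_time = mean(per_trial$prop),
    pursuit_catchup_count = sum(per_trial$catchup)
  )
}

#' Assemble the canonical oculomotor profile
#'
#' Flattens per-task parameter rows into the canonical 20-slot profile
#' (plus the optional anti-saccade time-to-target as a 21st column).
#' Absent tasks leave their slots explicitly missing.
#'
#' @param fixation,prosaccade,antisaccade,pursuit One-row tibbles from
#'   the respective `compute_*_params()` functions, or `NULL`.
#' @param include_time_to_target Carry `anti_time_to_target`.
#' @return One-row tibble with canonical columns.
#' @export
assemble_profile <- function(fixation = NULL, prosaccade = NULL,
                             antisaccade = NULL, pursuit = NULL,
                             include_time_to_target = TRUE) {
  parts <- purrr::compact(list(fixation, prosaccade, antisaccade, pursuit))
  vals <- list()
  for (p in parts) {
    dup <- intersect(names(p), names(vals))
    if (length(dup) > 0) {
      abort(sprintf("Duplicate parameter name(s): %s.", paste(dup, collapse = ", ")))
    }
    vals <- c(vals, as.list(p))
  }
  nms <- profile_parameter_names(include_time_to_target)
  out <- setNames(as.list(rep(NA_real_, length(nms))), nms)
  for (nm in intersect(names(vals), nms)) out[[nm]] <- vals[[nm]]
  as_tibble(out)
}

#' Extract the full oculomotor profile from one participant's battery
#'
#' Runs the extraction pipeline (artifact removal, velocity estimation,
#' saccade detection, waveform fitting, task metrics) over the four task
#' recordings of one participant.
#'
#' @param sims Named list (or tibble with `task` and `sim` columns) of
#'   [simulate_gaze_recording()] results — or of lists with elements
#'   `recording` and `spec` for real data.
#' @param settings A [detection_settings()].
#' @param include_time_to_target Carry the optional 21st parameter.
#' @return One-row profile tibble.
#' @export
extract_profile <- function(sims, settings = detection_settings(),
                            include_time_to_target = TRUE) {
  if (is.data.frame(sims)) sims <- setNames(sims$sim, sims$task)
  get_task <- function(name) sims[[name]]
  one <- function(name, fun) {
    s <- get_task(name)
    if (is.null(s)) return(NULL)
    rec <- remove_artifacts(s$recording)
    vel <- estimate_velocity(rec)
    events <- detect_saccades(rec, settings, vel = vel)
    events <- fit_saccades(rec, events, settings)
    fun(rec, events, s$spec, vel)
  }
  fixation <- one("fixation", function(rec, ev, spec, vel)
    compute_fixation_params(rec, ev, spec, settings))
  prosaccade <- one("prosaccade", function(rec, ev, spec, vel)
    compute_prosaccade_params(rec, ev, spec, settings))
  antisaccade <- one("antisaccade", function(rec, ev, spec, vel) {
    trials <- purrr::map(seq_len(nrow(spec)), function(i)
      classify_antisaccade_trial(rec, ev, spec[i, ])) %>% bind_rows()
    compute_antisaccade_params(trials)
  })
  pursuit <- one("pursuit", function(rec, ev, spec, vel)
    compute_pursuit_params(rec, ev, spec, settings, vel = vel))
  assemble_profile(fixation, prosaccade, antisaccade, pursuit,
                   include_time_to_target = include_time_to_target)
}

#' Extract oculomotor profiles for a whole simulated cohort
#'
#' @param cohort_sim A [simulate_cohort()] result with gaze recordings.
#' @param settings A [detection_settings()].
#' @param include_time_to_target Carry the optional 21st parameter.
#' @return Tibble: `participant` plus the canonical profile columns.
#' @export
extract_cohort_profiles <- function(cohort_sim,
                                    settings = detection_settings(),
                                    include_time_to_target = TRUE) {
  if (is.null(cohort_sim$recordings)) {
    abort("Cohort was simulated without gaze recordings.")
  }
  cohort_sim$recordings %>%
    dplyr::group_split(.data$participant) %>%
    purrr::map(function(df) {
      prof <- extract_profile(df, settings, include_time_to_target)
      dplyr::bind_cols(tibble(participant = df$participant[1]), prof)
    }) %>%
    bind_rows()
}
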