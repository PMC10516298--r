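# Saccade event detection (adaptive velocity threshold) and parametric
# main-sequence waveform fitting.

#' Saccadic main sequence
#'
#' The saturating relation between saccade amplitude and peak angular
#' velocity, `Vp = eta * (1 - exp(-A / c))`.
#'
#' @param amplitude Saccade amplitude A in degrees (>= 0, vectorized).
#' @param eta Saturation peak velocity (deg/s, > 0).
#' @param c Amplitude constant (deg, > 0).
#' @return Peak velocity in deg/s.
#' @export
#' @examples
#' main_sequence(10, 500, 6) # ~405.6 deg/s
main_sequence <- function(amplitude, eta, c) {
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    abort("`amplitude` must be finite and >= 0.")
  }
  check_pos(eta, "eta")
  check_pos(c, "c")
  eta * (1 - exp(-amplitude / c))
}

#' Detection settings for the adaptive velocity-based saccade detector
#'
#' @param lambda Threshold multiplier: the peak threshold is `lambda`
#'   times the robust (median-absolute-deviation based, Gaussian
#'   consistent) SD of the speed signal over non-saccadic samples.
#' @param min_dur_ms Minimum event duration: the event must hold at least
#'   `ceiling(min_dur_ms / sample interval)` samples above the onset
#'   threshold (17 ms is 2 samples at 60 Hz).
#' @param min_amp Minimum displacement amplitude in degrees; smaller
#'   events are discarded (also enforces that sub-degree microsaccades
#'   are out of scope at this sampling rate).
#' @param merge_ms Events separated by less than this are merged.
#' @param hysteresis Onset/offset threshold as a fraction of the peak
#'   threshold; candidate peaks are extended to this lower crossing
#'   before the duration rule is applied.
#' @param fit_margin Samples of context on each side of the event handed
#'   to the waveform fit.
#' @param rmse_ceiling Waveform-fit RMSE (deg) above which the fit is
#'   rejected in favour of non-parametric estimates.
#' @param c_default Amplitude constant used to report `eta` from a fitted
#'   peak velocity (eta and c are only jointly identifiable across
#'   saccades; per event the fit estimates A, t0 and Vp).
#' @return List of class `detection_settings`.
#' @export
detection_settings <- function(lambda = 5, min_dur_ms = 17, min_amp = 0.5,
                               merge_ms = 33, hysteresis = 0.5,
                               fit_margin = 3L, rmse_ceiling = 0.75,
                               c_default = 6) {
  check_pos(lambda, "lambda")
  check_nonneg(min_dur_ms, "min_dur_ms")
  check_nonneg(min_amp, "min_amp")
  check_nonneg(merge_ms, "merge_ms")
  if (!is_scalar_number(hysteresis) || hysteresis <= 0 || hysteresis > 1) {
    abort("`hysteresis` must be in (0, 1].")
  }
  structure(list(lambda = lambda, min_dur_ms = min_dur_ms, min_amp = min_amp,
                 merge_ms = merge_ms, hysteresis = hysteresis,
                 fit_margin = as.integer(fit_margin),
                 rmse_ceiling = rmse_ceiling, c_default = c_default),
            class = c("detection_settings", "list"))
}

empty_event_table <- function() {
  tibble(
    event = integer(), onset_s = numeric(), offset_s = numeric(),
    t_peak = numeric(), amplitude_deg = numeric(), angle_deg = numeric(),
    peak_vel_dps = numeric(), eta = numeric(), c = numeric(),
    t0_s = numeric(), rmse_deg = numeric(), fitted = logical(),
    provenance = character()
  )
}

robust_speed_sd <- function(speed) {
  stats::mad(speed, na.rm = TRUE) # median abs deviation * 1.4826
}

#' Detect saccades with an adaptive velocity threshold
#'
#' Two-pass adaptive thresholding in the spirit of engineering practice
#' for low-rate trackers: a robust SD of the speed signal sets a peak
#' threshold at `lambda` robust SDs (recomputed once after excluding the
#' first-pass events); candidate peaks are extended down to the
#' hysteresis (onset) threshold, must hold the minimum duration there,
#' nearby events are merged, onsets/offsets are nudged toward the local
#' speed minima bracketing the peak (bounded to one sample so drift
#' wander stays out of the event window), and events whose displacement
#' falls below the minimum amplitude are discarded.
#'
#' @param rec A preprocessed recording (see [remove_artifacts()]).
#' @param settings A [detection_settings()].
#' @param vel Optional precomputed [estimate_velocity()] trace.
#' @return Event tibble (possibly empty): `onset_s`, `offset_s`,
#'   `t_peak`, `amplitude_deg`, `angle_deg`, `peak_vel_dps` (trace-based
#'   until fitted), `eta`, `c`, `t0_s`, `rmse_deg`, `fitted`,
#'   `provenance`; the adaptive peak threshold (deg/s) is attached as the
#'   `threshold_peak` attribute.
#' @export
detect_saccades <- function(rec, settings = detection_settings(), vel = NULL) {
  assert_gaze_recording(rec)
  if (!"usable" %in% names(rec)) rec <- remove_artifacts(rec)
  if (is.null(vel)) vel <- estimate_velocity(rec)
  speed <- ifelse(vel$usable, vel$speed, NA_real_)
  if (all(is.na(speed))) {
    out <- empty_event_table()
    attr(out, "threshold_peak") <- NA_real_
    return(out)
  }
  dt <- median(diff(rec$t_s))
  min_run <- max(1L, ceiling(settings$min_dur_ms / 1000 / dt))

  runs_from_threshold <- function(speed, thr_peak, thr_low) {
    above_low <- !is.na(speed) & speed > thr_low
    r <- rle(above_low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    out <- cbind(starts[keep], ends[keep])
    # peak rule: the run must contain a sample above the peak threshold
    if (nrow(out) > 0) {
      has_peak <- vapply(seq_len(nrow(out)), function(i) {
        any(speed[out[i, 1]:out[i, 2]] > thr_peak, na.rm = TRUE)
      }, logical(1))
      out <- out[has_peak, , drop = FALSE]
    }
    out
  }

  # pass 1: threshold from all usable samples; pass 2: exclude detected runs
  sigma <- robust_speed_sd(speed)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-6
  thr_peak <- settings$lambda * sigma
  runs <- runs_from_threshold(speed, thr_peak, settings$hysteresis * thr_peak)
  excl <- rep(FALSE, length(speed))
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) excl[runs[i, 1]:runs[i, 2]] <- TRUE
  }
  sigma2 <- robust_speed_sd(speed[!excl])
  if (is.finite(sigma2) && sigma2 > 0) thr_peak <- settings$lambda * sigma2
  thr_low <- settings$hysteresis * thr_peak
  runs <- runs_from_threshold(speed, thr_peak, thr_low)
  if (nrow(runs) == 0) {
    out <- empty_event_table()
    attr(out, "threshold_peak") <- thr_peak
    return(out)
  }

  # merge runs separated by less than merge_ms
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      prev <- merged[[length(merged)]]
      gap <- (rec$t_s[runs[i, 1]] - rec$t_s[prev[2]]) * 1000
      if (gap < settings$merge_ms) {
        merged[[length(merged)]] <- c(prev[1], runs[i, 2])
      } else {
        merged <- c(merged, list(runs[i, ]))
      }
    }
    runs <- do.call(rbind, merged)
  }

  # onset/offset at the hysteresis-crossing edges, nudged one sample
  # outward when the neighbouring sample is still a descent toward the
  # local speed minimum (bounded refinement keeps drift wander out of the
  # event window); displacement is measured with a one-sample pad so the
  # waveform tails are captured
  n <- length(speed)
  events <- purrr::map(seq_len(nrow(runs)), function(i) {
    i0 <- runs[i, 1]; i1 <- runs[i, 2]
    if (i0 > 1 && !is.na(speed[i0 - 1]) && speed[i0 - 1] < speed[i0]) i0 <- i0 - 1L
    if (i1 < n && !is.na(speed[i1 + 1]) && speed[i1 + 1] < speed[i1]) i1 <- i1 + 1L
    ipk <- (runs[i, 1]:runs[i, 2])[which.max(speed[runs[i, 1]:runs[i, 2]])]
    i0d <- max(1L, i0 - 1L)
    i1d <- min(n, i1 + 1L)
    dx <- rec$x_deg[i1d] - rec$x_deg[i0d]
    dy <- rec$y_deg[i1d] - rec$y_deg[i0d]
    tibble(
      event = i, onset_s = rec$t_s[i0], offset_s = rec$t_s[i1],
      t_peak = rec$t_s[ipk],
      amplitude_deg = sqrt(dx^2 + dy^2),
      angle_deg = atan2(dy, dx) * 180 / pi,
      peak_vel_dps = speed[ipk],
      eta = NA_real_, c = NA_real_, t0_s = rec$t_s[i0],
      rmse_deg = NA_real_, fitted = FALSE, provenance = "detected"
    )
  }) %>% bind_rows()
  events <- events[events$amplitude_deg >= settings$min_amp, , drop = FALSE]
  events$event <- seq_len(nrow(events))
  attr(events, "threshold_peak") <- thr_peak
  events
}

#' Fit the parametric saccade waveform to one detected event
#'
#' Least-squares fit of the gaze position, projected on the saccade's
#' principal displacement axis, to a smooth sigmoidal ramp
#' `s(t) = s0 + A * plogis(k * (t - tm))` whose peak velocity `A*k/4` is
#' reported as the fitted `Vp`; the main-sequence parameter `eta` is
#' back-solved at the reported `c` so that `Vp = eta * (1 - exp(-A/c))`
#' holds by construction. The refined onset `t0_s` is the 1% point of the
#' ramp. If the optimizer fails or the fit RMSE exceeds the ceiling, the
#' event keeps its non-parametric estimates and stays flagged unfitted.
#'
#' @param rec Preprocessed recording containing the event.
#' @param event One-row event tibble from [detect_saccades()].
#' @param settings A [detection_settings()].
#' @return The event row with refined `amplitude_deg`, `peak_vel_dps`,
#'   `eta`, `c`, `t0_s`, `rmse_deg` and `fitted = TRUE` on success.
#' @export
fit_saccade_waveform <- function(rec, event, settings = detection_settings()) {
  assert_gaze_recording(rec)
  if (!"usable" %in% names(rec)) rec <- remove_artifacts(rec)
  dt <- median(diff(rec$t_s))
  margin <- settings$fit_margin * dt
  seg <- rec[rec$t_s >= event$onset_s - margin &
               rec$t_s <= event$offset_s + margin & rec$usable, ]
  if (nrow(seg) < 3) abort("Segment shorter than 3 samples; cannot fit.")
  pre <- sum(seg$t_s < event$onset_s)
  post <- sum(seg$t_s > event$offset_s)
  if (pre < 2 || post < 2) {
    # not enough context to anchor the plateaus: keep detection estimates
    return(event)
  }
  ang <- event$angle_deg * pi / 180
  u <- c(cos(ang), sin(ang))
  p0 <- c(seg$x_deg[1], seg$y_deg[1])
  s <- (seg$x_deg - p0[1]) * u[1] + (seg$y_deg - p0[2]) * u[2]
  a0 <- max(event$amplitude_deg, settings$min_amp)
  vp0 <- main_sequence(a0, 500, settings$c_default)
  start <- list(s0 = s[1], a = a0, tm = (event$onset_s + event$offset_s) / 2,
                logk = log(4 * vp0 / a0))
  k_lo <- log(4 * 25 / 40)   # slowest: Vp 25 deg/s at A 40 deg
  k_hi <- log(4 * 1300 / 0.3) # fastest conceivable ramp
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ s0 + a * plogis(exp(logk) * (t_s - tm)),
      data = data.frame(s = s, t_s = seg$t_s),
      start = start,
      lower = c(s0 = s[1] - 5, a = 0.05, tm = seg$t_s[1], logk = k_lo),
      upper = c(s0 = s[1] + 5, a = 60, tm = seg$t_s[nrow(seg)], logk = k_hi),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(event)
  cf <- coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  if (rmse > settings$rmse_ceiling) {
    event$rmse_deg <- rmse
    return(event)
  }
  a <- unname(cf["a"])
  k <- exp(unname(cf["logk"]))
  vp <- a * k / 4
  eta <- vp / (1 - exp(-a / settings$c_default))
  eta_clipped <- min(max(eta, 50), 1200)
  event$amplitude_deg <- a
  event$peak_vel_dps <- if (eta_clipped == eta) vp else
    main_sequence(a, eta_clipped, settings$c_default)
  event$eta <- eta_clipped
  event$c <- settings$c_default
  event$t0_s <- unname(cf["tm"]) - log(99) / k
  event$offset_s <- unname(cf["tm"]) + log(99) / k
  event$onset_s <- event$t0_s
  event$rmse_deg <- rmse
  event$fitted <- TRUE
  event
}

#' Fit all detected saccades of a recording
#'
#' @param rec Preprocessed recording.
#' @param events Event tibble from [detect_saccades()].
#' @param settings A [detection_settings()].
#' @return Event tibble with fitted rows where the fit succeeded.
#' @export
fit_saccades <- function(rec, events, settings = detection_settings()) {
  if (nrow(events) == 0) return(events)
  if (!"usable" %in% names(rec)) rec <- remove_artifacts(rec)
  purrr::map(seq_len(nrow(events)), function(i) {
    tryCatch(fit_saccade_waveform(rec, events[i, ], settings),
             error = function(e) events[i, ])
  }) %>% bind_rows()
}
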