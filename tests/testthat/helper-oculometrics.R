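# shared fixtures, built in code

# a noiseless, artifact-free truth for exact-limit tests
quiet_truth <- function(...) {
  args <- list(
    latency_pro_sd = 0, latency_anti_correct_sd = 0, latency_anti_error_sd = 0,
    time_to_correct_sd = 0, amp_gain_sd = 0,
    fix_sigma_x = 0, fix_sigma_y = 0,
    intrusion_rate = 0, blink_rate = 0, noise_rms_s2s = 0
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(planted_truth, args)
}

# uniform 60 Hz recording from x/y vectors
as_recording <- function(x, y = rep(0, length(x)), rate = 60,
                         valid = rep(TRUE, length(x))) {
  tibble::tibble(t_s = (seq_along(x) - 1) / rate, x_deg = x, y_deg = y,
                 valid = valid)
}

# noiseless logistic saccade template: amplitude A, midpoint tm, main
# sequence (eta, c); returns the recording plus the analytic truth
template_saccade <- function(amplitude, eta = 500, c = 6, tm = 0.5,
                             duration = 1, rate = 60, angle = 0) {
  vp <- eta * (1 - exp(-amplitude / c))
  k <- 4 * vp / amplitude
  t <- seq(0, duration, by = 1 / rate)
  s <- amplitude * stats::plogis(k * (t - tm))
  rec <- tibble::tibble(t_s = t, x_deg = s * cos(angle), y_deg = s * sin(angle),
                        valid = TRUE)
  list(rec = rec, vp = vp, k = k, onset = tm - log(99) / k,
       offset = tm + log(99) / k, amplitude = amplitude)
}

# event row bracketing the template, as detection would hand to the fit
template_event <- function(tpl) {
  tibble::tibble(
    event = 1L, onset_s = tpl$onset, offset_s = tpl$offset,
    t_peak = (tpl$onset + tpl$offset) / 2, amplitude_deg = tpl$amplitude,
    angle_deg = 0, peak_vel_dps = tpl$vp, eta = NA_real_, c = NA_real_,
    t0_s = tpl$onset, rmse_deg = NA_real_, fitted = FALSE,
    provenance = "detected"
  )
}

# greedy interval matching between detected and ground-truth events
match_events <- function(events, truth, pad = 0.017) {
  if (nrow(events) == 0 || nrow(truth) == 0) {
    return(list(truth_found = rep(FALSE, nrow(truth)),
                event_matched = rep(FALSE, nrow(events)),
                pairs = data.frame(event = integer(), truth = integer())))
  }
  m <- outer(seq_len(nrow(events)), seq_len(nrow(truth)),
             Vectorize(function(i, j) {
               max(0, min(events$offset_s[i] + pad, truth$t_off[j]) -
                     max(events$onset_s[i] - pad, truth$t_on[j])) > 0
             }))
  pairs <- which(m, arr.ind = TRUE)
  list(truth_found = apply(m, 2, any),
       event_matched = apply(m, 1, any),
       pairs = data.frame(event = pairs[, 1], truth = pairs[, 2]))
}

# full single-participant battery simulation
simulate_battery <- function(truth, seed = 1L, battery = NULL) {
  battery <- battery %||% make_task_battery(seed)
  tasks <- c("fixation", "prosaccade", "antisaccade", "pursuit")
  stats::setNames(lapply(seq_along(tasks), function(k) {
    simulate_gaze_recording(battery[[tasks[k]]], truth, seed = seed * 10 + k)
  }), tasks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# session-cached synthetic cohort shared by the heavier tests
cached_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 60, seed = 11) {
    key <- sprintf("c_%d_%d", n, seed)
    if (is.null(cache[[key]])) {
      cs <- simulate_cohort(cohort_config(n_participants = n, seed = seed))
      profiles <- extract_cohort_profiles(cs)
      cache[[key]] <- list(cs = cs, profiles = profiles)
    }
    cache[[key]]
  }
})

# brute-force BH oracle: run the step-up rejection rule at every candidate
# alpha and report, per hypothesis, the smallest alpha at which it is
# rejected (the adjusted p-value), independently of p.adjust()
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  if (!is.finite(k)) return(rep(FALSE, m))
  p <= ps[k]
}

bh_oracle <- function(p) {
  m <- length(p)
  alphas <- sort(unique(pmin(1, m * sort(p) / seq_len(m))))
  adj <- rep(1, m)
  for (a in rev(alphas)) {
    rej <- bh_stepup_reject(p, a * (1 + 1e-12)) # nudge past the float boundary
    adj[rej] <- a
  }
  adj
}

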