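#' Build the stimulus timelines of the four-task oculomotor battery
#'
#' Generates one stimulus timeline ("task spec") per task of the battery:
#'
#' * **fixation** — a stationary target shown 7 s at each of five locations
#'   (screen centre, 10 degrees left/right, 14 degrees up/down), in
#'   randomized order;
#' * **pro-saccade** — 24 trials over 8 eccentric locations (short:
#'   5 degrees horizontal / 6 vertical; large: 10 horizontal / 12 vertical),
#'   each sampled 3 times in shuffled order, with a pre-target central
#'   fixation of uniform 1.0–3.5 s and 1.5 s of target display;
#' * **anti-saccade** — targets at ±10 degrees shown 100 ms after a
#'   1.0–3.5 s central fixation, followed by a 1200 ms blank, a 400 ms
#'   arrow cue at the mirror location and a 5 s answer screen;
#' * **pursuit** — step–ramp trials (step 1.5 degrees against the motion,
#'   ramp at 8.65 deg/s until the target reaches 10 degrees), one trial per
#'   direction (right, left, up, down), preceded by a 1–2 s central cross.
#'
#' All task specs are tibbles with one row per trial and absolute onset
#' times (seconds) within the task recording, so they double as the
#' stimulus-timeline sidecar of a recording.
#'
#' @param seed Integer seed; the same seed reproduces the same battery.
#' @param pursuit_speed Ramp speed in deg/s. The protocol value is 8.65
#'   (one figure caption rounds it to 8); it is exposed here rather than
#'   asserted.
#' @param n_anti_trials Number of anti-saccade trials (the protocol fixes
#'   per-trial timing but not the trial count; 12 keeps the battery under
#'   ten minutes).
#' @return A named list of class `task_battery` with elements `fixation`,
#'   `prosaccade`, `antisaccade`, `pursuit`; each element is a tibble with
#'   a `task_kind` and `duration_s` attribute.
#' @export
#' @examples
#' battery <- make_task_battery(seed = 1)
#' nrow(battery$prosaccade) # 24 trials
make_task_battery <- function(seed = 1L, pursuit_speed = 8.65, n_anti_trials = 12L) {
  if (!is_scalar_number(seed)) abort("`seed` must be a single integer.")
  withr::with_seed(as.integer(seed), {
    battery <- list(
      fixation    = fixation_task_spec(),
      prosaccade  = prosaccade_task_spec(),
      antisaccade = antisaccade_task_spec(n_trials = n_anti_trials),
      pursuit     = pursuit_task_spec(speed = pursuit_speed)
    )
  })
  structure(battery, class = c("task_battery", "list"))
}

task_spec <- function(df, kind, duration) {
  df <- as_tibble(df)
  attr(df, "task_kind") <- kind
  attr(df, "duration_s") <- duration
  class(df) <- c("task_spec", class(df))
  df
}

fixation_task_spec <- function(dwell = 7) {
  locs <- tibble(
    target_x = c(0, -10, 10, 0, 0),
    target_y = c(0, 0, 0, 14, -14)
  )
  locs <- locs[sample.int(nrow(locs)), ]
  df <- locs %>%
    mutate(
      trial = seq_len(nrow(locs)),
      onset = (trial - 1) * dwell,
      offset = trial * dwell
    ) %>%
    select("trial", "onset", "offset", "target_x", "target_y")
  task_spec(df, "fixation", nrow(locs) * dwell)
}

prosaccade_task_spec <- function(n_per_location = 3L, display = 1.5,
                                 fix_range = c(1.0, 3.5)) {
  locs <- tibble(
    target_x = c(-5, 5, 0, 0, -10, 10, 0, 0),
    target_y = c(0, 0, -6, 6, 0, 0, -12, 12),
    ecc_class = rep(c("short", "large"), each = 4)
  )
  trials <- locs[rep(seq_len(nrow(locs)), each = n_per_location), ]
  trials <- trials[sample.int(nrow(trials)), ]
  n <- nrow(trials)
  fix_dur <- runif(n, fix_range[1], fix_range[2])
  trial_len <- fix_dur + display
  start <- cumsum(c(0, head(trial_len, -1)))
  df <- trials %>%
    mutate(
      trial = seq_len(n),
      fix_onset = start,
      fix_dur = fix_dur,
      target_onset = start + fix_dur,
      target_offset = start + fix_dur + display,
      eccentricity = sqrt(.data$target_x^2 + .data$target_y^2)
    ) %>%
    select("trial", "fix_onset", "fix_dur", "target_onset", "target_offset",
           "target_x", "target_y", "eccentricity", "ecc_class")
  task_spec(df, "prosaccade", sum(trial_len))
}

antisaccade_task_spec <- function(n_trials = 12L, fix_range = c(1.0, 3.5),
                                  target_dur = 0.1, blank_dur = 1.2,
                                  arrow_dur = 0.4, answer_dur = 5) {
  n_trials <- as.integer(n_trials)
  side <- sample(rep(c(-1L, 1L), length.out = n_trials))
  fix_dur <- runif(n_trials, fix_range[1], fix_range[2])
  trial_len <- fix_dur + target_dur + blank_dur + arrow_dur + answer_dur
  start <- cumsum(c(0, head(trial_len, -1)))
  df <- tibble(
    trial = seq_len(n_trials),
    side = side,
    fix_onset = start,
    fix_dur = fix_dur,
    target_onset = start + fix_dur,
    target_x = side * 10,
    target_y = 0,
    blank_onset = start + fix_dur + target_dur,
    arrow_onset = start + fix_dur + target_dur + blank_dur,
    arrow_dir = sample(c("left", "right", "up", "down"), n_trials, replace = TRUE),
    answer_onset = start + fix_dur + target_dur + blank_dur + arrow_dur,
    answer_offset = start + trial_len
  )
  task_spec(df, "antisaccade", sum(trial_len))
}

pursuit_task_spec <- function(speed = 8.65, step = 1.5, end_ecc = 10,
                              fix_range = c(1.0, 2.0)) {
  check_pos(speed, "speed")
  dirs <- tibble(
    dir_x = c(1, -1, 0, 0),
    dir_y = c(0, 0, 1, -1)
  )
  dirs <- dirs[sample.int(4L), ]
  fix_dur <- runif(4L, fix_range[1], fix_range[2])
  ramp_dur <- (end_ecc + step) / speed
  trial_len <- fix_dur + ramp_dur
  start <- cumsum(c(0, head(trial_len, -1)))
  df <- dirs %>%
    mutate(
      trial = 1:4,
      fix_onset = start,
      fix_dur = fix_dur,
      ramp_onset = start + fix_dur,
      ramp_offset = start + fix_dur + ramp_dur,
      step = step,
      speed = speed,
      start_pos = -step,
      end_pos = end_ecc
    ) %>%
    select("trial", "fix_onset", "fix_dur", "ramp_onset", "ramp_offset",
           "dir_x", "dir_y", "step", "speed", "start_pos", "end_pos")
  task_spec(df, "pursuit", sum(trial_len))
}

#' @export
print.task_battery <- function(x, ...) {
  cat("<task_battery>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %2d trials, %6.1f s\n", nm, nrow(x[[nm]]),
                attr(x[[nm]], "duration_s")))
  }
  invisible(x)
}
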