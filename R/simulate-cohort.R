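# Synthetic cohort: a latent severity variable drives both the planted
# oculomotor truths (signed as the clinical literature reports: higher
# severity -> longer latencies, lower peak velocity, larger fixation
# scatter, more intrusions, more anti-saccade errors, lower pursuit gain)
# and the clinical test scores (marginals matched to a typical MS cohort).

#' Default severity -> oculomotor effect map
#'
#' Each entry maps the latent severity (standard normal) to one
#' [planted_truth()] field via `value = link^-1(link(base) + beta * severity
#' + N(0, sd))`, with optional clipping. `link` is one of `"identity"`,
#' `"log"`, `"logit"`.
#'
#' @return Named list of effect entries.
#' @export
default_effect_map <- function() {
  list(
    latency_pro_mean          = list(base = 220,  beta = 25,    sd = 12,  link = "identity", clip = c(140, 400)),
    latency_anti_correct_mean = list(base = 280,  beta = 30,    sd = 15,  link = "identity", clip = c(160, 500)),
    latency_anti_error_mean   = list(base = 230,  beta = 20,    sd = 15,  link = "identity", clip = c(140, 450)),
    time_to_correct_mean      = list(base = 250,  beta = 25,    sd = 20,  link = "identity", clip = c(120, 500)),
    eta                       = list(base = 500,  beta = -0.08, sd = 0.05, link = "log",     clip = c(250, 750)),
    amp_gain                  = list(base = 0.95, beta = -0.03, sd = 0.02, link = "identity", clip = c(0.6, 1.1)),
    fix_sigma_x               = list(base = 0.30, beta = 0.25,  sd = 0.10, link = "log",     clip = c(0.1, 1.2)),
    fix_sigma_y               = list(base = 0.30, beta = 0.25,  sd = 0.10, link = "log",     clip = c(0.1, 1.2)),
    intrusion_rate            = list(base = 0.30, beta = 0.35,  sd = 0.15, link = "log",     clip = c(0.02, 1.5)),
    intrusion_amp_mean        = list(base = 1.3,  beta = 0.10,  sd = 0.08, link = "log",     clip = c(0.8, 2.5)),
    anti_error_prob           = list(base = 0.25, beta = 0.5,   sd = 0.2,  link = "logit",   clip = c(0.02, 0.95)),
    anti_correction_prob      = list(base = 0.80, beta = -0.4,  sd = 0.2,  link = "logit",   clip = c(0.05, 0.98)),
    pursuit_gain              = list(base = 0.93, beta = -0.06, sd = 0.03, link = "identity", clip = c(0.4, 1.02)),
    pursuit_lag               = list(base = 0.5,  beta = 0.25,  sd = 0.10, link = "log",     clip = c(0.2, 2.0))
  )
}

#' Default severity -> clinical score map
#'
#' Same entry structure as [default_effect_map()], plus `round_to` for
#' score quantization. EDSS is additionally quantized to 0.5 steps and
#' clipped to 0–10 by the generator. Bases and spreads mirror a typical
#' MS cohort (EDSS mean ~3.5, SDMT ~50, heavy-tailed timed tests).
#'
#' @return Named list of effect entries.
#' @export
default_clinical_map <- function() {
  list(
    age    = list(base = 51,   beta = 3,     sd = 10,   link = "identity", clip = c(20, 85), round_to = 1),
    edss   = list(base = 3.5,  beta = 1.7,   sd = 0.8,  link = "identity", clip = c(0, 10), round_to = 0.5),
    sdmt   = list(base = 49.7, beta = -9,    sd = 9,    link = "identity", clip = c(5, 110), round_to = 1),
    ravlt  = list(base = 54.2, beta = -7,    sd = 8,    link = "identity", clip = c(10, 75), round_to = 1),
    bvmtr  = list(base = 24.2, beta = -4.5,  sd = 5,    link = "identity", clip = c(0, 36), round_to = 1),
    t25fw  = list(base = 4.8,  beta = 0.55,  sd = 0.35, link = "log",      clip = c(2.5, 180), round_to = 0.1),
    hpt9   = list(base = 21.5, beta = 0.30,  sd = 0.18, link = "log",      clip = c(15, 170), round_to = 0.1)
  )
}

apply_effect <- function(entry, severity) {
  link <- entry$link %||% "identity"
  fwd <- switch(link, identity = identity, log = log, logit = qlogis,
                abort(sprintf("Unknown link '%s'.", link)))
  inv <- switch(link, identity = identity, log = exp, logit = plogis)
  val <- inv(fwd(entry$base) + entry$beta * severity +
               rnorm(length(severity), 0, entry$sd %||% 0))
  if (!is.null(entry$clip)) val <- pmin(pmax(val, entry$clip[1]), entry$clip[2])
  if (!is.null(entry$round_to)) val <- round(val / entry$round_to) * entry$round_to
  val
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configure a synthetic cohort
#'
#' @param n_participants Cohort size (>= 2).
#' @param seed Master seed; all per-participant seeds derive from it.
#' @param effect_map Severity -> planted-oculomotor-truth map; entries must
#'   name [planted_truth()] fields (see [default_effect_map()]).
#' @param clinical_map Severity -> clinical score map (see
#'   [default_clinical_map()]).
#' @param severity Optional explicit vector of latent severities (length
#'   `n_participants`); by default drawn standard normal.
#' @param missing_prob Named probabilities of missing-at-random clinical
#'   components (e.g. `c(sdmt = 0.05)`).
#' @param baseline_truth Baseline [planted_truth()] whose unmapped fields
#'   are shared by all participants.
#' @param simulate_gaze If `TRUE`, [simulate_cohort()] renders the full
#'   four-task battery per participant.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 60, seed = 1L,
                          effect_map = default_effect_map(),
                          clinical_map = default_clinical_map(),
                          severity = NULL,
                          missing_prob = NULL,
                          baseline_truth = planted_truth(),
                          simulate_gaze = TRUE) {
  if (!is_scalar_number(n_participants) || n_participants < 2) {
    abort("`n_participants` must be >= 2.")
  }
  unknown <- setdiff(names(effect_map), names(baseline_truth))
  if (length(unknown) > 0) {
    abort(sprintf("effect_map refers to unknown planted-truth parameter(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  known_clin <- c("age", "edss", "sdmt", "ravlt", "bvmtr", "t25fw", "hpt9")
  unknown <- setdiff(names(clinical_map), known_clin)
  if (length(unknown) > 0) {
    abort(sprintf("clinical_map refers to unknown score(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(severity) && length(severity) != n_participants) {
    abort("`severity` must have length n_participants.")
  }
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    effect_map = effect_map, clinical_map = clinical_map,
    severity = severity, missing_prob = missing_prob,
    baseline_truth = baseline_truth, simulate_gaze = simulate_gaze
  ), class = c("cohort_config", "list"))
}

#' Simulate a synthetic cohort
#'
#' Draws a latent severity per participant, maps it to clinical scores
#' (EDSS quantized to 0.5 steps and clipped to 0–10) and to the planted
#' oculomotor truth, and (optionally) renders the full four-task gaze
#' battery per participant. Deterministic for a fixed master seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort_simulation` with
#'   * `cohort`: tibble (participant, severity, age, edss, sdmt, ravlt,
#'     bvmtr, t25fw, hpt9);
#'   * `truths`: tibble of planted truth values, one row per participant;
#'   * `recordings`: tibble (participant, task, sim list-column of
#'     [simulate_gaze_recording()] results), or `NULL` when gaze
#'     simulation is disabled.
#' @export
#' @examples
#' cs <- simulate_cohort(cohort_config(n_participants = 3, simulate_gaze = FALSE))
#' cs$cohort
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config().")
  n <- config$n_participants
  withr::with_seed(config$seed, {
    severity <- config$severity %||% rnorm(n)
    clin <- purrr::map(config$clinical_map, apply_effect, severity = severity)
    cohort <- tibble(participant = sprintf("P%03d", seq_len(n)),
                     severity = severity) %>%
      dplyr::bind_cols(as_tibble(clin))
    if ("edss" %in% names(cohort)) { # EDSS grid is guaranteed regardless of map
      cohort$edss <- pmin(pmax(round(cohort$edss * 2) / 2, 0), 10)
    }
    if (!is.null(config$missing_prob)) {
      for (nm in names(config$missing_prob)) {
        gone <- runif(n) < config$missing_prob[[nm]]
        cohort[[nm]][gone] <- NA_real_
      }
    }
    truths <- purrr::map(seq_len(n), function(i) {
      tr <- config$baseline_truth
      for (nm in names(config$effect_map)) {
        tr[[nm]] <- apply_effect(config$effect_map[[nm]], severity[i])
      }
      validate_planted_truth(tr)
      tr
    })
    truth_tbl <- purrr::map(truths, ~ as_tibble(unclass(.x))) %>%
      bind_rows() %>%
      mutate(participant = cohort$participant, .before = 1)
    participant_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * 5),
                                nrow = n)
  })
  recordings <- NULL
  if (isTRUE(config$simulate_gaze)) {
    tasks <- c("fixation", "prosaccade", "antisaccade", "pursuit")
    recordings <- purrr::map(seq_len(n), function(i) {
      battery <- make_task_battery(seed = participant_seeds[i, 1])
      sims <- purrr::map(seq_along(tasks), function(k) {
        simulate_gaze_recording(battery[[tasks[k]]], truths[[i]],
                                seed = participant_seeds[i, k + 1])
      })
      tibble(participant = cohort$participant[i], task = tasks, sim = sims)
    }) %>% bind_rows()
  }
  structure(list(cohort = cohort, truths = truth_tbl, truth_list = truths,
                 recordings = recordings, config = config),
            class = c("cohort_simulation", "list"))
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf("<cohort_simulation> n = %d participants%s\n",
              nrow(x$cohort),
              if (is.null(x$recordings)) " (clinical + truths only)"
              else sprintf(", %d gaze recordings", nrow(x$recordings))))
  invisible(x)
}
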