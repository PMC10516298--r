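# End-to-end pipeline: simulate -> extract -> associate -> model, with
# CSV/JSON outputs and a run-metadata log.

#' Configure an end-to-end pipeline run
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_config()] describing the synthetic cohort.
#' @param detection A [detection_settings()].
#' @param search A [search_settings()] for the PLS stage.
#' @param alpha Significance level of the association screen.
#' @param bh_family BH family scope (`"per_outcome"` or `"global"`).
#' @param outcomes Clinical outcomes to analyse.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("oculometrics_run_"),
                            cohort = cohort_config(),
                            detection = detection_settings(),
                            search = search_settings(mode = "greedy"),
                            alpha = 0.05,
                            bh_family = c("per_outcome", "global"),
                            outcomes = c("edss", "sdmt", "bicams", "msfc")) {
  bh_family <- match.arg(bh_family)
  if (!inherits(cohort, "cohort_config")) abort("`cohort` must be a cohort_config().")
  if (!inherits(detection, "detection_settings")) abort("`detection` must be detection_settings().")
  if (!inherits(search, "search_settings")) abort("`search` must be search_settings().")
  known <- c("edss", "sdmt", "bicams", "msfc")
  bad <- setdiff(outcomes, known)
  if (length(bad) > 0) abort(sprintf("Unknown outcome(s): %s.", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, cohort = cohort, detection = detection,
                 search = search, alpha = alpha, bh_family = bh_family,
                 outcomes = outcomes),
            class = c("pipeline_config", "list"))
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic cohort + gaze CSVs with sidecars),
#' `extract` (oculomotor profiles), `associate` (composites, Spearman/BH
#' correlation tables, EDSS radar table), `model` (PLS feature selection
#' per outcome), or `all`. Each stage writes its tables under the
#' configured output directory together with `run_metadata.json` (config
#' hash, seeds, settings, warnings such as a capped search). Re-running
#' with the same config reproduces the outputs.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"simulate"`, `"extract"`, `"associate"`,
#'   `"model"`, `"all"`.
#' @return Invisibly, a list with the stage results (`cohort_sim`,
#'   `profiles`, `correlations`, `radar`, `models`).
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "extract",
                                           "associate", "model")) {
  stage <- match.arg(stage)
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config().")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  gaze_dir <- file.path(config$out_dir, "gaze")
  run_warnings <- character(0)
  results <- list()
  do_sim <- stage %in% c("all", "simulate", "extract", "associate", "model")

  # simulate ---------------------------------------------------------------
  cohort_sim <- simulate_cohort(config$cohort)
  results$cohort_sim <- cohort_sim
  if (stage %in% c("all", "simulate")) {
    dir.create(gaze_dir, showWarnings = FALSE)
    write_cohort_csv(cohort_sim$cohort, file.path(config$out_dir, "cohort.csv"))
    readr::write_csv(cohort_sim$truths, file.path(config$out_dir, "planted_truths.csv"),
                     progress = FALSE)
    if (!is.null(cohort_sim$recordings)) {
      purrr::pwalk(cohort_sim$recordings, function(participant, task, sim) {
        write_gaze_simulation(sim, file.path(gaze_dir, paste0(participant, "_", task)))
      })
    }
    if (stage == "simulate") {
      write_run_metadata(config, run_warnings)
      return(invisible(results))
    }
  }

  # extract ----------------------------------------------------------------
  profiles <- extract_cohort_profiles(cohort_sim, config$detection)
  results$profiles <- profiles
  write_profiles_csv(profiles, file.path(config$out_dir, "profiles.csv"))
  if (stage == "extract") {
    write_run_metadata(config, run_warnings)
    return(invisible(results))
  }

  # associate --------------------------------------------------------------
  cohort <- compute_composites(cohort_sim$cohort)
  outcomes_tbl <- cohort[, c("participant", config$outcomes)]
  corr <- spearman_with_fdr(profiles, outcomes_tbl, alpha = config$alpha,
                            family = config$bh_family)
  radar <- tryCatch(
    compare_edss_subgroups(profiles, cohort[, c("participant", "edss")],
                           alpha = config$alpha),
    error = function(e) {
      run_warnings <<- c(run_warnings,
                         paste("EDSS subgroup contrast skipped:", conditionMessage(e)))
      warn(paste("EDSS subgroup contrast skipped:", conditionMessage(e)))
      tibble(parameter = character(), mean_z_low = numeric(),
             mean_z_high = numeric(), n_low = integer(), n_high = integer(),
             statistic = numeric(), p = numeric(), p_adj = numeric(),
             significant = logical())
    }
  )
  results$correlations <- corr
  results$radar <- radar
  readr::write_csv(corr, file.path(config$out_dir, "correlations.csv"), progress = FALSE)
  readr::write_csv(radar, file.path(config$out_dir, "edss_radar.csv"), progress = FALSE)
  if (stage == "associate") {
    write_run_metadata(config, run_warnings)
    return(invisible(results))
  }

  # model ------------------------------------------------------------------
  model_data <- dplyr::inner_join(profiles, cohort, by = "participant")
  models <- list()
  for (oc in config$outcomes) {
    sel <- withCallingHandlers(
      exhaustive_feature_selection(model_data, oc, config$search),
      warning = function(w) {
        run_warnings <<- c(run_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    models[[oc]] <- sel
    jsonlite::write_json(
      list(outcome = oc, selected = sel$selected_parameters,
           covariate = sel$covariate, ncomp = sel$ncomp,
           coefficients = as.list(sel$fit$coefficients),
           intercept = sel$fit$intercept,
           beta_std = as.list(sel$fit$beta_std),
           contributions = as.list(sel$fit$contributions),
           r_squared = sel$r_squared, adj_r_squared = sel$adj_r_squared,
           cv_r2 = sel$cv_r2, n = sel$n, capped = sel$capped),
      file.path(config$out_dir, paste0("model_", oc, ".json")),
      auto_unbox = TRUE, digits = NA)
    readr::write_csv(
      tibble(observed = sel$fit$observed, predicted = sel$fit$fitted),
      file.path(config$out_dir, paste0("predictions_", oc, ".csv")),
      progress = FALSE)
  }
  results$models <- models
  contrib <- purrr::imap(models, function(m, oc) {
    tidy(m) %>% mutate(outcome = oc)
  }) %>% bind_rows()
  readr::write_csv(contrib, file.path(config$out_dir, "contributions.csv"),
                   progress = FALSE)
  write_run_metadata(config, run_warnings)
  invisible(results)
}

write_run_metadata <- function(config, warnings) {
  meta <- list(
    config_hash = config_hash(config),
    seed = config$cohort$seed,
    n_participants = config$cohort$n_participants,
    alpha = config$alpha,
    bh_family = config$bh_family,
    outcomes = config$outcomes,
    detection = unclass(config$detection),
    search = unclass(config$search)[c("min_size", "max_size", "folds",
                                      "seed", "metric", "mode")],
    warnings = warnings,
    package_version = as.character(utils::packageVersion("oculometrics"))
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(meta)
}
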