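# Standard on-disk formats: gaze CSV (t_s, x_deg, y_deg, valid), cohort
# and profile CSVs, JSON stimulus-timeline and ground-truth sidecars.

#' Read and write gaze recordings as CSV
#'
#' The gaze CSV dialect has exactly the header
#' `t_s,x_deg,y_deg,valid`; timestamps are seconds, positions degrees of
#' visual angle, `valid` is 0/1 or TRUE/FALSE. Reading checks the schema
#' and strict time monotonicity and reports the first offending line.
#'
#' @param path File path.
#' @return `read_gaze_csv()`: a gaze recording tibble.
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0) abort(sprintf("%s: empty recording.", path))
  need <- c("t_s", "x_deg", "y_deg", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(miss, collapse = ", ")))
  }
  df$valid <- as.logical(df$valid)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: timestamps not strictly increasing at line %d.",
                  path, bad[1] + 2L)) # +1 header, +1 second row of the pair
  }
  as_tibble(df[need])
}

#' @rdname read_gaze_csv
#' @param rec Gaze recording tibble.
#' @return `write_gaze_csv()`: the path, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  assert_gaze_recording(rec)
  readr::write_csv(rec[c("t_s", "x_deg", "y_deg", "valid")], path, progress = FALSE)
  invisible(path)
}

#' Write a simulated recording with its sidecars
#'
#' Writes the gaze CSV plus a JSON stimulus-timeline sidecar
#' (`<stem>_stimulus.json`) and a JSON ground-truth event log
#' (`<stem>_truth.json`).
#'
#' @param sim A [simulate_gaze_recording()] result.
#' @param stem Output path stem (no extension).
#' @return Named character vector of the files written, invisibly.
#' @export
write_gaze_simulation <- function(sim, stem) {
  paths <- c(
    gaze = paste0(stem, ".csv"),
    stimulus = paste0(stem, "_stimulus.json"),
    truth = paste0(stem, "_truth.json")
  )
  write_gaze_csv(sim$recording, paths[["gaze"]])
  spec <- sim$spec
  jsonlite::write_json(
    list(task_kind = attr(spec, "task_kind"),
         duration_s = attr(spec, "duration_s"),
         trials = as.data.frame(spec)),
    paths[["stimulus"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.data.frame(sim$events), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read and write the cohort clinical-score table
#'
#' One row per participant; columns `age`, `edss`, `sdmt`, `ravlt`,
#' `bvmtr`, `t25fw`, `hpt9` (plus `participant` and, after
#' [compute_composites()], `bicams` and `msfc`). Missing values are
#' empty cells.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("age", "edss", "sdmt", "ravlt", "bvmtr", "t25fw", "hpt9")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path, paste(miss, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write oculomotor profile tables
#'
#' One row per participant: `participant` plus the canonical parameter
#' columns (see [oculomotor_parameters()]); missing values are empty
#' cells.
#'
#' @param path File path.
#' @return `read_profiles_csv()`: profiles tibble.
#' @export
read_profiles_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  as_tibble(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(participant = readr::col_character(),
                            .default = readr::col_double())
  ))
}

#' @rdname read_profiles_csv
#' @param profiles Profiles tibble.
#' @export
write_profiles_csv <- function(profiles, path) {
  readr::write_csv(profiles, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a detected-event table as CSV
#'
#' @param events Event tibble from [detect_saccades()]/[fit_saccades()].
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(events, path, na = "", progress = FALSE)
  invisible(path)
}
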