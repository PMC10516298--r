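# ggplot2 views of the main result types.  Tables are the contract;
# these helpers are conveniences for inspection and reporting.

#' Plot a gaze recording with detected events
#'
#' @param rec Gaze recording tibble.
#' @param events Optional event tibble to overlay.
#' @return A ggplot object (x/y position vs time).
#' @export
plot_gaze <- function(rec, events = NULL) {
  long <- tidyr::pivot_longer(rec[, c("t_s", "x_deg", "y_deg")],
                              c("x_deg", "y_deg"),
                              names_to = "axis", values_to = "deg")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$deg,
                                          colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "gaze (deg)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Plot detected saccades against the main sequence
#'
#' @param events Fitted event tibble.
#' @param eta,c Main-sequence curve overlaid for reference.
#' @return A ggplot object (amplitude vs peak velocity).
#' @export
plot_main_sequence <- function(events, eta = 500, c = 6) {
  grid <- tibble(amplitude_deg = seq(0.1, max(events$amplitude_deg, 1), length.out = 100))
  grid$peak_vel_dps <- main_sequence(grid$amplitude_deg, eta, c)
  ggplot2::ggplot(events, ggplot2::aes(x = .data$amplitude_deg,
                                       y = .data$peak_vel_dps)) +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "amplitude (deg)", y = "peak velocity (deg/s)") +
    ggplot2::theme_minimal()
}

#' Radar-style plot of the EDSS subgroup contrast
#'
#' Displays the subgroup mean z-scores per parameter from
#' [compare_edss_subgroups()] (as a dot plot; the underlying table is the
#' tested interface).
#'
#' @param radar Result of [compare_edss_subgroups()].
#' @return A ggplot object.
#' @export
plot_edss_radar <- function(radar) {
  long <- tidyr::pivot_longer(radar, c("mean_z_low", "mean_z_high"),
                              names_to = "group", values_to = "mean_z")
  long$group <- ifelse(long$group == "mean_z_low", "EDSS ≤ 4", "EDSS ≥ 4.5")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_z, y = .data$parameter,
                                     colour = .data$group)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "mean z-score", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the correlation screen
#'
#' @param corr Result of [spearman_with_fdr()].
#' @return A ggplot object (parameter x outcome grid of rho).
#' @export
plot_correlations <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$outcome, y = .data$parameter,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman ρ") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pls_fit <- function(object, ...) {
  df <- tibble(observed = object$observed, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(
      x = paste("observed", object$outcome),
      y = paste("predicted", object$outcome),
      subtitle = sprintf("R² = %.2f (n = %d)", object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pls_selection <- function(object, ...) autoplot(object$fit, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of PLS contribution weights across outcomes
#'
#' @param models Named list of [exhaustive_feature_selection()] results
#'   (e.g. from [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_contributions <- function(models) {
  df <- purrr::imap(models, function(m, oc) {
    tidy(m) %>% mutate(outcome = oc)
  }) %>% bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$term,
                                   fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "contribution") +
    ggplot2::theme_minimal()
}
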