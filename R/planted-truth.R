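#' Per-participant generative oculomotor ground truth
#'
#' Bundles every generative quantity the gaze simulator needs for one
#' participant: saccade latency distributions, the main-sequence
#' parameters `eta` (saturation peak velocity, deg/s) and `c` (amplitude
#' constant, deg) of the relation `Vp = eta * (1 - exp(-A / c))`, saccade
#' amplitude gain, fixational scatter (stationary SDs and correlation of
#' an Ornstein–Uhlenbeck drift process; the default correlation time of 1 s keeps drift speeds physiological), square-wave-jerk intrusion rate
#' and amplitude, anti-saccade error and correction probabilities,
#' smooth-pursuit gain/lag and catch-up triggering, blink rate, and the
#' sensor noise model.
#'
#' Sensor noise is parameterized by the device precision convention:
#' `noise_rms_s2s` is the root-mean-square sample-to-sample distance of a
#' stationary gaze point (the standard precision metric for eye
#' trackers); the implied white per-axis Gaussian SD is
#' `noise_rms_s2s / 2`. `bias_deg` adds a constant accuracy offset.
#'
#' @param latency_pro_mean,latency_pro_sd Pro-saccade latency mean/SD (ms).
#' @param latency_anti_correct_mean,latency_anti_correct_sd Latency of
#'   correct-direction anti-saccades (ms).
#' @param latency_anti_error_mean,latency_anti_error_sd Latency of
#'   incorrect-direction anti-saccades (ms).
#' @param time_to_correct_mean,time_to_correct_sd Delay from an incorrect
#'   anti-saccade to its corrective saccade (ms).
#' @param eta,c Main-sequence parameters (deg/s, deg); both > 0.
#' @param amp_gain,amp_gain_sd Saccade amplitude gain (relative to target
#'   eccentricity) and its per-trial SD.
#' @param fix_sigma_x,fix_sigma_y,fix_rho Stationary fixational scatter
#'   SDs (deg) and correlation (|rho| < 1).
#' @param scatter_tau Correlation time of the fixational drift process (s).
#' @param intrusion_rate Saccadic-intrusion rate during fixation
#'   (individual saccades per second; square-wave-jerk pairs are generated
#'   at half this rate since each pair contributes two saccades).
#' @param intrusion_amp_mean,intrusion_amp_sd Intrusion amplitude mean/SD
#'   (deg); draws are truncated below at 0.5 deg.
#' @param swj_interval Time between the end of the outgoing and the start
#'   of the return saccade of an intrusion pair (s).
#' @param anti_error_prob,anti_correction_prob Probability of an initial
#'   wrong-direction anti-saccade, and of correcting it.
#' @param pursuit_gain Smooth-pursuit velocity gain (eye speed / target
#'   speed).
#' @param pursuit_lag Positional lag behind the target after a catch-up
#'   saccade (deg).
#' @param pursuit_latency Pursuit onset latency (s).
#' @param catchup_threshold Positional error (deg) that triggers a
#'   catch-up saccade.
#' @param blink_rate Blink rate (events/s); blinks mark 100–300 ms of
#'   samples invalid.
#' @param noise_rms_s2s Sensor precision as RMS sample-to-sample distance
#'   (deg); per-axis white SD is half this value.
#' @param bias_deg Constant horizontal accuracy offset (deg).
#' @return A list of class `planted_truth`.
#' @export
#' @examples
#' truth <- planted_truth(eta = 500, c = 6)
#' main_sequence(10, truth$eta, truth$c) # planted peak velocity of a 10 deg saccade
planted_truth <- function(latency_pro_mean = 220, latency_pro_sd = 30,
                          latency_anti_correct_mean = 280,
                          latency_anti_correct_sd = 40,
                          latency_anti_error_mean = 230,
                          latency_anti_error_sd = 40,
                          time_to_correct_mean = 250, time_to_correct_sd = 60,
                          eta = 500, c = 6,
                          amp_gain = 0.95, amp_gain_sd = 0.04,
                          fix_sigma_x = 0.30, fix_sigma_y = 0.30, fix_rho = 0,
                          scatter_tau = 1.0,
                          intrusion_rate = 0.30,
                          intrusion_amp_mean = 1.3, intrusion_amp_sd = 0.25,
                          swj_interval = 0.2,
                          anti_error_prob = 0.25, anti_correction_prob = 0.8,
                          pursuit_gain = 0.93, pursuit_lag = 0.5,
                          pursuit_latency = 0.12, catchup_threshold = 2.0,
                          blink_rate = 0.08,
                          noise_rms_s2s = 0.33, bias_deg = 0) {
  truth <- as.list(environment())
  validate_planted_truth(truth)
  structure(truth, class = c("planted_truth", "list"))
}

validate_planted_truth <- function(truth) {
  check_pos(truth$eta, "eta")
  check_pos(truth$c, "c")
  for (nm in c("latency_pro_mean", "latency_anti_correct_mean",
               "latency_anti_error_mean", "time_to_correct_mean")) {
    check_pos(truth[[nm]], nm)
  }
  for (nm in c("latency_pro_sd", "latency_anti_correct_sd",
               "latency_anti_error_sd", "time_to_correct_sd",
               "amp_gain", "amp_gain_sd", "fix_sigma_x", "fix_sigma_y",
               "intrusion_rate", "intrusion_amp_mean", "intrusion_amp_sd",
               "pursuit_gain", "pursuit_lag", "blink_rate",
               "noise_rms_s2s", "catchup_threshold")) {
    check_nonneg(truth[[nm]], nm)
  }
  check_prob(truth$anti_error_prob, "anti_error_prob")
  check_prob(truth$anti_correction_prob, "anti_correction_prob")
  if (!is_scalar_number(truth$fix_rho) || abs(truth$fix_rho) >= 1) {
    abort("`fix_rho` must satisfy |rho| < 1.")
  }
  check_pos(truth$scatter_tau, "scatter_tau")
  invisible(truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>\n")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-26s %g\n", nm, flat[[nm]]))
  invisible(x)
}
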