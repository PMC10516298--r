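# Trace conditioning: artifact (blink) handling and smoothed velocity.

#' Remove non-saccadic artifacts from a gaze recording
#'
#' Invalid-sample runs (blinks, tracking losses) are handled by rule:
#' runs no longer than `interp_limit_ms` are linearly interpolated (and
#' flagged `interp`); longer runs are masked together with a guard margin
#' of `guard_ms` on each side. No sample values are invented beyond the
#' interpolation. The sensor's `valid` flag is preserved; the analysis
#' mask lives in a new `usable` column, which makes the operation
#' idempotent.
#'
#' @param rec Gaze recording tibble (`t_s`, `x_deg`, `y_deg`, `valid`).
#' @param guard_ms Guard margin masked around long invalid runs (ms).
#' @param interp_limit_ms Maximum gap length that is interpolated (ms).
#' @return The recording with `usable` and `interp` columns; interpolated
#'   samples carry filled `x_deg`/`y_deg`.
#' @export
#' @examples
#' rec <- tibble::tibble(t_s = (0:9) / 60, x_deg = 1, y_deg = 0,
#'                       valid = rep(c(TRUE, FALSE, TRUE), c(4, 2, 4)))
#' remove_artifacts(rec)
remove_artifacts <- function(rec, guard_ms = 50, interp_limit_ms = 75) {
  assert_gaze_recording(rec)
  rec <- as_tibble(rec)
  bad <- !rec$valid | !is.finite(rec$x_deg) | !is.finite(rec$y_deg)
  if (all(bad)) abort("All samples are invalid: empty recording after artifact removal.")
  usable <- !bad
  interp <- rep(FALSE, nrow(rec))
  x <- rec$x_deg
  y <- rec$y_deg
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      # gap duration measured between the flanking valid samples
      t_lo <- if (i0 > 1) rec$t_s[i0 - 1L] else rec$t_s[i0]
      t_hi <- if (i1 < nrow(rec)) rec$t_s[i1 + 1L] else rec$t_s[i1]
      gap_ms <- (t_hi - t_lo) * 1000
      if (gap_ms <= interp_limit_ms && i0 > 1 && i1 < nrow(rec)) {
        idx <- i0:i1
        w <- (rec$t_s[idx] - t_lo) / (t_hi - t_lo)
        x[idx] <- x[i0 - 1L] + w * (x[i1 + 1L] - x[i0 - 1L])
        y[idx] <- y[i0 - 1L] + w * (y[i1 + 1L] - y[i0 - 1L])
        usable[idx] <- TRUE
        interp[idx] <- TRUE
      } else {
        guard <- guard_ms / 1000
        in_guard <- rec$t_s >= rec$t_s[i0] - guard & rec$t_s <= rec$t_s[i1] + guard
        usable[in_guard] <- FALSE
      }
    }
  }
  rec$x_deg <- x
  rec$y_deg <- y
  rec$usable <- usable
  rec$interp <- interp
  rec
}

# Vectorized local-polynomial (Savitzky-Golay-style) first derivative of
# order 2 on the actual timestamps: for each interior sample, a quadratic
# is least-squares fitted to the `window` surrounding samples and its
# slope at the centre timestamp is returned.  Exact for polynomials up to
# order 2; reduces to the classic SG derivative on a uniform grid.
local_quadratic_deriv <- function(t, z, window = 5L) {
  n <- length(t)
  half <- (window - 1L) %/% 2L
  offs <- (-half):half
  idx <- outer(seq_len(n), offs, `+`)
  ok_idx <- idx >= 1L & idx <= n
  idx[!ok_idx] <- 1L # placeholder, masked below
  tm <- matrix(t[idx], n, window) - t
  zm <- matrix(z[idx], n, window)
  tm[!ok_idx] <- NA
  zm[!ok_idx] <- NA
  s0 <- rowSums(!is.na(zm))
  s1 <- rowSums(tm, na.rm = TRUE)
  s2 <- rowSums(tm^2, na.rm = TRUE)
  s3 <- rowSums(tm^3, na.rm = TRUE)
  s4 <- rowSums(tm^4, na.rm = TRUE)
  b0 <- rowSums(zm, na.rm = TRUE)
  b1 <- rowSums(tm * zm, na.rm = TRUE)
  b2 <- rowSums(tm^2 * zm, na.rm = TRUE)
  # solve [s0 s1 s2; s1 s2 s3; s2 s3 s4] a = [b0 b1 b2] for a1 (Cramer)
  det3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33) {
    a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
  }
  d <- det3(s0, s1, s2, s1, s2, s3, s2, s3, s4)
  d1 <- det3(s0, b0, s2, s1, b1, s3, s2, b2, s4)
  v <- d1 / d
  v[s0 < window | rowSums(!is.finite(zm)) > 0] <- NA_real_
  v
}

#' Estimate smoothed gaze velocity
#'
#' Local polynomial (Savitzky–Golay-style) differentiation of order 2
#' over a `window`-sample neighbourhood, computed on the actual
#' timestamps so unequal sample spacing is handled exactly. Masked
#' (unusable) samples propagate: the velocity is masked wherever any
#' sample of the local window is unusable, and at the trace edges.
#'
#' @param rec A gaze recording, ideally from [remove_artifacts()] (a raw
#'   recording is accepted; its `valid` flag is used as the mask).
#' @param window Window length in samples (odd, >= 5).
#' @return Tibble with `t_s`, `vx`, `vy`, `speed` (deg/s) and `usable`.
#' @export
#' @examples
#' rec <- tibble::tibble(t_s = (0:19) / 60, x_deg = 8.65 * (0:19) / 60,
#'                       y_deg = 0, valid = TRUE)
#' v <- estimate_velocity(remove_artifacts(rec))
#' v$vx[5] # ~8.65: exact on a linear ramp
estimate_velocity <- function(rec, window = 5L) {
  assert_gaze_recording(rec)
  if (window < 5L || window %% 2L == 0L) abort("`window` must be an odd number >= 5.")
  if (!"usable" %in% names(rec)) rec <- remove_artifacts(rec)
  ok <- rec$usable
  if (sum(ok) < window) abort("Recording too short: need at least `window` usable samples.")
  x <- rec$x_deg
  y <- rec$y_deg
  x[!ok] <- NA_real_
  y[!ok] <- NA_real_
  vx <- local_quadratic_deriv(rec$t_s, x, window)
  vy <- local_quadratic_deriv(rec$t_s, y, window)
  usable <- is.finite(vx) & is.finite(vy)
  tibble(t_s = rec$t_s, vx = vx, vy = vy,
         speed = sqrt(vx^2 + vy^2), usable = usable)
}
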