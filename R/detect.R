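#' Fixation detection configuration
#'
#' Thresholds for velocity/acceleration based fixation detection: a sample
#' belongs to a fixation when the pupil is valid and both the gaze velocity
#' and the magnitude of the gaze acceleration are strictly below their
#' thresholds (30 deg/s and 8000 deg/s^2 by default, the usual video-tracker
#' saccade-detector settings).
#'
#' @param velocity_threshold Saccade velocity threshold, deg/s.
#' @param acceleration_threshold Saccade acceleration threshold, deg/s^2.
#' @param min_fixation_ms Minimum duration for a run of fixational samples to
#'   be reported as a fixation.
#' @param smoothing_window Moving-average window (odd sample count, >= 3)
#'   applied to the gaze trace before differentiation.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(velocity_threshold = 30,
                             acceleration_threshold = 8000,
                             min_fixation_ms = 40,
                             smoothing_window = 5L) {
  if (velocity_threshold <= 0 || acceleration_threshold <= 0 || min_fixation_ms <= 0)
    stop("thresholds must be positive")
  w <- as.integer(smoothing_window)
  if (w < 3L || w %% 2L == 0L) stop("smoothing_window must be odd and >= 3")
  structure(list(velocity_threshold = velocity_threshold,
                 acceleration_threshold = acceleration_threshold,
                 min_fixation_ms = min_fixation_ms,
                 smoothing_window = w),
            class = "detection_config")
}

# centered moving average with replicated ends
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  stats::filter(xp, rep(1 / w, w), sides = 2)[(h + 1L):(h + length(x))]
}

# central difference with one-sided ends
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# strict-inequality sample classifier (exactly-at-threshold is saccadic)
sample_is_fixational <- function(vel_deg_s, acc_deg_s2, valid, config) {
  valid & vel_deg_s < config$velocity_threshold &
    abs(acc_deg_s2) < config$acceleration_threshold
}

#' Detect fixations in a raw gaze track
#'
#' Converts the pixel trace to visual angle about the screen centre (per axis,
#' through the geometry's calibrated pixel pitch), smooths it with a centred
#' moving average, differentiates by central differences, and labels each
#' sample as fixational when it is valid and both speed and acceleration
#' magnitude are strictly below the configured thresholds. Maximal runs of
#' fixational samples spanning at least `min_fixation_ms` become fixations
#' with the run centroid as position, the first sample time as onset, and the
#' run length times the sampling interval as duration. Invalid (blink)
#' samples break runs.
#'
#' @param track A [raw_track()], approximately uniformly sampled (at most 10%
#'   jitter in the inter-sample interval).
#' @param geometry A [screen_geometry()].
#' @param config A [detection_config()].
#' @return data.frame of fixations (`onset_ms`, `duration_ms`, `x_px`,
#'   `y_px`), time-ordered and non-overlapping; zero rows when no run
#'   qualifies.
#' @export
detect_fixations <- function(track, geometry = screen_geometry(),
                             config = detection_config()) {
  stopifnot(inherits(track, "raw_track"), inherits(geometry, "screen_geometry"),
            inherits(config, "detection_config"))
  n <- length(track$times_ms)
  if (n < 3) stop("need at least 3 samples for event detection")
  dts <- diff(track$times_ms)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 0.10 * dt))
    stop("sampling interval varies by more than 10%; resample the track first")
  to_deg <- function(px, center) {
    atan((px - center) * geometry$pitch_mm / geometry$distance_mm) * 180 / pi
  }
  dt_s <- dt / 1000
  tx <- to_deg(moving_average(track$x_px, config$smoothing_window),
               geometry$width_px / 2)
  ty <- to_deg(moving_average(track$y_px, config$smoothing_window),
               geometry$height_px / 2)
  vx <- central_diff(tx, dt_s); vy <- central_diff(ty, dt_s)
  speed <- sqrt(vx^2 + vy^2)
  ax <- central_diff(vx, dt_s); ay <- central_diff(vy, dt_s)
  accel <- sqrt(ax^2 + ay^2)
  fixational <- sample_is_fixational(speed, accel, track$valid, config)

  r <- rle(fixational)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * dt >= config$min_fixation_ms
  out <- data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                    x_px = numeric(0), y_px = numeric(0))
  for (k in which(keep)) {
    idx <- starts[k]:ends[k]
    out <- rbind(out, data.frame(
      onset_ms = track$times_ms[starts[k]],
      duration_ms = r$lengths[k] * dt,
      x_px = mean(track$x_px[idx]),
      y_px = mean(track$y_px[idx])))
  }
  rownames(out) <- NULL
  out
}
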