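#' Screen geometry and degree/pixel calibration
#'
#' Describes the display an eye-movement experiment was run on: pixel
#' resolution, viewing distance, and a calibration pair fixing the physical
#' pixel pitch. The pitch is derived from the calibration pair through the
#' exact tangent chord formula, so the pair is reproduced exactly by
#' [deg_to_px()] and all other conversions stay principled at larger
#' eccentricities instead of relying on a small-angle linear scale.
#'
#' The default geometry is a 1920 x 1080 display viewed at 855 mm, calibrated
#' so that 5 degrees of visual angle span 270 pixels.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param distance_mm Viewing distance in millimetres.
#' @param calib_deg,calib_px Calibration pair: a visual angle (degrees) and the
#'   on-screen extent (pixels) it subtends at `distance_mm`.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' deg_to_px(2.5, geom)  # 135
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            distance_mm = 855, calib_deg = 5, calib_px = 270) {
  stopifnot(is.numeric(width_px), is.numeric(height_px), is.numeric(distance_mm))
  if (width_px <= 0 || height_px <= 0 || distance_mm <= 0)
    stop("screen dimensions and viewing distance must be positive")
  if (!is.finite(calib_deg) || !is.finite(calib_px) || calib_deg <= 0 || calib_px <= 0)
    stop("calibration pair must be positive and finite")
  pitch_mm <- 2 * distance_mm * tan(calib_deg * pi / 360) / calib_px
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         distance_mm = distance_mm,
         calib_deg = calib_deg, calib_px = calib_px, pitch_mm = pitch_mm),
    class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %g mm viewing distance\n",
              x$width_px, x$height_px, x$distance_mm))
  cat(sprintf("  calibration: %g deg <-> %g px (pitch %.4f mm/px)\n",
              x$calib_deg, x$calib_px, x$pitch_mm))
  invisible(x)
}

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Convert visual angle to on-screen pixels
#'
#' Uses the chord formula `extent = 2 * d * tan(angle / 2) / pitch` with the
#' pixel pitch fixed by the geometry's calibration pair, then rounds half-up
#' to whole pixels. With the default geometry, 5 degrees map to 270 px and
#' 2.5 degrees to 135 px (the recurrence radius used throughout).
#'
#' @param angle_deg Visual angle(s) in degrees, `>= 0`.
#' @param geometry A [screen_geometry()].
#' @return Integer pixel extent(s).
#' @seealso [px_to_deg()] for the exact inverse (before rounding).
#' @export
deg_to_px <- function(angle_deg, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0))
    stop("angle_deg must be finite and non-negative")
  px <- 2 * geometry$distance_mm * tan(angle_deg * pi / 360) / geometry$pitch_mm
  as.integer(round_half_up(px))
}

#' Convert an on-screen pixel extent to visual angle
#'
#' Exact inverse of the unrounded [deg_to_px()] chord formula.
#'
#' @param px Pixel extent(s), `>= 0`.
#' @inheritParams deg_to_px
#' @return Visual angle(s) in degrees.
#' @export
px_to_deg <- function(px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(!is.finite(px)) || any(px < 0))
    stop("px must be finite and non-negative")
  2 * atan(px * geometry$pitch_mm / (2 * geometry$distance_mm)) * 180 / pi
}

#' Screen diagonal in pixels
#'
#' Normalization constant for the scanpath-similarity dissimilarities.
#'
#' @inheritParams deg_to_px
#' @return Length of the screen diagonal in pixels.
#' @export
screen_diag_px <- function(geometry = screen_geometry()) {
  sqrt(geometry$width_px^2 + geometry$height_px^2)
}
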