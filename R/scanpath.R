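#' Construct a scanpath
#'
#' A scanpath is the ordered fixation sequence of one participant x trial x
#' phase, with the screen geometry attached. Fixations are given as a data
#' frame with one row per fixation and columns `onset_ms`, `duration_ms`,
#' `x_px`, `y_px` (additional columns are carried along untouched).
#' Coordinates are screen pixels, origin top-left, x rightward, y downward,
#' 0-based; positions may be fractional; times are milliseconds.
#'
#' @param fixations data.frame with columns `onset_ms`, `duration_ms`, `x_px`,
#'   `y_px`; rows must be ordered by strictly increasing onset.
#' @param participant,trial Labels identifying the recording.
#' @param phase One of `"encoding"`, `"imagery"`, `"reinspection"`.
#' @param condition Encoding condition: `"FP"` (free perception), `"GCW"`
#'   (gaze-contingent window), `"AS"` (artificial scotoma), or `NA`.
#' @param category Stimulus category (`"abstract"`, `"indoor"`, `"outdoor"`)
#'   or `NA`.
#' @param geometry A [screen_geometry()].
#' @param validate Check invariants (strictly increasing onsets, positive
#'   durations). Positions are allowed off-screen here; preprocessing removes
#'   them.
#' @return An object of class `scanpath`.
#' @export
scanpath <- function(fixations, participant = "p1", trial = "t1",
                     phase = c("encoding", "imagery", "reinspection"),
                     condition = NA_character_, category = NA_character_,
                     geometry = screen_geometry(), validate = TRUE) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(fixations), inherits(geometry, "screen_geometry"))
  needed <- c("onset_ms", "duration_ms", "x_px", "y_px")
  miss <- setdiff(needed, names(fixations))
  if (length(miss))
    stop("fixations lack column(s): ", paste(miss, collapse = ", "))
  if (!is.na(condition) && !condition %in% c("FP", "GCW", "AS"))
    stop("condition must be FP, GCW, AS or NA")
  if (!is.na(category) && !category %in% c("abstract", "indoor", "outdoor"))
    stop("category must be abstract, indoor, outdoor or NA")
  if (validate && nrow(fixations)) {
    if (any(fixations$duration_ms <= 0)) stop("durations must be positive")
    if (any(fixations$onset_ms < 0)) stop("onsets must be non-negative")
    if (nrow(fixations) > 1 && any(diff(fixations$onset_ms) <= 0))
      stop(sprintf("onsets not strictly increasing in %s/%s/%s",
                   participant, trial, phase))
  }
  rownames(fixations) <- NULL
  structure(
    list(participant = as.character(participant), trial = as.character(trial),
         phase = phase, condition = condition, category = category,
         fixations = fixations, geometry = geometry),
    class = "scanpath")
}

#' Number of fixations in a scanpath
#' @param sp A [scanpath()].
#' @return Integer count.
#' @export
n_fixations <- function(sp) {
  stopifnot(inherits(sp, "scanpath"))
  nrow(sp$fixations)
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> %s / %s / %s (condition %s, category %s): %d fixations\n",
              x$participant, x$trial, x$phase, x$condition, x$category,
              nrow(x$fixations)))
  if (nrow(x$fixations)) {
    span <- max(x$fixations$onset_ms + x$fixations$duration_ms) -
      min(x$fixations$onset_ms)
    cat(sprintf("  span %.0f ms, mean duration %.0f ms\n",
                span, mean(x$fixations$duration_ms)))
  }
  invisible(x)
}

#' @export
as.data.frame.scanpath <- function(x, ...) {
  if (!nrow(x$fixations)) {
    out <- data.frame(participant = character(), trial = character(),
                      phase = character(), condition = character(),
                      category = character())
    return(cbind(out, x$fixations))
  }
  data.frame(participant = x$participant, trial = x$trial, phase = x$phase,
             condition = x$condition, category = x$category,
             x$fixations, stringsAsFactors = FALSE)
}

#' Raw gaze sample track
#'
#' Regularly sampled gaze positions as delivered by a video eye tracker,
#' before event detection. `valid` marks samples with a usable pupil; invalid
#' samples (blinks) never belong to a fixation.
#'
#' @param times_ms Strictly increasing sample times (ms).
#' @param x_px,y_px Gaze coordinates (pixels).
#' @param valid Logical vector, pupil present.
#' @return An object of class `raw_track`.
#' @export
raw_track <- function(times_ms, x_px, y_px, valid = rep(TRUE, length(times_ms))) {
  n <- length(times_ms)
  if (length(x_px) != n || length(y_px) != n || length(valid) != n)
    stop("times_ms, x_px, y_px and valid must have equal length")
  if (n > 1 && any(diff(times_ms) <= 0))
    stop("times_ms must be strictly increasing")
  structure(list(times_ms = as.numeric(times_ms), x_px = as.numeric(x_px),
                 y_px = as.numeric(y_px), valid = as.logical(valid)),
            class = "raw_track")
}

#' @export
print.raw_track <- function(x, ...) {
  n <- length(x$times_ms)
  cat(sprintf("<raw_track> %d samples, %.0f-%.0f ms, %.1f%% valid\n",
              n, if (n) min(x$times_ms) else NA, if (n) max(x$times_ms) else NA,
              if (n) 100 * mean(x$valid) else NA))
  invisible(x)
}
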