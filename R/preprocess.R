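#' Filter fixations by screen bounds and duration
#'
#' Applies the standard fixation-report filters: removes fixations that land
#' off-screen, then fixations shorter than `min_ms`, then fixations longer
#' than `max_ms`. The duration cut-offs are strict inequalities ("shorter
#' than" / "longer than" read literally), so a fixation of exactly 100 or
#' 5000 ms is kept. The screen is treated as the half-open rectangle
#' `[0, width) x [0, height)`: a position exactly at the width or height is
#' off-screen. Removal reasons are checked in the order off-screen, short,
#' long, so the per-reason counts partition the removed rows.
#'
#' @param sp A [scanpath()] with geometry attached.
#' @param min_ms,max_ms Duration cut-offs in ms (defaults 100 and 5000).
#' @return A list with elements `scanpath` (the filtered [scanpath()], order
#'   preserved) and `report` (a `preprocess_report` with counts `n_input`,
#'   `n_removed_offscreen`, `n_removed_short`, `n_removed_long`, `n_kept`).
#' @export
filter_fixations <- function(sp, min_ms = 100, max_ms = 5000) {
  stopifnot(inherits(sp, "scanpath"))
  fx <- sp$fixations
  g <- sp$geometry
  off <- fx$x_px < 0 | fx$x_px >= g$width_px | fx$y_px < 0 | fx$y_px >= g$height_px
  short <- !off & fx$duration_ms < min_ms
  long <- !off & !short & fx$duration_ms > max_ms
  keep <- !(off | short | long)
  out <- sp
  out$fixations <- fx[keep, , drop = FALSE]
  rownames(out$fixations) <- NULL
  report <- structure(
    list(n_input = nrow(fx),
         n_removed_offscreen = sum(off),
         n_removed_short = sum(short),
         n_removed_long = sum(long),
         n_kept = sum(keep),
         min_ms = min_ms, max_ms = max_ms),
    class = "preprocess_report")
  list(scanpath = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "<preprocess_report> %d fixations in: %d kept, %d off-screen, %d < %g ms, %d > %g ms\n",
    x$n_input, x$n_kept, x$n_removed_offscreen, x$min_ms, x$n_removed_short,
    x$max_ms, x$n_removed_long))
  invisible(x)
}

#' Combine preprocess reports
#'
#' Sums the counts of several `preprocess_report`s (e.g. one per trial).
#'
#' @param reports List of `preprocess_report` objects.
#' @return A single `preprocess_report`.
#' @export
combine_reports <- function(reports) {
  stopifnot(all(vapply(reports, inherits, TRUE, "preprocess_report")))
  tot <- function(f) sum(vapply(reports, `[[`, numeric(1), f))
  structure(list(n_input = tot("n_input"),
                 n_removed_offscreen = tot("n_removed_offscreen"),
                 n_removed_short = tot("n_removed_short"),
                 n_removed_long = tot("n_removed_long"),
                 n_kept = tot("n_kept"),
                 min_ms = reports[[1]]$min_ms, max_ms = reports[[1]]$max_ms),
            class = "preprocess_report")
}

#' Per-participant gaze quality summary
#'
#' Aggregates total fixation time, fixation count and mean fixation duration
#' per participant, and compares each participant with the rest of the sample
#' through z-scores. Participants with `|z| >` the threshold on any statistic
#' are flagged — flagged only, never excluded automatically.
#'
#' @param scanpaths List of [scanpath()] objects.
#' @param z_threshold Flagging threshold on the absolute z-score (default 3).
#' @return data.frame with one row per participant: the three statistics,
#'   their z-scores (`NA` with a `status` attribute of `"no-z"` when fewer
#'   than two participants are present) and a logical `flagged` column. Empty
#'   input yields an empty data.frame.
#' @export
qc_summary <- function(scanpaths, z_threshold = 3) {
  if (!length(scanpaths)) {
    return(data.frame(participant = character(), total_fix_time_ms = numeric(),
                      n_fixations = integer(), mean_duration_ms = numeric(),
                      z_total_time = numeric(), z_n_fixations = numeric(),
                      z_mean_duration = numeric(), flagged = logical()))
  }
  stopifnot(all(vapply(scanpaths, inherits, TRUE, "scanpath")))
  ids <- vapply(scanpaths, `[[`, character(1), "participant")
  per <- lapply(split(scanpaths, ids), function(sps) {
    dur <- unlist(lapply(sps, function(sp) sp$fixations$duration_ms))
    data.frame(total_fix_time_ms = sum(dur), n_fixations = length(dur),
               mean_duration_ms = if (length(dur)) mean(dur) else NA_real_)
  })
  out <- do.call(rbind, per)
  out <- cbind(data.frame(participant = names(per), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  if (nrow(out) >= 2) {
    out$z_total_time <- zscore(out$total_fix_time_ms)
    out$z_n_fixations <- zscore(out$n_fixations)
    out$z_mean_duration <- zscore(out$mean_duration_ms)
    out$flagged <- abs(out$z_total_time) > z_threshold |
      abs(out$z_n_fixations) > z_threshold |
      abs(out$z_mean_duration) > z_threshold
  } else {
    out$z_total_time <- out$z_n_fixations <- out$z_mean_duration <- NA_real_
    out$flagged <- NA
    attr(out, "status") <- "no-z"
    warning("z-scores need at least two participants; returning summary only")
  }
  out
}
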