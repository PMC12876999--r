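#' Read a tabular fixation report
#'
#' Reads the canonical delimited fixation-report dialect: one row per
#' fixation, header
#' `participant trial phase condition category onset_ms duration_ms x_px y_px`,
#' tab-separated (a comma-separated variant is accepted and auto-detected).
#' Rows are grouped into one [scanpath()] per (participant, trial, phase)
#' group, in file order. Unknown columns are preserved as opaque annotation
#' columns and written back verbatim by [write_fixation_report()], so a
#' read/write cycle is lossless on the canonical dialect.
#'
#' @param path File to read.
#' @param geometry [screen_geometry()] attached to every scanpath.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma from
#'   the header line.
#' @return List of [scanpath()] objects.
#' @export
read_fixation_report <- function(path, geometry = screen_geometry(), sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "", quote = "")
  mandatory <- c("participant", "trial", "phase", "condition", "category",
                 "onset_ms", "duration_ms", "x_px", "y_px")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("fixation report is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), mandatory)
  if (!nrow(df)) return(list())
  key <- paste(df$participant, df$trial, df$phase, sep = "\r")
  groups <- unname(split(seq_len(nrow(df)), factor(key, levels = unique(key))))
  lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    if (nrow(g) > 1 && any(diff(g$onset_ms) <= 0))
      stop(sprintf("onsets not monotone in group %s/%s/%s",
                   g$participant[1], g$trial[1], g$phase[1]))
    fx <- g[c("onset_ms", "duration_ms", "x_px", "y_px", extra)]
    scanpath(fx, participant = g$participant[1], trial = g$trial[1],
             phase = g$phase[1],
             condition = if (is.na(g$condition[1])) NA_character_ else as.character(g$condition[1]),
             category = if (is.na(g$category[1])) NA_character_ else as.character(g$category[1]),
             geometry = geometry)
  })
}

fmt_time <- function(t) sprintf("%d", as.integer(round(t)))
fmt_pos <- function(p) sprintf("%.2f", p)

#' Write scanpaths as a fixation report
#'
#' Inverse of [read_fixation_report()]: deterministic column order, positions
#' with two decimals, times as integer milliseconds, tab-separated, UTF-8.
#' An empty scanpath list yields a header-only file.
#'
#' @param scanpaths List of [scanpath()] objects (a single scanpath is
#'   accepted).
#' @param path Output file.
#' @param sep Field separator (tab for the canonical dialect).
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(scanpaths, path, sep = "\t") {
  if (inherits(scanpaths, "scanpath")) scanpaths <- list(scanpaths)
  mandatory <- c("participant", "trial", "phase", "condition", "category",
                 "onset_ms", "duration_ms", "x_px", "y_px")
  extra <- unique(unlist(lapply(scanpaths, function(sp)
    setdiff(names(sp$fixations), c("onset_ms", "duration_ms", "x_px", "y_px")))))
  lines <- paste(c(mandatory, extra), collapse = sep)
  for (sp in scanpaths) {
    fx <- sp$fixations
    if (!nrow(fx)) next
    cols <- cbind(sp$participant, sp$trial, sp$phase,
                  as.character(sp$condition), as.character(sp$category),
                  fmt_time(fx$onset_ms), fmt_time(fx$duration_ms),
                  fmt_pos(fx$x_px), fmt_pos(fx$y_px))
    for (e in extra)
      cols <- cbind(cols, if (e %in% names(fx)) as.character(fx[[e]]) else "")
    lines <- c(lines, apply(cols, 1L, paste, collapse = sep))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a raw gaze-sample track
#'
#' TSV with header `time_ms x_px y_px valid` (`valid` as 0/1 or TRUE/FALSE).
#'
#' @param path File to read.
#' @return A [raw_track()].
#' @export
read_raw_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("time_ms", "x_px", "y_px", "valid"), names(df))
  if (length(miss))
    stop("raw track is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  raw_track(df$time_ms, df$x_px, df$y_px, as.logical(df$valid))
}

#' Write a raw gaze-sample track
#'
#' @param track A [raw_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_raw_track <- function(track, path) {
  stopifnot(inherits(track, "raw_track"))
  df <- data.frame(time_ms = track$times_ms, x_px = track$x_px,
                   y_px = track$y_px, valid = as.integer(track$valid))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
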