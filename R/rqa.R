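#' RQA configuration
#'
#' Parameters of the fixation-sequence recurrence quantification analysis.
#' The recurrence radius is specified in degrees of visual angle and
#' converted to pixels through the geometry ([deg_to_px()]); the default
#' 2.5 degrees corresponds to 135 px at the default geometry, a radius
#' spanning the fovea into the parafovea. `radius_px` may be given directly
#' to bypass the conversion.
#'
#' @param radius_deg Recurrence radius in degrees (default 2.5).
#' @param l_min Minimum line length for determinism/laminarity (default 2).
#' @param radius_px Optional explicit pixel radius overriding `radius_deg`.
#' @return An object of class `rqa_config`.
#' @export
rqa_config <- function(radius_deg = 2.5, l_min = 2L, radius_px = NULL) {
  if (!is.null(radius_px) && radius_px <= 0) stop("radius must be positive")
  if (is.null(radius_px) && radius_deg <= 0) stop("radius must be positive")
  if (l_min < 2) stop("l_min must be at least 2")
  structure(list(radius_deg = radius_deg, l_min = as.integer(l_min),
                 radius_px = radius_px, distance = "euclidean"),
            class = "rqa_config")
}

resolve_radius_px <- function(config, geometry) {
  if (!is.null(config$radius_px)) config$radius_px
  else deg_to_px(config$radius_deg, geometry)
}

#' Recurrence matrix of a scanpath
#'
#' Two fixations are recurrent when the Euclidean distance between their
#' positions is less than or equal to the radius (inclusive threshold, per
#' the Heaviside step definition of the recurrence matrix). The matrix is
#' symmetric with an all-true main diagonal (self recurrence).
#'
#' @param sp A [scanpath()] with `n >= 2` fixations.
#' @param config An [rqa_config()].
#' @return A `recurrence_plot`: list with the `n x n` logical `matrix`, `n`,
#'   and the pixel radius used.
#' @export
recurrence_matrix <- function(sp, config = rqa_config()) {
  stopifnot(inherits(sp, "scanpath"), inherits(config, "rqa_config"))
  n <- nrow(sp$fixations)
  if (n < 2) stop("recurrence analysis needs at least 2 fixations")
  eps <- resolve_radius_px(config, sp$geometry)
  d <- as.matrix(stats::dist(cbind(sp$fixations$x_px, sp$fixations$y_px)))
  structure(list(matrix = d <= eps, n = n, radius_px = eps,
                 l_min = config$l_min),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  r <- sum(x$matrix[upper.tri(x$matrix)])
  cat(sprintf("<recurrence_plot> n = %d, radius = %g px, %d recurrent pairs\n",
              x$n, x$radius_px, r))
  invisible(x)
}

#' @export
plot.recurrence_plot <- function(x, ...) {
  graphics::image(seq_len(x$n), seq_len(x$n), t(x$matrix[x$n:1, ]),
                  col = c("white", "black"), xlab = "fixation j",
                  ylab = "fixation i", main = "Recurrence plot", ...)
  invisible(x)
}

upper_pairs <- function(plot) sum(plot$matrix[upper.tri(plot$matrix)])

# Points on qualifying runs of a logical sequence. A maximal run qualifies
# when its length reaches l_min, or when it fills the whole segment it lives
# on (border completion: lines truncated by the matrix border still count, so
# a fully recurrent plot scores 100).
run_points <- function(seq, l_min) {
  if (!length(seq)) return(0L)
  r <- rle(seq)
  qual <- r$values & (r$lengths >= l_min | r$lengths == length(seq))
  sum(r$lengths[qual])
}

diag_line_points <- function(mat, l_min) {
  n <- nrow(mat)
  total <- 0L
  for (k in seq_len(n - 1)) {
    i <- seq_len(n - k)
    total <- total + run_points(mat[cbind(i, i + k)], l_min)
  }
  total
}

hv_line_points <- function(mat, l_min) {
  n <- nrow(mat)
  h <- 0L; v <- 0L
  for (i in seq_len(n - 1)) h <- h + run_points(mat[i, (i + 1):n], l_min)
  for (j in 2:n) v <- v + run_points(mat[1:(j - 1), j], l_min)
  c(horizontal = h, vertical = v)
}

#' Recurrence rate
#'
#' Percentage of recurrent fixation pairs: `100 * 2R / (n(n-1))` with `R` the
#' number of recurrent pairs in the upper triangle (main diagonal excluded) —
#' the standard fixation-RQA normalization.
#'
#' @param plot A `recurrence_plot` from [recurrence_matrix()].
#' @return Percentage in [0, 100].
#' @export
recurrence_rate <- function(plot) {
  stopifnot(inherits(plot, "recurrence_plot"))
  100 * 2 * upper_pairs(plot) / (plot$n * (plot$n - 1))
}

#' Determinism
#'
#' Percentage of recurrence points lying on diagonal lines of the recurrence
#' matrix: refixations that repeat in the same sequential order. Computed on
#' the upper triangle only (the matrix is symmetric), with the main diagonal
#' of self recurrence excluded. A maximal diagonal run counts when it has at
#' least `l_min` points or fills its entire diagonal (border completion), so
#' a fully recurrent plot is 100% deterministic. Returns 0 (degenerate) when
#' there is no recurrence.
#'
#' @inheritParams recurrence_rate
#' @param l_min Minimum line length (default taken from the plot, normally 2).
#' @return Percentage in [0, 100].
#' @export
determinism <- function(plot, l_min = plot$l_min) {
  stopifnot(inherits(plot, "recurrence_plot"))
  r <- upper_pairs(plot)
  if (r == 0) return(0)
  100 * diag_line_points(plot$matrix, l_min) / r
}

#' Laminarity
#'
#' Percentage of recurrence points on horizontal or vertical lines of the
#' recurrence matrix: clustered dwells where an area is inspected or
#' reinspected with consecutive fixations. Counted as
#' `100 * (H + V) / (2R)` with `H` and `V` the points on horizontal and
#' vertical runs of length `>= l_min` scanned in the upper triangle (both
#' triangles of the symmetric matrix are thereby represented, matching the
#' full-matrix sum of the defining formula). Runs filling their whole border
#' segment count regardless of length (border completion). Returns 0 when
#' there is no recurrence.
#'
#' @inheritParams determinism
#' @return Percentage in [0, 100].
#' @export
laminarity <- function(plot, l_min = plot$l_min) {
  stopifnot(inherits(plot, "recurrence_plot"))
  r <- upper_pairs(plot)
  if (r == 0) return(0)
  hv <- hv_line_points(plot$matrix, l_min)
  100 * sum(hv) / (2 * r)
}

#' Fixation spread
#'
#' Root-mean-square Euclidean distance of the fixations from their centroid;
#' the dispersion covariate reported alongside the recurrence measures (more
#' spread-out scanpaths mechanically recur less).
#'
#' @param sp A [scanpath()] with at least 2 fixations.
#' @return Spread in pixels.
#' @export
fixation_spread <- function(sp) {
  stopifnot(inherits(sp, "scanpath"))
  n <- nrow(sp$fixations)
  if (n < 2) stop("fixation spread needs at least 2 fixations")
  x <- sp$fixations$x_px; y <- sp$fixations$y_px
  sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
}

#' Recurrence quantification analysis of a scanpath
#'
#' Convenience wrapper computing the recurrence matrix and all scalar
#' measures at once.
#'
#' @inheritParams recurrence_matrix
#' @return An `rqa_result`: list with `n`, `rec_count` (recurrent pairs in
#'   the upper triangle), `recurrence_rate`, `determinism`, `laminarity`
#'   (percentages), `fixation_spread` (px), `radius_px`, and `degenerate`
#'   (TRUE when no pair recurs, in which case determinism and laminarity are
#'   0 by convention).
#' @export
rqa <- function(sp, config = rqa_config()) {
  plot <- recurrence_matrix(sp, config)
  r <- upper_pairs(plot)
  structure(list(n = plot$n, rec_count = r,
                 recurrence_rate = recurrence_rate(plot),
                 determinism = determinism(plot, config$l_min),
                 laminarity = laminarity(plot, config$l_min),
                 fixation_spread = fixation_spread(sp),
                 radius_px = plot$radius_px,
                 degenerate = r == 0L),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf(
    "<rqa_result> n = %d, R = %d | REC %.2f%%, DET %.2f%%, LAM %.2f%%, spread %.1f px%s\n",
    x$n, x$rec_count, x$recurrence_rate, x$determinism, x$laminarity,
    x$fixation_spread, if (x$degenerate) " (degenerate: no recurrence)" else ""))
  invisible(x)
}
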